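id,region,hemisphere,x,y,z
AGl_L,AGl,L,-2.25111637390219,17.9518236962147,1.16320800501853
AGm_L,AGm,L,-2.23775475202128,17.9743086339906,0.315810416359454
CERC_L,CERC,L,-2.62831627912819,5.81497241314501,0.718056611716747
Cu_L,Cu,L,-2.3017314243596,3.18941596550867,1.29126375680789
DCeN_L,DCeN,L,-2.4149526886642,6.47270049955696,1.55164672527462
DRGC1_L,DRGC1,L,-2.48854243052192,0.18303063865751,1.12729368312284
DRGC2_L,DRGC2,L,-2.35804701121524,-0.844898037798703,0.467406797222793
DRGC3_L,DRGC3,L,-2.71920004165731,-1.94400849221274,0.179961032699794
Gr_L,Gr,L,-2.4058046257589,3.18838664414361,0.171224129851907
ILN_L,ILN,L,-2.37696112957783,12.5475352829322,0.610436738934368
IO_L,IO,L,-2.52535493425094,4.93337088450789,1.33485302934423
LTNG_L,LTNG,L,-2.36853264900856,12.1386992992833,0.000477793160825968
mPFC_L,mPFC,L,-2.23919665170833,18.9593941645697,0.417139913886786
Pn_L,Pn,L,-2.64674270539545,8.11387711027637,1.86606825469062
PTG_L,PTG,L,-2.52262430647388,11.6155745964497,1.85128949722275
S1_L,S1,L,-2.23599128634669,16.0995181544684,1.46818860201165
S2_L,S2,L,-2.21306414296851,15.5709107320756,0.666143966838717
VL_L,VL,L,-2.72950758300722,11.8685057321563,1.03012665966526
VNT_L,VNT,L,-2.51500175106339,11.4044351855293,1.48794929264113
VPL_L,VPL,L,-2.46380035225302,12.0057651738636,1.23831848008558
AGl_R,AGl,R,2.74241883237846,18.0702429098077,1.25249068904668
AGm_R,AGm,R,2.28322610063478,18.1931268791668,0.434315396472812
CERC_R,CERC,R,2.79333503735252,6.10381770702079,0.433134621940553
Cu_R,Cu,R,2.76800093953498,3.02659536963329,0.777890057303011
DCeN_R,DCeN,R,2.24946253485978,6.63987588742748,1.88491138396785
DRGC1_R,DRGC1,R,2.50852707060985,-0.124210425838828,1.9252160275355
DRGC2_R,DRGC2,R,2.43412208026275,-1.09148535411805,1.47971055842936
DRGC3_R,DRGC3,R,2.74344287854619,-1.868736605905,1.46649181144312
Gr_R,Gr,R,2.46818177686073,3.07728192815557,1.07152257999405
ILN_R,ILN,R,2.70160255599767,12.396217895858,0.00454593217000365
IO_R,IO,R,2.64255737066269,4.81719551840797,1.2178749050945
LTNG_R,LTNG,R,2.68663308476098,12.0561916376464,1.67360311886296
mPFC_R,mPFC,R,2.4328649696894,18.8865541660227,1.50304512539878
Pn_R,Pn,R,2.61110183764249,7.99175942568108,0.905463145114481
PTG_R,PTG,R,2.20236900327727,11.6789641369134,1.07157998764887
S1_R,S1,R,2.69974964815192,16.0877423350699,1.07475339062512
S2_R,S2,R,2.20440048812889,15.3031538954936,0.00276168715208769
VL_R,VL,R,2.3245953836944,11.9501959858462,0.711331907659769
VNT_R,VNT,R,2.7439608446788,11.5057630833238,1.22426618030295
VPL_R,VPL,R,2.56706718606874,11.8006282216869,1.65788426110521
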