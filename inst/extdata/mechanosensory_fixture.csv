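source,target,weight,category,contralateral
DRGC1_L,Cu_L,1,4,FALSE
DRGC2_L,Cu_L,1,4,FALSE
DRGC3_L,Cu_L,1,4,FALSE
Cu_L,VL_R,1,4,TRUE
Cu_L,VPL_R,1,4,TRUE
VL_L,S1_L,1,4,FALSE
VPL_L,S1_L,1,4,FALSE
Gr_L,VPL_R,0.471486636345739,3,TRUE
Cu_L,CERC_L,0.0494171336132384,2,FALSE
Pn_L,CERC_R,0.471486636345739,3,TRUE
IO_L,CERC_R,0.471486636345739,3,TRUE
CERC_L,DCeN_L,1,4,FALSE
DCeN_L,VL_R,0.471486636345739,3,TRUE
S1_L,S2_L,1,4,FALSE
S2_L,S1_L,0.471486636345739,3,FALSE
S1_L,AGl_L,0.471486636345739,3,FALSE
AGl_L,AGm_L,0.471486636345739,3,FALSE
AGm_L,mPFC_L,0.0494171336132384,2,FALSE
S1_L,Pn_L,0.471486636345739,3,FALSE
S1_L,S1_R,0.0494171336132384,2,TRUE
ILN_L,S1_L,0.0494171336132384,2,FALSE
ILN_L,AGm_L,0.0494171336132384,2,FALSE
LTNG_L,S2_L,0.0494171336132384,2,FALSE
PTG_L,S2_L,0.0494171336132384,2,FALSE
VNT_L,AGl_L,0.00115139539932645,1,FALSE
DRGC1_R,Cu_R,1,4,FALSE
DRGC2_R,Cu_R,1,4,FALSE
DRGC3_R,Cu_R,1,4,FALSE
Cu_R,VL_L,1,4,TRUE
Cu_R,VPL_L,1,4,TRUE
VL_R,S1_R,1,4,FALSE
VPL_R,S1_R,1,4,FALSE
Gr_R,VPL_L,0.471486636345739,3,TRUE
Cu_R,CERC_R,0.0494171336132384,2,FALSE
Pn_R,CERC_L,0.471486636345739,3,TRUE
IO_R,CERC_L,0.471486636345739,3,TRUE
CERC_R,DCeN_R,1,4,FALSE
DCeN_R,VL_L,0.471486636345739,3,TRUE
S1_R,S2_R,1,4,FALSE
S2_R,S1_R,0.471486636345739,3,FALSE
S1_R,AGl_R,0.471486636345739,3,FALSE
AGl_R,AGm_R,0.471486636345739,3,FALSE
AGm_R,mPFC_R,0.0494171336132384,2,FALSE
S1_R,Pn_R,0.471486636345739,3,FALSE
S1_R,S1_L,0.0494171336132384,2,TRUE
ILN_R,S1_R,0.0494171336132384,2,FALSE
ILN_R,AGm_R,0.0494171336132384,2,FALSE
LTNG_R,S2_R,0.0494171336132384,2,FALSE
PTG_R,S2_R,0.0494171336132384,2,FALSE
VNT_R,AGl_R,0.00115139539932645,1,FALSE
mPFC_R,LTNG_R,0.0494171336132384,2,FALSE
IO_R,LTNG_L,0.00115139539932645,1,TRUE
Pn_R,DCeN_R,0.00115139539932645,1,FALSE
Pn_R,AGm_L,0.00115139539932645,1,TRUE
ILN_R,LTNG_R,0.471486636345739,3,FALSE
PTG_L,S1_R,0.0494171336132384,2,TRUE
VL_L,PTG_L,0.0494171336132384,2,FALSE
VL_R,S1_L,0.00115139539932645,1,TRUE
ILN_R,AGl_R,0.471486636345739,3,FALSE
mPFC_R,PTG_R,0.0494171336132384,2,FALSE
Pn_R,VPL_R,0.0494171336132384,2,FALSE
VL_L,mPFC_L,0.471486636345739,3,FALSE
Cu_R,Pn_R,0.471486636345739,3,FALSE
PTG_L,VL_L,0.00115139539932645,1,FALSE
AGm_R,IO_R,0.471486636345739,3,FALSE
mPFC_L,AGm_L,0.0494171336132384,2,FALSE
AGl_L,ILN_R,0.00115139539932645,1,TRUE
LTNG_R,AGl_L,0.471486636345739,3,TRUE
mPFC_L,DCeN_R,0.471486636345739,3,TRUE
VL_R,VNT_L,0.0494171336132384,2,TRUE
S1_R,AGm_R,0.471486636345739,3,FALSE
VL_R,IO_L,0.00115139539932645,1,TRUE
AGm_R,PTG_R,0.00115139539932645,1,FALSE
S2_R,VPL_R,0.0494171336132384,2,FALSE
Gr_L,PTG_L,0.00115139539932645,1,FALSE
AGl_R,VNT_L,0.471486636345739,3,TRUE
VNT_R,Gr_R,0.0494171336132384,2,FALSE
PTG_R,Gr_R,0.471486636345739,3,FALSE
ILN_L,IO_R,0.00115139539932645,1,TRUE
Cu_L,mPFC_R,0.00115139539932645,1,TRUE
VL_L,ILN_R,0.00115139539932645,1,TRUE
S2_R,LTNG_L,0.00115139539932645,1,TRUE
S1_L,AGm_R,0.00115139539932645,1,TRUE
DCeN_L,ILN_R,0.0494171336132384,2,TRUE
IO_R,ILN_R,0.471486636345739,3,FALSE
AGm_R,VPL_L,0.471486636345739,3,TRUE
S2_R,S1_L,0.471486636345739,3,TRUE
LTNG_L,VL_L,0.00115139539932645,1,FALSE
ILN_R,Gr_L,0.00115139539932645,1,TRUE
ILN_R,IO_L,0.00115139539932645,1,TRUE
Cu_L,LTNG_L,0.0494171336132384,2,FALSE
S1_L,CERC_R,0.471486636345739,3,TRUE
LTNG_L,AGm_L,0.471486636345739,3,FALSE
VNT_R,IO_R,0.00115139539932645,1,FALSE
Cu_L,Cu_R,0.471486636345739,3,TRUE
LTNG_L,VPL_L,0.0494171336132384,2,FALSE
AGm_R,Pn_L,0.471486636345739,3,TRUE
LTNG_L,Cu_L,0.0494171336132384,2,FALSE
Cu_R,mPFC_L,0.471486636345739,3,TRUE
VL_L,VL_R,0.471486636345739,3,TRUE
S2_R,DCeN_L,0.00115139539932645,1,TRUE
LTNG_L,CERC_R,0.00115139539932645,1,TRUE
S1_L,DCeN_R,0.00115139539932645,1,TRUE
VL_L,Pn_R,0.471486636345739,3,TRUE
Cu_L,IO_R,0.0494171336132384,2,TRUE
CERC_L,CERC_R,0.00115139539932645,1,TRUE
DCeN_L,VNT_R,0.471486636345739,3,TRUE
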