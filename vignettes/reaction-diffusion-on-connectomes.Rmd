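---
title: "Reaction-diffusion dynamics on weighted directed connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-diffusion dynamics on weighted directed connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdconnectome)
```

## The modelling problem

A connectome is a weighted, directed map of the projections between brain
regions. Neural signal propagation through such a network can be emulated by
reaction-diffusion (RD) dynamics: each region carries concentrations of
interacting species governed by local reaction kinetics, and the network
edges transport the species between regions. The motivating application is
demyelinating disease (multiple sclerosis): demyelination of a tract is
modelled as a time-varying reduction of the corresponding connection weights,
and one asks how oscillation amplitudes, synchrony and the cluster structure
of region co-activity change downstream of the lesion — here along the
mechanosensitive pathway from the cervical dorsal root ganglia (DRG) through
the cuneate nucleus and contralateral thalamus to the primary somatosensory
cortex.

`rdconnectome` implements the full pipeline: graph representation and I/O,
reaction kinetics, the network diffusion operator with time-varying weights,
noise, distance relays, numerical integration, time-series similarity
statistics, clustering, parameter sweeps, and the linear stability analysis
of the activator-inhibitor kinetics.

## Reaction models

Four kinetics are available, each as an `rd_model` constructor:

* **Gierer-Meinhardt** (`gm_model`), activator `u` / inhibitor `v`:
  $f = r_u u^2/((1+\kappa u^2)v) - \mu_u u + \sigma_u$,
  $g = r_v u^2 - \mu_v v + \sigma_v$. The division by $v$ makes $v \le 0$ a
  *hard domain error*; a silent clamp would mask stiffness problems, so the
  epsilon floor (`solver_config(v_floor = ...)`) is an explicit, warned
  opt-in.
* **Mimura-Murray** (`mm_model`), a predator-prey generalization of
  Lotka-Volterra: $f = ((A + Bu - u^2)/C - v)\,u$, $g = (u - (1 + Dv))\,v$.
  The canonical literature form is adopted (parameter names match the sweep
  labels $A$-$D$); the default set $A=35, B=16, C=9, D=0.4$ has the
  coexistence equilibrium $(5, 10)$.
* **Gray-Scott** (`gs_model`): $f = -uv^2 + F(1-u)$,
  $g = uv^2 - (F+k)v$ with feed rate $F$ and kill rate $k$; $(1,0)$ is
  always an equilibrium. This model does not sustain the long oscillations
  needed for connectome synchrony analysis and serves as a contrast case.
* **Wilson-Cowan** (`wc_model`), the neural-mass baseline: excitatory and
  inhibitory populations with the classic offset-subtracted logistic
  response, refractory factor $(1-E)$, and a network term
  $\eta\, W^\top E$ inside the excitatory sigmoid argument. The exact
  variant used by the original simulation framework is not published; we
  adopt the classic 1972 formulation and flag it as such. Notably, the
  widely quoted "single-oscillator limit cycle" parameter set
  (aE 1.2, aI 2.0, cEE 5, cII 1, cIE 6, cEI 10, thetaE 2, thetaI 3.5,
  P 0.25) is *not* oscillatory under this variant (we scanned the
  offset/no-offset, refractory/no-refractory and both threshold-scaling
  conventions, and the external drive over [0, 10]; the fixed point is
  always attracting). The preset `wc_limit_cycle` ships that parameter list
  for reference; the package's limit-cycle tests use the canonical
  oscillatory set (cEE 16, cEI 12, cIE 15, cII 3, aE 1.3, thetaE 4,
  P 1.25), under which the implementation does produce a sustained cycle.

## The coupling operator

`build_coupling` assembles the diffusion operator $L$ entering
$\dot U = f(U) + L U$. In the default `out_diffusion` mode, mass flows along
edge direction: node $i$ gains $\sum_j w_{ji} U_j$ and loses
$U_i \sum_j w_{ij}$. Columns of $L$ then sum to zero, so total mass is
conserved exactly (to machine precision under Euler, since conservation is a
linear identity). `in_diffusion` sends mass against the edges, and the two
`*_transpose` modes apply the same constructions to the transposed
adjacency; `out_diffusion` of a graph equals `in_diffusion` of the
edge-reversed graph, which the tests exploit. Self-loops never contribute:
diffusion to self is a no-op. Species-specific diffusion constants
($D_u, D_v$) scale $L$ per species.

Ordinal connection strengths $x \in [0,4]$ from tract-tracing metastudies
are mapped to weights by the exponential transform
$w(x) = 10^{-\frac{16}{49}(x-4)^2}$ (`weight_from_category`), strictly
increasing with $w(4)=1$.

## Time-varying weights, noise, distance relays

*Demyelination schedules.* `modulation_schedule` multiplies the weights of
selected edges by $m(t)$: a step (e.g. factor 0.3 or 0.1 held from onset), a
damped cosine
$m(t) = \max(\mathrm{floor},\, 1 - A e^{-\lambda t}(1-\cos 2\pi t/T)/2)$
bounded in $[\mathrm{floor}, 1]$ (defaults: amplitude 10, floor 0.1 —
relapsing-remitting episodes that plateau), or an explicit per-step table.
Because $L$ is linear in the edge weights, the integrator assembles
$L(t) = L_\mathrm{fixed} + m(t) L_\mathrm{modulated}$ exactly, rather than
rebuilding the operator approximately. The damped-cosine *formula* is our
parameterization: only the amplitude/floor pair and the qualitative shape
are prescribed by the motivating study.

*Noise.* A scalar Ornstein-Uhlenbeck process $\delta_t$
(Euler-Maruyama: $\delta_{t+dt} = \delta_t + \theta(\mu-\delta_t)dt +
\sigma\sqrt{dt}\,\xi$) perturbs the diffusion term additively after each
deterministic step: $U \leftarrow U + dt\,\delta\,L U$. It is applied to
the activator only by default (switchable to all species), since the
reference formulation writes the noisy update for $U$ alone. Plain additive
Gaussian state noise is also available. One seeded generator drives the
whole run; the seed is recorded in the trajectory metadata and identical
seeds give bitwise identical runs.

*Distance relays.* Straight-line centroid distances enter by inserting
relay nodes on an edge (`insert_distance_nodes`): an edge of weight $e_1$
with $k$ relays becomes the chain with rate $D e_1$ out of the source and
$\Theta D e_1$ out of each relay, so signal arrival is delayed without
destroying mass conservation. The per-edge relay count comes from the
transform $F_1 d + F_2/w + S$ (`distance_factor`, defaults
$F_1 = F_2 = 0.01$), rounded to the nearest nonnegative integer with
$\Theta = 1$ — the mapping from the transform to graph changes is only
described qualitatively in the source material, so both the count and the
$\Theta$ hook are exposed.

## Solvers and numerical choices

`solver_config` selects forward Euler, classic RK4, step-controlled
Dormand-Prince (`deSolve`'s `ode45`), or backward Euler with damped Newton
iteration and a finite-difference Jacobian for stiff systems (the implicit
scheme is quadratic in state dimension per step and intended for small
networks). The time axis is iteration-step based and dimensionless, matching
how the results are reported. Cross-solver consistency is enforced in the
tests on the relay chain, whose exact solution is the matrix exponential.
A non-finite state aborts with the step index; explicit methods add a hint
to try the implicit solver. Default experiment scales follow the reference
conditions: Gierer-Meinhardt runs use $dt = 2$ over 5000 steps (10000 time
units), Mimura-Murray 400 steps of $dt = 0.1$.

Default diffusion constants for `gm_model` are $D_u = 0.01, D_v = 0.1$ —
inhibitor faster than activator, and small enough that explicit stepping at
$dt = 2$ is stable on connectome-scale weight sums. The Turing-regime preset
`gm_turing` instead uses the stable-kinetics point $(a, b) = (0.005, 0.025)$
with a strong contrast $D_u = 0.005, D_v = 0.5$, which places the most
unstable lattice mode inside the spectrum of the 32x32 grid Laplacian; from
near-uniform noisy initial conditions it develops a stationary heterogeneous
(Turing) pattern whose spatial variance the tests compare against a
diffusion-only control.

## Stability and bifurcation analysis

For a single uncoupled node the Gierer-Meinhardt model with reaction
constants fixed at 0.01 reduces to
$\dot u = 0.01 u^2/v - b u + a$, $\dot v = 0.01 u^2 - 0.01 v$,
with $a = \sigma_u$ and $b = \mu_u$. The positive fixed point is closed
form, $v^* = u^{*2}$, $u^* = (0.01 + a)/b$ (`gm_fixed_point`) — $(2, 4)$ at
$a = b = 0.01$. `gm_stability` evaluates the analytic Jacobian there and
classifies by the leading eigenvalue ("first eigenvalue" = largest real
part, the one that governs stability; marginal within $10^{-10}$). The
determinant is $0.01\,b > 0$ for all admissible parameters, so loss of
stability always occurs through a Hopf bifurcation (complex pair crossing
the axis). The trace is $b\,(0.02/(0.01+a) - 1) - 0.01$: for $a \ge 0.01$
it is negative for every $b$ (always stable), while for $a < 0.01$ it
crosses zero at a unique $b^*(a)$ — so in the $(a, b)$ plane small $a$
(left of the curve) is the oscillatory region and large $a$ the stable one,
with oscillation for $b > b^*$ at fixed $a$. `gm_boundary_curve` finds
$b^*(a)$ by Brent root search on the leading real part, bracketed by a
coarse logarithmic scan; the tests check the root against a brute-force
sign-change scan and check that classification agrees with long-run
simulation (decay versus sustained oscillation of $|u - u^*|$) on a probe
grid, including after network coupling.

## Similarity, synchrony, clustering

* `cross_correlation_matrix`: zero-lag Pearson correlation of post-transient
  series. Zero-lag is our default reading of "cross-correlation" — it
  reproduces the block structure of interest; constant series get
  correlation 0 with a warning. The default transient discards the first
  10% of samples (the burn-in visible in all the reference trajectories).
* `coactivation_matrix`: series are binarized at mean + 0.5 SD per node (a
  co-activation threshold is nowhere defined in the source material, so the
  rule is configurable) and pairs scored by the Jaccard overlap of active
  time bins.
* `kuramoto_order`: instantaneous phases from the FFT analytic signal
  (discrete Hilbert transform) of mean-subtracted series;
  $r(t) = |N^{-1}\sum_j e^{i\phi_j(t)}| \in [0,1]$. The window edges (5%
  each side) are trimmed, and constant series are excluded with a warning
  since they carry no phase.
* `spectral_cluster`: symmetric normalized-Laplacian embedding plus k-means
  with fixed seed; `k = "auto"` uses the eigengap heuristic (the cluster
  count is never stated in the reference analyses). Correlations are mapped
  to affinities by $(1+c)/2$ first.
* `mcl`: Markov clustering with the published parameter semantics — values
  normalized to $[0,1]$, entries below `zero_threshold` ($10^{-7}$) zeroed,
  `loop_gain` written onto the diagonal when positive, inflation exponent
  2.0, convergence when successive iterates differ by less than
  `equal_threshold` entrywise. Clusters are the connected components of the
  limit matrix's nonzero structure.
* `jaccard_clustering_similarity`: the average best-match Jaccard
  coefficient over the clusters of both partitions; 1 exactly for identical
  partitions.
* `modularity_partition`: Louvain on the symmetrized weighted graph
  (igraph), returning the partition and its modularity $Q$.
* `local_graph_metrics`: in/out/total degree, `DGinDGall` (adopted as the
  ratio deg_in/deg_all — the original "convergent-divergent degree
  coefficient" formula is unpublished), the out-neighbourhood clustering
  coefficient, mean matching indices, and average-tie ranks.

`run_sweep` enumerates inclusive-endpoint parameter grids (`sweep_grid`,
`sweep_preset`) in deterministic lexicographic order — inclusive endpoints
are required to reproduce the documented combination counts (16, 256, 540,
375) — and assembles per-combination similarity matrices, clusterings, the
entrywise-average matrix and the pairwise clustering-similarity matrix.
Failed combinations are recorded and excluded with a warning rather than
aborting a long sweep.

## The synthetic fixture and surrogate networks

`mechanosensory_fixture` builds a 40-node bilateral network (20 named
regions x left/right) whose mechanosensitive chain is wired anatomically
(DRG to ipsilateral cuneate nucleus, cuneate to contralateral VL/VPL
thalamus, thalamus to ipsilateral S1; DRG nodes have no afferents) and whose
remaining cortico-cortical, thalamo-cortical and cerebellar edges are drawn
with a seeded RNG from ordinal categories 1-4. The fixture emulates the
*structure* of the real subconnectome — bilateral symmetry, contralateral
crossings, sensory feed-forward chain, no DRG afferents — but its weights
are synthetic stand-ins: the real adjacency values live in a separately
downloadable project and are deliberately not reproduced. Consequently,
quantities that depend on the real weights (specific correlation values,
the exact three-module partition, amplitude traces) are out of scope here;
the package instead tests *properties* on the fixture (e.g. that reducing
the DRG-to-cuneate weights by a factor 0.3 measurably changes the S1
cross-correlation pattern). Tests passing on the fixture therefore validate
the machinery, not any empirical claim about the rat brain.

`generate_surrogate` provides seed-deterministic structural null models:
Erdos-Renyi, a directed Watts-Strogatz ring with rewiring, Barabasi-Albert,
exact degree-preserving rewiring via directed double-edge swaps, and a
Klemm-Eguiluz growing scale-free generator with an active-node window
(random orientation per bond). Node counts are exact; edge counts are
matched to a template exactly by random trimming/addition (rewiring is
exact by construction). `build_lattice` produces the regular 2D grid
(reflecting or periodic, 4- or 8-neighbourhood) whose coupling operator
discretizes the continuous Laplacian.

## Reproducibility and I/O

Connectomes round-trip through edge-list CSV (with a node-attribute
companion), adjacency TSV with id headers, and GraphML; malformed input
fails with the offending line. Trajectories export as long-format TSV with
a JSON metadata sidecar; every `run_from_config` output directory contains
a manifest (config, seed, package version, artifact checksums) sufficient
to reproduce it. The `inst/cli/rdconnectome` script exposes `simulate`,
`sweep` (with `--dry-run` combination counts), `stability`, `netgen` and
`fixture` subcommands as a thin layer over the exported functions.

## Problem sizes and limitations

The shipped test and example configurations use desk-scale sizes chosen to
exercise every code path: the 40-node fixture with 1500-2000 step runs for
network experiments, a 32x32 lattice over 12000 steps for the Turing
pattern, 3-6 node chains and toy graphs for solver oracles, and 2-3
combination sweeps (the full 256/540-combination enumerations are verified
as counts and available through the presets).

Known limitations: delay differential equations (distance enters only
through relay nodes, not true delays), spectral/wavelet analysis of the
trajectories, Turing analysis over network Laplacian spectra, and the
binary project format of the original GUI framework are all out of scope.
The implicit solver's finite-difference Jacobian is dense; for large
networks use the explicit methods with a smaller step instead.
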