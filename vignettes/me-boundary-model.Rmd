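---
title: "An adaptive vertex model of the mesectoderm-ectoderm boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive vertex model of the mesectoderm-ectoderm boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meboundary)
```

## The biological question

In the early *Drosophila* embryo a supracellular actomyosin cable runs
along the interface between the mesectoderm -- the single-file rows of
midline neural and glial progenitors -- and the flanking ectoderm. The
cable keeps the two populations separate, but it is disassembled over the
hour in which the mesectoderm constricts apically and internalizes, while
the ectoderm around it divides vigorously. This package implements a
computational model of that interface together with the measurement layer
needed to quantify it, asking how a boundary can stay sharp while the
tension that maintains it decays, and what role the surrounding divisions
play -- as a challenge to the boundary, as a source of tissue fluidity, or
both.

## The model

The tissue is a two-dimensional vertex model: a confluent polygonal tiling
of a periodic box in which each cell $i$ contributes

$$E_i = K_A (A_i - A_{0i})^2 + K_P (P_i - P_{0i})^2$$

and every edge separating a mesectoderm cell from an ectoderm cell carries
an additional line energy $\gamma(t)\, l$, modelling the actomyosin cable.
Vertices follow overdamped Brownian dynamics integrated with forward
Euler,

$$\mathbf r_k \leftarrow \mathbf r_k + \mu \mathbf F_k \,\Delta t +
\boldsymbol\eta_k, \qquad \mathbf F_k = -\nabla_k E,$$

with $\boldsymbol\eta_k$ zero-mean Gaussian noise of per-component
variance $2\mu T \Delta t$. Lengths are measured in units of
$\sqrt{A_0}$ of a reference cell, energies in units of $K_A A_0^2$, and
time in units of $\tau = 1/(\mu K_A A_0)$, which corresponds to 0.1 min of
developmental time; the integration step is $\Delta t = 0.01\tau$ and the
noise strength is $T = 0.010$. Preferred perimeters are slaved to
preferred areas through a constant target shape index $q = P_0/\sqrt{A_0}
= 3.4$, which places the passive tissue in the solid (jammed) regime: at
that $q$ cells cannot satisfy area and perimeter targets simultaneously,
junctions carry positive tension at rest, and spontaneous neighbour
exchanges are rare.

Three time-varying inputs make the model adaptive:

* **Cable decay.** $\gamma(t) = \gamma_0 e^{-k_\gamma t}$, emulating the
  gradual disassembly of the boundary cable.
* **Apical constriction.** The preferred area of mesectoderm cells
  decreases linearly from its initial value to a configurable fraction
  over the 40-minute horizon (the in-vivo constriction curve is not
  tabulated anywhere we can import it from, so the simplest monotone
  emulation is used; the fraction is a configuration value).
* **Divisions.** Ectoderm cells that have not yet divided are selected by
  Poisson thinning at a tissue-level rate; a selected cell is split
  through its centroid perpendicular to a spindle angle, its daughters
  take the post-division preferred area, and the system relaxes at zero
  temperature after each event. Cells touching the boundary orient their
  spindle along the dorsal-ventral axis (wrapped normal, 15 degree spread
  -- the observation is "preferential" orientation without a stated
  distribution); all others divide with uniformly random orientation.
  In division-inhibition scenarios divisions stop at 5 min, mimicking the
  delayed action of a cell-cycle inhibitor injected at time zero.

Neighbour exchanges (T1 transitions) are performed whenever an edge drops
below $l_{T1} = 0.04$ length units; the new edge opens at $1.5\,l_{T1}$
perpendicular to the old one. Both values are standard vertex-model
practice; the source framework for this class of models performs the swap
internally and does not expose its thresholds. Candidate swaps are
validated against the full tiling (simple polygons, every edge shared by
exactly two cells in opposite orientations) and skipped when a triangle
would be destroyed.

### Junctional tension

The tension along the junction between vertices $a$ and $b$, shared by
cells $j$ and $k$, is the energy gradient with respect to the edge length:

$$T_{ab} = \frac{\partial E}{\partial l_{ab}}
         = 2K_P (P_j - P_{0j}) + 2K_P (P_k - P_{0k})\; [+\ \gamma
           \text{ on boundary edges}].$$

The factor of 2 follows from differentiating the squared perimeter term;
it is verified against a finite-difference oracle in the test suite
rather than against any external convention. Negative values indicate
compression.

## Initialization and the time origin

Simulations start from a Voronoi tessellation of 400 uniformly random
points in a periodic square (mean cell area 1), relaxed for $10^3\tau$ at
uniform target parameters. A central horizontal stripe of cells about one
cell diameter in half-width (roughly two cell rows, around 40 cells) is
then labelled mesectoderm; the remaining cells become a 50/50 bidisperse
mixture of pre- and post-division ectoderm. Before measurements start the
labelled tissue equilibrates for a few minutes with the full cable tension
$\gamma_0$ and constant preferred areas; time zero -- when the mesectoderm
width starts decreasing -- is the onset of constriction, cable decay and
division scheduling. The equilibration length is a configuration value: it
sets how far the freshly labelled (still cell-scale-ragged) interface has
relaxed toward the cable-smoothed steady state at $t=0$, and therefore the
baseline against which all relative roughness changes are measured.

## Micrometre calibration

One simulation length unit is mapped to micrometres by requiring the mean
ectoderm cell radius to be about 4 um, the same length used as the
self-overlap radius ("approximately one cell radius"). With mean cell
area 1 the effective radius is $1/\sqrt{\pi}$, giving
$4\sqrt{\pi} \approx 7.09$ um per unit; the 400-cell box is then about
142 um across, comparable to the 136 um field used for the in-vivo
division counts.

## Calibrated defaults

The study's exact parameter table is in supplementary material that is
not part of the main text, so the free parameters were fixed by a
documented calibration (`analysis/00_calibrate.R`) anchored on the
published in-silico outcomes: the control boundary refines by about 7%
over 40 min while acute loss of boundary tension roughens it by about 36%
within 10 min; secondary anchors are the division-driven tension release
and the self-overlap half-time. The frozen defaults are:

```{r}
unlist(me_schedule())
me_params()
```

Two of these deserve comment. The division rate is expressed per tissue
per minute; because only pre-division ectoderm cells are eligible, the
pool (about 180 cells) depletes over the 40-minute horizon and the
realized division count saturates near the pool size, which reproduces
the published average junction counts per simulation. The bidisperse
preferred areas encode more than size heterogeneity: each division
replaces one pre-division cell with two daughters whose summed preferred
area exceeds the parent's by $2A_0^{post} - A_0^{pre}$. That net
injection of preferred area is the mechanism by which divisions compress
the tissue, lower junctional tension, and press the ectoderm smoothly
against the boundary; it is the main lever behind both the tension
release and the slow boundary refinement in control simulations.

## Measurement layer

All quantification operates on tabular data (centroid tracks, boundary
polylines, recoil curves) and applies identically to simulation records
and tracked-cell data.

* **Boundary roughness** -- a polyline is rotated so its least-squares
  line is horizontal, detrended to zero mean, and summarized by the
  population standard deviation of the transverse coordinates. Curves are
  reported relative to $t=0$, and windowed statistics use the area under
  the curve re-anchored at the window start. For simulation records the
  trace is the per-side envelope of the mesectoderm stripe (extreme
  dorsoventral extent in bins along the anterior-posterior axis, with
  interpolation across bins where ectoderm bridges interrupt the stripe);
  only the largest edge-connected mesectoderm component is traced, since
  an annotator following the interface would not detour around single
  cells that have detached into the ectoderm.
  This mimics an interactive annotation, which always spans the field of
  view; a naive walk along heterotypic edges is also provided but becomes
  ill-defined once the stripe fragments.
* **Self-overlap** $Q(t)$ -- the fraction of cells displaced less than
  4 um since the reference frame, over ectoderm cells that never divide
  during the observation window. The half-time is the linearly
  interpolated first crossing of $Q = 0.5$; series that never reach 0.5
  are reported as "no decrease" (`NA`). The published definition ("half
  of the reduction") does not state whether the threshold is 0.5 or
  halfway to the final value; we use 0.5, which coincides with the
  published control half-times, and keep the threshold configurable.
* **MSD** -- mean squared centroid displacement after subtracting the
  mean mesectoderm drift (registration), with anterior-posterior and
  dorsal-ventral components that sum exactly to the total.
* **Junctional tension** -- the per-edge analytic $\partial E/\partial l$
  averaged over ectoderm-ectoderm junctions per frame.
* **Kelvin-Voigt recoil fitting** -- post-ablation end-to-end distance
  curves are fitted with $L(t) = L_0 + D(1 - e^{-t/\tau})$, the step
  response of a spring-dashpot pair in parallel: $D$ estimates the
  stress-to-elasticity ratio and $\tau$ the viscosity-to-elasticity
  ratio, and the initial recoil velocity is $v_0 = D/\tau$. The model
  equation is typeset as a figure in the source article, so this is a
  reconstruction from the canonical Kelvin-Voigt response and the
  article's verbal description of $D$ and $\tau$. The secant velocity
  over the first sampling interval is reported alongside $v_0$, since it
  is not stated which of the two the published recoil velocities are;
  the secant necessarily under-estimates the tangent of the concave
  recoil curve.
* **Group comparisons** -- Kruskal-Wallis with Dunn's pairwise z tests
  for three or more groups, Mann-Whitney for two, Wilcoxon signed-rank
  for paired designs. Dunn's test is computed in-package (pooled-rank z
  statistics with tie correction) because no installed package provides
  it.

## Synthetic data

`make_boundary_series()`, `make_track_table()` and `make_recoil_set()`
generate inputs with the statistical structure the analysis assumes --
sinusoidal boundaries of known RMS, trajectories with closed-form MSD and
overlap behaviour (static, diffusive, ballistic, with common drift and
labelled division events), and Kelvin-Voigt recoil curves with known
parameters -- so that every measurement stage is testable without the
simulator. Each generator returns its ground truth next to the data;
recovery tests compare against stored truth, never hard-coded numbers.
They emulate segmented and tracked microscopy output statistically; they
do not emulate segmentation error structure, uneven illumination, or
tracking identity switches, so passing recovery tests certifies the
measurement code, not robustness to raw-image artefacts.

## Numerical choices and degenerate inputs

* Geometry uses the minimum-image convention; per-cell computations
  unwrap each loop locally, which assumes consecutive loop vertices are
  closer than half the box (guaranteed for cell-sized polygons in a
  20-unit box).
* Zero-temperature relaxations stop early once the largest vertex force
  falls below 0.01 (energy units per length unit), the practical
  definition of "relaxed to a new energy minimum" after divisions.
* A division whose cut line grazes a vertex or fails to produce two
  simple polygons is retried with a jittered angle and skipped after five
  attempts; a T1 on a triangle-sided edge is skipped; unswappable short
  edges are temporarily ignored rather than retried forever.
* The Brownian noise inside a dynamics chunk is drawn from a fast local
  generator seeded from R's random stream, so whole runs are byte-for-
  byte reproducible under `set.seed()`.
* Roughness of a near-vertical polyline is computed after a 90-degree
  pre-rotation. Because an ordinary least-squares line fitted to a
  sinusoid over whole periods retains a small slope (the $x\sin x$
  boundary term), the rotate-and-detrend roughness of a sinusoid sits
  about 1% below the ideal $a/\sqrt 2$; tests account for that.
* The flat recoil series is a degenerate ridge for the Kelvin-Voigt fit
  (any tiny $D$ with a huge $\tau$ matches); it is detected and reported
  as $D = 0$ with an unidentifiable relaxation time.

## Problem sizes

The full study design runs 80 replicates per scenario. The bundled
analysis scripts and the acceptance script run 20 replicates of 400 cells
over 40 simulated minutes -- ensemble means of all reported quantities
stabilize well below that -- and the test suite uses 6-replicate
ensembles plus 25-64-cell tissues for unit-level checks, comparing
against the published means within combined sampling error. Replicates
are independent seeded runs; within a seed, all four scenarios start from
the same initialized tissue so that perturbation contrasts are paired.

## Known limitations

* The model omits germband extension/retraction, mesoderm and posterior
  midgut invagination; in embryos these add ectoderm motion that the
  model does not reproduce, which is why registered, division-blocked
  embryos still move more than division-blocked simulations.
* Supplementary parameter values (exact $\gamma_0$, $k_\gamma$, $K_P$,
  preferred areas, division frequency) are calibrated, not transcribed;
  conclusions that depend on their precise values inherit that
  uncertainty even where the calibrated model reproduces the published
  ensemble statistics.
* The in-vivo division count (about one cytokinesis per minute in a
  136 um field) corresponds to a substantially lower tissue-level rate
  than the calibrated in-silico rate; the published per-simulation
  junction counts require the higher rate, and we follow the in-silico
  anchors. The in-vivo figure likely reflects completed cytokineses
  rather than division onsets.
* Mesectoderm internalization itself (the end state of the real tissue)
  is outside the model: the stripe constricts but never leaves the
  plane.
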