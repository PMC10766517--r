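---
title: "From stained sections to a CA1 scaffold connectome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stained sections to a CA1 scaffold connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1scaffold)
```

## What the package computes

`ca1scaffold` builds *scaffold* models of the hippocampal CA1 region:
cell positions, class labels and a synaptic pair list, without biophysical
neuron or synapse models. The pipeline has four blocks:

1. **Placement** — cell-body-stained section stacks are contrast-enhanced,
   binarized with a per-section Otsu threshold, and every stained pixel
   becomes one soma coordinate (at ~20 µm pixels a pixel is about one
   pyramidal soma). The cloud is randomly pruned to the putative neuron
   count, split 90/10 into excitatory pyramidal cells (PCs) and
   interneurons, and the interneurons are assigned to seven morphological
   classes using the geometry of anatomical landmark surfaces.
2. **Morphology** — each neuron's axonal and dendritic arbors are replaced
   by geometric probability volumes: cones (PC dendrites), ellipsoids
   (interneuron arbors) and a surface-following tube (the PC axon, which
   runs through the stratum oriens towards the subiculum, bending with the
   gyrified CA1 surface). Dendritic volumes are scattered at one point per
   64,000 µm³ (a 40 µm voxel); axonal clouds are converted to convex
   hulls.
3. **Connectivity** — touch detection: a directed pair (pre → post) is a
   candidate when the axonal and dendritic bounding boxes overlap (closed
   intervals) *and* at least one dendritic point of the postsynaptic
   neuron falls inside the presynaptic axonal hull. Candidates are pruned
   per class pair to `round(p · N_pre · N_post)` using a connection
   probability table.
4. **Validation** — indegree/outdegree and connection-length probability
   densities, Kullback–Leibler (KL) comparisons against a random baseline
   and against parameter-perturbed variants, and hub detection.

Because whole-hemisphere image data and the full 5.28-million-neuron model
need supercomputer resources, the package ships a first-class synthetic
**mini-CA1** generator with known ground truth, so the entire pipeline
runs and is tested at desk scale.

## The synthetic mini-CA1

The fixture is a bent rectangular sheet (a half-pipe) whose deep (SO)
surface follows

$$z_{SO}(x, y) = b\,(2y/W - 1)^2 + A\,(1 + \sin(2\pi x/\lambda)),$$

with the SR and SLM surfaces parallel offsets along depth. Defaults:
length 6,000 µm (antero-posterior), width 3,000 µm (transversal, CA2 side
at $y = 0$, subiculum side at $y = W$), thickness 1,500 µm, bend depth
600 µm, gyrification amplitude $A$ = 200 µm and wavelength $\lambda$ =
2,000 µm. These sizes keep every topological feature the algorithms rely
on — two separable layer surfaces, two transversal end landmarks,
surface curvature that axon trajectories must follow — at a scale where a
5,000-neuron scaffold builds in minutes on one CPU.

Soma placement emulates the anisotropy seen in human CA1: a thick
pyramidal layer holding ~70% of somas with density rising towards the SR
border (default within-SP gradient 3:1), plus an antero-posterior ramp
(default 2:1). The generator renders somas as single dark pixels (mean
intensity 30 on background 200, optional Gaussian noise) at
20 × 20 × 20 µm³ voxel resolution, with a ground-truth table of rendered
pixel indices. What the fixture does **not** emulate: real staining
artifacts (uneven illumination, vascular/glial structures, touching
somas), anatomically faithful hippocampal curvature, and realistic
per-layer absolute densities. Passing tests therefore demonstrate the
correctness of the algorithms, not segmentation performance on real
histology.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `xy_resolution`, `z_resolution` | 20 | µm | soma-sized pixels justify one-soma-per-pixel |
| inhibitory ratio | 0.10 | – | conserved across species and regions |
| dendritic point volume | 64,000 | µm³ | one scatter point per 40 µm voxel |
| rodent→human scale | 1.5 | – | human PC dendrites ≈ 150% of mouse |
| tube radius | 150 (scaled) | µm | 300 µm diameter axonal cross-section |
| back-propagation cap | 500 | µm | maximum extension back towards CA2 |
| back-propagation gain `k_back` | 0.1 | – | typical back-projection ≈ 150 µm on the fixture |
| hull tolerance | 1e-9 × extent | µm | closed inclusion; boundary points kept |
| degree / length bin width | 10–100 / 100 | – / µm | configurable |
| hub threshold `k_sd` | 3 | SD | see the caveat below |

The per-class shape dimensions (`default_morphology_params()`) are
representative rodent-scale values assembled from the morphology
literature and public repositories, scaled by 1.5 and drawn per neuron
from truncated normal distributions (floor 0.2 × mean, so no dimension
can collapse to zero). They are configuration, not measurements: studies
with measured per-class tables should substitute their own. The mean
pyramidal apical cone (900 µm height, ~112 µm base radius after scaling)
has a volume of ≈ 1.178 × 10⁷ µm³ and therefore a budget of 184 dendritic
points.

The connection-probability table (`default_p_conn()`) is likewise a
documented example in the spirit of rodent CA1 compilations; its absolute
values control connectome size, not the shape of the degree
distributions, which is what the validation module examines.

## Design choices in detail

**Ellipsoid parametrization.** The canonical spherical parametrization
used for ellipsoid surfaces is
$(\lambda_1\cos\vartheta\sin\varphi,\ \lambda_2\sin\vartheta\sin\varphi,\
\lambda_3\cos\varphi)$. A variant in which both the first and second
coordinates carry $\cos\vartheta$ collapses the surface to a curve and is
not used. Volume filling uses exact uniform-ball sampling (normalized
Gaussian direction, radius $u^{1/3}$), so the sample covariance converges
to $U\,\mathrm{diag}(\lambda_i^2/5)\,U^T$ — the moment test in the suite.

**Cone sampling.** The lateral-surface form places points exactly at
radius $R\,h/H$; the solid fill uses the inverse-CDF construction
($h = H u^{1/3}$, in-disc radius $\sqrt{u}$), which is exact (no
rejection) and testable through the $3H/4$ centroid.

**Orientation planes.** Each neuron's transversal plane spans its
minimum-distance vectors to the CA2 and subiculum landmarks. On a
sheet-like geometry those two vectors are nearly antiparallel for somas
far from both ends, and their cross product degenerates into
nearest-vertex noise; below a sine threshold of 0.1 the plane normal
falls back to the cross product of the transversal direction and the
local surface normal (approximated by the direction to the nearest SO
vertex), with a warning. A tube whose plane still misses the SO surface
(somas right next to a landmark) is rebuilt once in that fallback plane.

**Tube construction.** SO-surface points within a 40 µm slab of the
transversal plane are binned at 25 µm along the transversal direction,
averaged into an ordered polyline, spline-resampled, and truncated at the
soma's arc position minus $\min(500, k_{back}\cdot d_{geo})$ where
$d_{geo}$ is the arc distance to the CA2 end. Somas at the subiculum end
keep at least one tube segment.

**Interneuron class assignment.** Class quotas are exact
(largest-remainder rounding of the configured proportions). Because OLM
and TRI may only draw from the SO-side soma subgroup and NGF, IVY, SCA
and PPA from the SR side, drawing the layer-unrestricted Perisomatic
class *first* would make exact quotas infeasible for almost every
realized side split. The implementation therefore draws the
side-restricted classes first and lets Perisomatic absorb the remainder
across the whole volume; a quota can then fail only against its side
subgroup itself, which is reported with both counts. The "outer part" of
a side subgroup is the configured proximity quantile (default 0.7),
extended to the quota-nearest somas when the quantile subset is smaller
than the quota. Default proportions (Perisomatic 0.22, OLM 0.07,
IVY 0.15, TRI 0.04, SCA 0.13, PPA 0.12, NGF 0.27) keep NGF the most
abundant class while staying feasible against the default density
profile's side split. SCA/PPA/NGF somas shift towards the SLM by
`gain · d(soma, SR border)` (gains 0.5/0.5/1.0 — only the ordering, NGF
largest, is anatomically constrained), capped at the SLM surface so
shifted somas stay inside the sheet.

**Otsu thresholding.** The threshold maximizes between-class variance
over all 255 cuts of the 256-bin histogram; ties resolve to the smallest
maximizer so the choice is deterministic. The SLM reference (a layer
known to be nearly soma-free) acts as a clamp: the threshold is lowered
until at most 1% of SLM reference pixels would be foreground. Contrast
enhancement before thresholding is the default and configurable.
A constant region yields a warning and an empty mask.

**Convex hulls.** The 3D hull is an incremental quickhull (compiled)
returning outward unit-normal facet planes; membership is a facet-plane
test with an absolute tolerance of 1e-9 times the hull extent. A strict
1e-9 µm tolerance would be below double-precision rounding at µm
coordinates of order 10³–10⁴ and would spuriously reject hull vertices;
the scaled tolerance keeps inclusion closed (boundary points are always
in). Collinear or coplanar inputs are rejected with an error.

**Density analysis.** The 300 µm voxel partition is a fixed-depth uniform
grid with half-open intervals, contract-equivalent to a recursive octree.
The antero-posterior statistic is
`(first four − last four) / last four × 100` by default; the direction is
configurable since either convention is defensible. The 13 repetitions
per profile position jitter voxel centres uniformly within ± half a voxel
and random transversal positions, seeded.

**Hub criterion.** Hubs are neurons with total degree above
`mean + 3·sd` (strict). One caveat is worth stating: for a *random*
network over $N$ neurons the degree distribution is close to binomial, so
the expected number of neurons above that threshold is ≈ 0.00135 · N —
about 7 at N = 5,000 — for any seed. An empty hub set in the random
baseline at `k_sd = 3` is therefore a rare event, and the meaningful
comparison is the *magnitude* of the hub count and the excess kurtosis of
the degree distribution, both of which the morphological network exceeds
by an order of magnitude in the shipped configuration (the acceptance
script recomputes both). Raising `k_sd` to 5–6 makes the baseline empty
in expectation while morphological hubs persist.

**KL divergence.** Computed as $-\sum_i p_i \log(q_i/p_i)$ in natural
log on per-bin probabilities, with additive $10^{-12}$ smoothing (and
renormalization) on Q so that support mismatches stay finite; histograms
are right-padded with empty bins to common edges before comparison.

**Determinism.** Every stochastic operation takes a seed; the pipeline
derives per-stage seeds from the master seed by a fixed affine scheme
(`stage_seed()`), and morphology generation derives per-neuron seeds so
that realized shape dimensions are identical across `size_scale`
settings. Two runs with the same configuration and seed are byte
identical.

## Problem sizes

The shipped tests and the acceptance script use: 10³–3×10⁴ somas for
segmentation, pruning and density statistics; 10⁵ sample points per shape
for the geometric exactness checks; a 200-neuron fixture for the
brute-force equivalence of the bounding-box prefilter; and a
5,000-neuron mini-scaffold (three morphology scales plus a random
baseline) for the topology comparisons. These sizes were chosen so the
full suite exercises every pipeline path in a few minutes on a single
CPU; all of them are arguments, not constants.

## Known limitations

* Geometric probability volumes are a deliberate simplification: no
  branching morphologies, no synapse placement on compartments, no
  conduction delays or weights.
* The convex hull of a whole curved tube bridges its concave side,
  slightly over-estimating the axonal reach of strongly bent PC axons;
  a piecewise-hull mode would tighten this and is a natural extension.
* Default morphology dimensions and connection probabilities are
  representative, not measured; absolute connectome sizes from the
  defaults should not be interpreted quantitatively.
* The fixture's density gradients are constructions for validating the
  gradient statistics, not measurements of human CA1.

```{r example, eval = FALSE}
# a complete desk-scale run
cfg <- default_pipeline_config()
cfg$n_total <- 1000L
res <- run_pipeline(cfg, "mini_ca1_run")
str(res$report)
```
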