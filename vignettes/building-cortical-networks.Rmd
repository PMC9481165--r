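---
title: "From quantitative anatomy to a sparse convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From quantitative anatomy to a sparse convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mvcnet` is a compiler from measured mouse-brain anatomy to a fully
specified convolutional network. This vignette explains the model, the
parameters that matter, the numerical decisions taken where the design
was genuinely open, and what the synthetic-data tests do and do not
establish.

## The model

A *region* is one cortical layer (L4, L2/3, L5) of one visual area. The
published configuration spans the thalamic relay dLGN, the primary
visual area VISp, five lateral higher areas (VISal, VISl, VISli, VISpl,
VISrl) arranged in parallel, and VISpor at the top of the hierarchy:
22 regions joined by 49 feedforward convolutional projections. Retinal
input enters dLGN, dLGN feeds VISp L4, laminar flow inside each area is
L4 &rarr; L2/3 &rarr; L5 (the canonical microcircuit feedforward path),
all three VISp layers fan out to the lateral L4s and to VISpor L4, and
all three layers of every lateral area converge on VISpor L4 (18 inbound
projections in total). There are no pooling layers in the trunk and no
feedback edges.

Each projection i &rarr; j is a convolution; a region applies one batch
normalization and a ReLU to the *sum* of its inbound convolution
outputs,

$$A^j = \mathrm{ReLU}\Big(\mathrm{BN}\big(\textstyle\sum_{i \in I^j}
C^{ij} * A^i\big)\Big).$$

The classifier head average-pools every area's L5 output to 4&times;4,
concatenates (16 &times; &Sigma; c^L5 = 2304 features in the published
configuration) and applies one linear map to the class logits, trained
with softmax cross-entropy.

### How anatomy fixes the meta-parameters

* **Grid sizes.** Mouse visual acuity of ~0.5 cycles/degree gives
  1 pixel/degree at Nyquist, and a ~60&times;90 degree coverage is
  simplified to a 64&times;64 input. dLGN and VISp keep the 64&times;64
  grid; every edge leaving VISp for another area has stride 2, so all
  later regions are 32&times;32.
* **Channels.** The excitatory census fixes channel counts:
  c = floor(n / (l_x l_y)), where n is the region's excitatory neuron
  count. The census itself is density &times; volume: laminar densities
  [neurons/mm^3] times the number of (10 um)^3 voxels in the region,
  rounded to the nearest integer. Areas without their own density
  measurements (VISrl, VISli, VISpor) use the four-area average per
  layer. Rounding conventions are load-bearing and validated against the
  printed tables: censuses *round* (VISal L4: 9704.6 &rarr; 9705),
  channels *floor* (VISpor L2/3: 29.86 &rarr; 29).
* **Kernels.** Connection density about a cortical point is modelled as
  a radial Gaussian P(r) = d_p exp(-r^2 / 2 d_w^2) with width d_w [um]
  and peak probability d_p. Widths convert to source-grid pixels via the
  pixel scale sigma_i = sqrt(l_x l_y / a_i) with a_i the area's flat-map
  surface area; the kernel spans one width each side of the center,
  k = 2 floor(sigma_i d_w) + 1. Padding p = (k - s)/2 is exact at
  stride 1 and rounded *up* at stride 2, the unique symmetric choice
  that keeps every 64-grid edge landing exactly on a 32 grid.
* **Interlaminar statistics.** The L4 &rarr; L4 width anchor is 114 um
  (mouse); relative widths between other layer pairs come from cat
  cortex and are scaled by 114/180. Peaks are recovered from measured
  pairwise connection probabilities at 75 um offset:
  d_p = d_75 / exp(-75^2 / 2 d_w^2).
* **Interareal statistics.** Estimated from a voxel-level connectome by
  the `flatmap` module (below). Peaks follow from an assumed extrinsic
  in-degree of e = 1000 inputs per neuron:
  e w_ij / &Sigma;_i w_ij = 2 pi (sigma_i d_w)^2 d_p c_i.
* **Subcortical kernels.** Receptive fields of ~9 degrees in dLGN and
  ~11 in VISp at 1 pixel/degree give a 9&times;9 input kernel and a
  3&times;3 dLGN &rarr; VISp4 kernel; these edges carry no Gaussian mask
  (no measured d_p/d_w exists for them; a config flag can add one).

### Sparsification by Gaussian masks

At initialization each masked edge samples a binary tensor
(c_out, c_in, k, k): element at spatial offset (u, v) is Bernoulli with
probability min(1, d_p exp(-(u^2+v^2)/2 (sigma_i d_w)^2)), independent
across channel pairs (the data constrain only the spatial profile;
independence is the maximum-entropy completion). Weights are multiplied
by the mask at initialization and re-masked after every optimizer step,
so masked weights are *exactly* zero at all times — a documented
contract, not a numerical aspiration. Two interareal peaks (VISal
L2/3 and L5 into VISpor L4) exceed 1 under the in-degree identity and
are capped at mask time, reproducing a known inconsistency of the
published parameter set (the VISal channel count is too small for the
other constraints).

## The flat-map pipeline

The interareal width/peak estimates come from a 100-um voxel connectome.
The voxel positions are fit by a least-squares sphere — the algebraic
linearization |x|^2 = 2c&middot;x + (r^2 - |c|^2), exact for noiseless
data, followed by Gauss–Newton refinement of the geometric residual —
and projected to 2D by an azimuth/elevation chart scaled by the radius.
Region surface areas are convex hulls of the projected positions.

Numerical choices worth knowing:

* **Units.** Everything is um; voxel-index inputs are multiplied by the
  100-um voxel size on ingest, which makes the voxel-size factor in the
  projection a pure unit conversion.
* **Chart distortion.** The chart stretches azimuthal arcs by
  1/cos(elevation): pairwise distances are good to ~2% within an
  11-degree cap and ~3.5% at 15 degrees. The generator confines regions
  to a single hemisphere-quadrant so the quadrant-naive arctan never
  bites; a `quadrant_aware` switch enables atan2.
* **Width estimator.** Per target voxel, the inbound width is the
  weighted *per-axis* standard deviation of source flat positions about
  their center of mass, sqrt(&Sigma; w d^2 / (2 &Sigma; w)). The factor
  2 converts the radial second moment (E[r^2] = 2 d_w^2 for an isotropic
  2D Gaussian) to the per-axis width that parameterizes P(r); without it
  the estimator overshoots a known-width synthetic profile by sqrt(2).
  The region-level width is the unweighted mean over target voxels and
  remains an upper bound on the neuron-level width, because a voxel
  pools neurons with partially overlapping input fields.
* **Unimodality filter.** Target voxels with multi-modal inbound
  profiles are excluded. No published criterion exists, so the package
  defines one: smooth the inbound weights over the source positions with
  a Gaussian of one voxel bandwidth, count local maxima above 10% of the
  field maximum within 1.5-voxel neighbourhoods (widened to 1.5 nearest-
  neighbour spacings on coarser grids); more than one maximum excludes
  the voxel. Bandwidth and threshold are config keys.

### The interareal profile stand-in

The published per-edge interareal aggregate weights live in a
supplementary table that is not redistributable and whose recomputation
from the real tract-tracing model is out of scope. The shipped
configuration therefore carries a **synthetic** stand-in, flagged
`synthetic-equal-weights` in the config and in each edge's provenance
field: kernel sizes come verbatim from the published meta-parameter
table (pixel widths take the midpoint of each kernel's preimage), and
peaks follow the in-degree identity with *equal* inbound weight
fractions per target. Consequences: the construction arithmetic, mask
machinery and both parameter-count identities are exact, but the
published "masked" parameter total (~87K) is not reproducible — the
stand-in lands at the same order (~60K) and the test suite asserts the
statistically checkable part (sampled nonzeros within 3 binomial
standard errors of the expected count), not the irreproducible bucket.

Two printed interlaminar kernel cells (VISli4 &rarr; VISli L2/3,
17&times;17; VISpl4 &rarr; VISpl L2/3, 19&times;19) disagree with the
width formula applied to the printed surface areas (15 and 17). The
dense conv parameter total printed alongside (2.1M) matches the
*formula* kernels (2,145,097) and not the printed cells (2,151,649
&rarr; 2.2M), so the generator follows the formula by default and ships
the as-published table as an explicit override (`kernels =
"published"`); the discrepancy is asserted by the tests rather than
hidden.

## Functional-comparison metrics

* **SSM.** Representation matrices (images &times; units) yield
  image-by-image Pearson similarity matrices; two representations are
  compared by the Spearman rank correlation of their flattened
  similarity matrices. Flattening uses the upper triangle *excluding*
  the diagonal: the diagonal is constant 1 in both matrices and would
  only dilute the rank correlation. Constant rows are recorded missing
  and excluded, never silently propagated as NaN.
* **Split-half reliability** of a neuron is the across-image correlation
  of trial-averaged responses between two disjoint halves of its trials,
  averaged over 10 random splits. For signal variance s^2 and i.i.d.
  trial noise n^2 at t trials it concentrates around
  s^2 / (s^2 + 2 n^2 / t).
* **Noise ceiling** is the SSM of a population with itself across
  disjoint trial halves, restricted to neurons above a reliability
  threshold; the best ceiling scans a threshold grid and breaks ties
  toward the lower threshold (more neurons).
* **Lifetime sparseness** S_L = (1 - (&Sigma;r)^2 / (N &Sigma;r^2)) /
  (1 - 1/N) and **circular selectivity** S_O = |&Sigma; r_k e^{2i
  theta_k}| / &Sigma; r_k (one minus circular variance; the doubled
  angle identifies opposite drift directions) are unit-level statistics;
  all-zero response profiles are recorded missing.
* **Jensen–Shannon distance** uses base-2 logs (so disjoint supports
  give exactly 1) on a shared 50-bin equal-width binning spanning the
  pooled range; the binning is configurable because no published value
  exists.
* **Layer-diversity layout** embeds the matrix of pairwise layer SSMs
  with classical metric MDS (`stats::cmdscale`) on distance 1 - SSM, and
  the diversity index is the product of singular values of the centered
  2D coordinates. Classical scaling is deterministic, so no MDS seed is
  needed (iterative SMACOF-style MDS would require one); diversity
  scales as alpha^2 under uniform distance scaling, and degenerate
  (identical or collinear) layouts give 0. Because the embedding
  dimension of the original analysis is ambiguous, printed diversity
  values are not acceptance surfaces.

## Synthetic data: what the generators state

All generators are pure functions of (spec, seed).

* **Voxel connectomes** place each region on a disjoint angular patch of
  a sphere (default radius 10 mm, 100-um pitch, matching the real
  model's resolution). The weight from source voxel l into target voxel
  k is peak &times; exp(-d_geo^2 / 2 sigma_true^2) + background, with
  d_geo the *geodesic* distance to k's mirror point in the source patch
  — geodesic on purpose, so the flat-map small-angle approximation is
  the thing under test. Source patches are made larger than their
  targets so no Gaussian center sits near a patch edge (edge truncation
  would bias the width estimate low, which would test the generator's
  truncation rather than the estimator). Default sigma_true = 200 um is
  of the order of the interareal widths in the published supplement.
* **Response tensors** default to 118 images &times; 50 trials,
  mirroring the natural-image protocol of the reference dataset; signal
  and noise variances dial the implied reliability through the closed
  form above. Rectification for calcium-like nonnegativity is available
  but off by default since it changes the closed form.
* **Stimuli** are sinusoidal gratings at the six static directions of
  the reference protocol, and 1/f-filtered Gaussian noise stands in for
  the (non-redistributable) 118 natural images — it matches only their
  second-order statistics.

A green test therefore establishes: the construction arithmetic on the
printed tables, exact mask/training contracts, estimator consistency
against known ground truth, and closed-form metric behaviour. It does
*not* establish anything about real tract-tracing data, real calcium
responses (no bursting, no rectified noise, no event extraction), or
task-trained representations at scale — ImageNet/CIFAR training runs and
all comparisons against recorded data are explicitly out of scope.

## Known limitations

* The runtime is base-R (im2col and shift-accumulate convolutions with a
  hand-written backward pass). It is exact — verified against a
  brute-force oracle and finite differences — but meant for desk-scale
  probing and toy training, not GPU-scale optimization.
* Gradient finite-difference checks are run on unmasked configurations:
  with batch normalization coupling every activation to every weight,
  ReLU kink crossings contaminate central differences at ~1e-4
  regardless of step size; the masked variant is covered by the exact
  mask-zero contract instead.
* Training-mode batch statistics make `train_step` loss comparisons
  approximate across steps; eval mode is bit-deterministic, and
  untrained-network analyses calibrate running statistics with one probe
  pass.
* Medial areas (VISpm, VISam), feedback and recurrence are outside the
  published configuration and outside this package's scope.
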