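---
title: "Deformation initialization for groupwise registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation initialization for groupwise registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Groupwise registration aligns a cohort of 3D images to a latent common
space without privileging any single reference image. When the cohort is
heterogeneous — several distinct anatomical sub-populations, large
inter-subject deformations — conventional groupwise algorithms converge
slowly or poorly, because every image starts far from the common space.
`groupinit` implements a *deformation initialization* front end: it first
removes the large, predictable part of the inter-subject variability so
that any downstream groupwise algorithm starts from a tight population.

The method is a two-stage pipeline:

1. **Clustering by graph coarsening.** The cohort is represented as a
   fully connected graph whose edge weights are pairwise normalized
   cross-correlations (NCC). Multi-level algebraic-multigrid (AMG) style
   coarsening designates a small set of *exemplar* images, one per
   homogeneous sub-population.
2. **Learned deformation prediction and mean-inverse warping.** A
   patch-based convolutional network per exemplar predicts the
   displacement field registering any image to that exemplar. Each image
   `i` with fields `u_ij` to the exemplars is warped by
   `ubar_i = ( mean_j u_ij^{-1} )^{-1}`, which moves it toward the
   barycenter of the exemplar geometry — the hidden common space — rather
   than toward any single template.

## Similarity graph and coarsening

NCC between two images is computed over the intersection of their
foreground masks (voxels with intensity > 0 when no mask is supplied,
appropriate for skull-stripped data); a flag allows the full field of
view. NCC is invariant to positive affine intensity rescaling, so the
graph is insensitive to global contrast differences; all images are
histogram-matched to the cohort's most central image first anyway.

A vertex `j` is a *strong connection* of `i` when
`|e_ij| >= rho * max_k |e_ik|`; the threshold is relative per vertex and
deliberately asymmetric. The default `rho = 0.95` counts edges within 95%
of a vertex's best similarity as strong; `rho = 1` keeps only the argmax
neighbour (many small clusters), while small `rho` merges everything (few
clusters). Desirability `psi_i` counts how many vertices have `i` among
their strong connections (in-degree): a good exemplar is an image that
many others resemble closely. The selection loop repeatedly promotes the
most desirable undesignated vertex to *coarse*, designates every
undesignated vertex strongly depending on it as *fine* (assigned to that
coarse vertex), then adjusts desirabilities (+1 to strong connections of
newly fine vertices, −1 to strong connections of the new coarse vertex;
values may go negative). Ties always break to the lowest vertex index,
which makes the whole hierarchy bit-for-bit reproducible.

Coarse vertices carry their original pairwise NCC values into the next
level (exemplars are always original images, never synthetic averages, so
no edge re-computation or Galerkin aggregation is needed). Two design
points deserve emphasis:

* **Direction of "strong with respect to".** The relative-threshold rule
  is asymmetric and the prose description of the selection loop admits two
  readings. We adopt the AMG convention: a coarse point is one that many
  fine points *depend on*, i.e. desirability is the in-degree under strong
  dependence, and `k` becomes fine when the new coarse vertex is one of
  `k`'s strong connections. The opposite (out-degree) reading would make
  an image desirable because *it* resembles many others, which selects
  near-duplicates rather than representatives.
* **Termination.** Because the strong-connection threshold is relative,
  any complete graph with at least two vertices keeps shrinking: at every
  level some vertex is the strong connection of another, so a literal
  "repeat until two consecutive graphs have equal size" never stabilizes
  above a single vertex. We therefore treat a level `>= 1` whose
  coarsening would fuse *all* surviving exemplars into one vertex as
  having reached stability: vertices at such levels are already cluster
  representatives whose mutual similarities are, by construction of the
  relative rule, within each other's strong range, and merging them would
  erase exactly the structure the hierarchy exists to expose. A collapse
  at level 0 is accepted as genuine homogeneity of the cohort (a
  single-cluster population should yield one exemplar). On a two-block
  graph this stops with one hub per block; on a uniform graph it yields a
  single exemplar.

## Displacement-field algebra

Fields are dense voxel-unit displacement vectors on the common grid, with
the pull-back convention `warped(x) = image(x + u(x))`; composition is
`(u then v)(x) = v(x) + u(x + v(x))`. All of the mean-inverse algebra is
grid-level, so fields are kept in voxel units and converted to/from world
mm only at I/O. Inversion uses the standard fixed-point iteration
`v_{k+1}(x) = -u(x + v_k(x))` (default 30 iterations, tolerance 0.01
voxel), which is contractive when the displacement gradient is below 1 —
comfortably true for the smooth fields generated or predicted here. On
that class the interior residual of `compose(u, invert(u))` stays below
0.1 voxel; nearest-edge extension makes the first and last few voxel
layers untrustworthy, so all accuracy statements are over the interior
(`interior_mask()`). The mean in the initialization formula is the plain
component-wise arithmetic mean of the inverse fields — the literal
reading of the formula, with no log-Euclidean lifting; with one template
the formula collapses to a double inversion (i.e. the input field up to
iteration tolerance), and with two opposite translations it vanishes,
both of which are asserted in the test suite.

## The prediction network

One network is associated with each exemplar template. The architecture
follows a U-Net pattern with the stated layer vocabulary: 3x3x3
convolutions (each followed by ReLU then batch normalization), 2x2x2 max
pooling down the contracting path, 2x2x2 transposed convolutions up the
expansive path, an extra 3x3x3 convolution bridging each skip connection,
and 1x1x1 heads emitting a 3-component displacement at the three finest
resolutions (deep supervision: the coarser heads regularize training and
force early layers to learn useful features; only the finest head is used
at inference). Channel counts and depth are configuration (`depth`
pooling levels, `base_channels` doubled per level) because the reference
description fixes the layer vocabulary but not the widths.

The network input is a *pair* of patches — the moving image and the
template, as two channels. With a single-channel input a convolutional
network is translation-equivariant and can only infer displacement from
memorized absolute template geometry; feeding the template patch
alongside makes the displacement locally observable (the network sees
both images and estimates their local offset, as in optical flow), which
is also how the patch-based registration networks this design descends
from are fed.

Patches: input `in_patch^3` (default 64^3) predicts the central
`out_patch^3` (default 24^3) field patch; the volume is padded
symmetrically to a multiple of `out_patch` plus the margin, output tiles
abut without overlap (step = `out_patch`), and input tiles overlap by
twice the margin. Assembling tiled ground truth and disassembling it
again is exact, which the tests assert.

**Dual-guidance loss.** `loss_u` compares predictions with a guidance
field (from any external registration tool, or the synthetic generator's
exact fields) at the three supervised resolutions; the guidance field is
average-pooled by 2 and 4 with displacement values divided by the same
factor, keeping units consistent per grid. `loss_SSD` is the mean squared
intensity difference between the template patch and the moving patch
warped by the finest prediction (differentiable through trilinear
interpolation). The total is the convex combination
`alpha * loss_u + beta * loss_SSD` with `alpha + beta = 1` at every
epoch; the default schedule takes `alpha` linearly from 1 (pure field
guidance, fast convergence) to 0 (pure image evidence, refinement) across
the epochs. Per-voxel *means* (not sums) are used in both terms so that
the balance between the two components does not depend on patch size or
resolution. The guidance term is the mean per-voxel Euclidean distance by
default, with a squared variant (`loss_u_squared = TRUE`). The squared
form matters in short training runs: the plain Euclidean distance has
unit-magnitude gradients regardless of the error size, so samples whose
true deformation is already near zero are pushed around as forcefully as
badly misregistered ones; the squared form weights each sample by its
actual error, which stabilizes the conditional prediction. The package's
scaled-down studies therefore use the squared guidance term together with
a half-decay schedule (`alpha` from 1 to 0.5), keeping field guidance
active across all of a short run; both choices are configuration, and the
defaults remain the linear 1-to-0 schedule with the plain Euclidean term.

Training runs ADAM (default learning rate 1e-2 for the central-template
network, 10 epochs) over all tiles of all training pairs, reshuffled per
epoch from the seed; everything — weight initialization, data order,
schedule — is deterministic given the configuration. Networks for the
remaining templates are transfer-trained: weights are cloned from the
central-template network and all of them fine-tuned at a very small rate
(default 1e-7); the base network is never modified. Although a transfer
pass at rate 1e-7 moves the weights by less than 1e-5, the pass is not a
no-op: it adapts the batch-normalization running statistics to the new
template's patch distribution, which measurably improves that template's
predictions — so even the reduced pipeline studies run one transfer
epoch per template (`transfer_epochs = 1`; `0` requests a bare weight
clone). The train/test split shuffles by seed and allocates
`round(0.75 * N)` images to training (69 non-template images -> 52/17).

## Synthetic cohorts

The generator emulates the situation the method targets: `K` latent
anatomy clusters with large systematic differences, plus smaller
individual variation, plus intensity noise. All images derive from one
*base anatomy* — nested ellipsoids (CSF shell / GM shell / WM core / a
small "hippocampus" blob) overlaid with a deterministic smooth
intra-tissue texture. The texture matters: real brain MR is rich in local
structure, and without it intensity gradients exist only at compartment
boundaries, so local displacement would be observable only along the
boundary normal (the aperture problem) and intensity-driven learning
would be ill-posed.

Each cluster prototype is the base anatomy warped by a *known* large
smooth deformation (an anisotropic scaling about the grid center, with a
cluster-specific axis pattern); each individual then adds a small smooth
field composed of a few shared population modes plus an image-specific
residual, mirroring the low-dimensional structure of anatomical
variability in real cohorts. The total generating field of every image —
cluster deformation composed with the individual field — is returned, so
exact ground-truth correspondences exist for *every* pair of images,
across clusters included: the field registering image i onto image j is
`compose(invert(F_i), F_j)`. This is what the oracle registration backend
and the endpoint-error evaluations use.

Defaults — 12 images, 3 clusters, 48^3 voxels, individual displacement up
to 3 voxels at Gaussian scale 6 (4 modes, residual fraction 0.25), noise
sd 0.02 confined to the head region (backgrounds stay exactly zero, as in
skull-stripped data) — are chosen so that within-cluster NCC (>= ~0.93)
cleanly exceeds cross-cluster NCC (<= ~0.86) and generated fields satisfy
the inversion precondition; both properties are asserted in the test
suite. Images and labels are geometrically consistent by construction
(labels are warped with the image's own total field, nearest-neighbour),
and every artifact is a deterministic function of the seed.

What passing tests on these phantoms do *not* show: robustness to MR
artifacts (bias fields, ghosting), to affine misalignment (inputs are
assumed affinely pre-registered), to multi-modal contrast, or to anatomy
whose variability is not well described by smooth diffeomorphic-ish
displacement of a prototype.

## Evaluation

Alignment of a (warped) cohort is scored exactly as the reference
evaluation protocol prescribes: NCC of every image against the voxelwise
group mean; Dice overlap (in percent) and robust Hausdorff distance of
every image's segmentation against a majority-vote reference (per-voxel
modal label, ties to the lowest label). Surface points are centers of
structure voxels with a 6-connected neighbour of a different label (grid
edges count as boundary), scaled to mm. The robust Hausdorff takes the
maximum of the two directed 95th percentiles, with linear interpolation
between order statistics; the percentile is a parameter (`1` recovers the
classical Hausdorff distance). Both Dice and the Hausdorff distance are
checked exactly against brute-force reference implementations on random
label volumes.

## Scaled-down study sizes

All empirical checks in the package run at desk scale, with sizes chosen
once as part of the study design: the clustering study uses the default
12-image 3-cluster 48^3 cohort; field-algebra residual checks use 20
seeded 48^3 fields of amplitude <= 3 voxels; the learning study registers
20 training / 5 held-out images of a 26-image 3-cluster 32^3 cohort to a
single cohort template, using 24^3 -> 16^3 patches and a
`base_channels = 8`, depth-2 network for 5 epochs with the squared
guidance term and half-decay schedule; the template-selection comparison
runs the full pipeline on the default cohort with a 32^3 -> 24^3 variant
of the same reduced network (2 epochs, transfer by weight cloning). The
methods themselves are size-agnostic; the defaults in `regnet_config()`
describe the full-scale geometry (64^3 -> 24^3 patches, 3 levels, 16 base
channels, 10 epochs).

What the learning study does and does not show: at this scale the network
reliably captures the *systematic*, cluster-level component of the
subject-to-template deformations — the large structured differences the
initialization framework exists to remove — while the small
image-specific residual fields are only partially predicted. Images whose
true deformation to the template is large (cross-cluster pairs) see their
endpoint error cut by well over half; images already close to the
template benefit little. A few hundred CPU optimizer steps on twenty
volumes cannot be expected to match what full-scale training (tens of
thousands of steps on dozens of full-resolution brains) achieves on the
individual component; the tests and the acceptance computations report
the reduction actually attained.

## Known limitations

* The AMG stopping rule is a design decision (see above); other readings
  of the stopping rule are conceivable but unstable on complete
  similarity graphs.
* Inversion assumes contractive fields; strongly folded fields are
  flagged via the `converged` attribute rather than repaired.
* The network is a CPU implementation intended for moderate volumes and
  desk-scale studies; it is faithful to the architecture contract, not a
  performance-parity reimplementation of a GPU training pipeline.
* Batch normalization uses per-patch statistics during training (batch
  size one) and running statistics at inference.
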