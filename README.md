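# groupinit

Deformation initialization for groupwise registration of heterogeneous 3D
image cohorts.

## The problem

Groupwise registration aligns a population of images to a latent common
space without picking a biased reference. On heterogeneous cohorts (for
example several age groups in one brain-MRI study) conventional groupwise
algorithms start far from the common space and converge slowly or
inaccurately. `groupinit` removes the large, systematic part of the
inter-subject variability first, so that any downstream groupwise method
starts from a tight population:

1. **Image clustering by multi-level graph coarsening.** The cohort is a
   fully connected graph with normalized cross-correlation (NCC) edge
   weights
   `e_ij = sum((I_i - mean(I_i)) (I_j - mean(I_j))) / sqrt(sum((I_i - mean(I_i))^2) sum((I_j - mean(I_j))^2))`.
   An algebraic-multigrid-style selection designates *coarse* vertices
   (cluster exemplars): vertex `j` is a *strong connection* of `i` when
   `|e_ij| >= rho * max_k |e_ik|` (default `rho = 0.95`), desirability
   counts how many vertices strongly depend on a candidate, and the most
   desirable vertex absorbs its strong dependents as *fine*. Levels repeat
   on the coarse vertices until the hierarchy is stable; top-level coarse
   vertices are the exemplar templates.
2. **Learned deformation prediction and mean-inverse warping.** A
   patch-based 3D U-Net-style network per exemplar (trained with a
   dual-guidance loss: distance to ground-truth fields plus intensity
   mismatch after warping, `loss = alpha * loss_u + beta * loss_SSD`,
   `alpha + beta = 1` per epoch, deep supervision at three resolutions)
   predicts the displacement field `u_ij` from any image `i` to exemplar
   `j`. Each image is then warped by the inverse of the mean of its
   inverse fields,
   `ubar_i = ( (1/N) sum_j u_ij^{-1} )^{-1}`,
   which moves it toward the barycenter of the exemplars — the hidden
   common space — rather than toward any single template.

Alignment is evaluated by NCC against the group mean, Dice overlap (%) and
95th-percentile Hausdorff distance (mm) against majority-vote reference
segmentations.

The package includes a seeded synthetic phantom generator (multi-
compartment textured "brain-like" volumes in latent shape clusters, with
exact ground-truth deformation fields), so every part of the method runs,
and is tested, without any external data.

## A worked example

```r
library(groupinit)

# a 12-image cohort in 3 latent shape clusters on a 48^3 grid
cohort <- make_cohort(phantom_cohort_spec(seed = 1))

# cluster the cohort and pick exemplar templates
graph <- build_graph(cohort$images)
coarse <- coarsen_multilevel(graph, rho = 0.95)
coarse
#> <coarsening_result> 2 levels, rho = 0.95, 3 exemplar(s): img01, img02, img03

# warp every image toward the common space using exact ground-truth fields
init <- initialize_cohort(cohort$images, oracle_backend(cohort$true_fields),
                          coarse$exemplar_ids, labels = cohort$labels)

# alignment before and after
ncc_to_mean(cohort$images)$mean
#> [1] 0.9542237
ncc_to_mean(init$warped)$mean
#> [1] 0.9994797
```

The NCC of each image to the cohort mean rises from about 0.954 to about
0.999: the mean-inverse initialization collapses most of the inter-subject
variability before any groupwise refinement is run. `run_pipeline()` wires
the same stages together end to end (histogram matching, graph building,
template selection by coarsening / random / single-template modes,
network training with transfer learning, initialization, evaluation), and
`evaluate_cohort()` produces the per-structure Dice / HD95 / NCC report.

A thin command-line wrapper over these functions is provided at
`inst/cli/groupinit.R` (verbs `synth`, `graph`, `cluster`, `evaluate`,
`run`).

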