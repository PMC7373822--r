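# Synthetic phantom cohorts: smooth 3D multi-compartment "brain-like"
# volumes falling into K latent shape clusters. All images derive from one
# textured base anatomy: each cluster is a known large anisotropic-scaling
# deformation of the base, and each individual adds a small smooth random
# field (a combination of shared population modes plus a residual). The
# total generating field of every image is therefore known exactly, so
# ground-truth subject-to-subject deformations exist for ALL pairs —
# including across clusters — and clustering, network training,
# initialization and evaluation all run without external data.

#' Specification of a synthetic phantom cohort
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 12 images in 3 shape clusters on a 48^3 grid,
#' individual smooth deformations of up to 3 voxels (Gaussian scale 6,
#' keeping the displacement gradient well below 1 so fields stay
#' invertible), and mild additive intensity noise (sd 0.02 on a unit
#' intensity range, confined to the head region as in skull-stripped
#' inputs).
#'
#' @param n_images cohort size (>= n_clusters).
#' @param n_clusters number of latent shape clusters K; clusters are known
#'   large smooth deformations (anisotropic scalings) of a common base
#'   anatomy, so cross-cluster correspondences are exact.
#' @param shape grid dimensions (length 3).
#' @param deform_amplitude maximum individual displacement norm in voxels;
#'   must stay below `min(shape)/4` so fields remain invertible with a
#'   meaningful interior margin.
#' @param deform_smoothness Gaussian scale of the individual fields (voxels).
#' @param n_deform_modes number of shared smooth population deformation
#'   modes; each individual field is a random combination of these plus a
#'   residual. Anatomical variability in real cohorts is low-dimensional
#'   (a few dominant modes), and that structure is part of what makes
#'   deformation prediction from appearance well-posed.
#' @param deform_residual fraction of the individual amplitude carried by
#'   the image-specific residual field (0 = purely modal, 1 = unstructured).
#' @param noise_sigma sd of additive Gaussian intensity noise.
#' @param seed integer master seed; everything the generator emits is a
#'   deterministic function of it.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_cohort_spec <- function(n_images = 12, n_clusters = 3,
                                shape = c(48, 48, 48),
                                deform_amplitude = 3, deform_smoothness = 6,
                                n_deform_modes = 4, deform_residual = 0.25,
                                noise_sigma = 0.02, seed = 1) {
  stop_if(n_clusters < 1 || n_images < n_clusters,
          "need n_images >= n_clusters >= 1")
  stop_if(length(shape) != 3 || any(shape < 8), "shape must be 3 dims >= 8")
  stop_if(deform_amplitude < 0, "deform_amplitude must be >= 0")
  stop_if(deform_amplitude >= min(shape) / 4,
          "deform_amplitude must be < min(shape)/4")
  stop_if(n_deform_modes < 0 || deform_residual < 0 || deform_residual > 1,
          "need n_deform_modes >= 0 and deform_residual in [0, 1]")
  structure(list(n_images = as.integer(n_images),
                 n_clusters = as.integer(n_clusters),
                 shape = as.integer(shape),
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 n_deform_modes = as.integer(n_deform_modes),
                 deform_residual = deform_residual,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Seeded smooth random displacement field
#'
#' Gaussian-filtered white-noise components, rescaled so the maximum vector
#' norm equals `amplitude` exactly (zero field if `amplitude` is 0).
#' Smoothing bounds the displacement gradient by roughly
#' `amplitude / smoothness`, so the default phantom settings (3 voxels over
#' a 6-voxel scale) satisfy the contraction precondition of
#' [invert_field()].
#'
#' @param shape grid dimensions.
#' @param amplitude maximum displacement norm (voxels).
#' @param smoothness Gaussian sigma (voxels).
#' @param seed integer seed.
#' @return a [disp_field()].
#' @export
random_smooth_field <- function(shape, amplitude, smoothness, seed) {
  stop_if(amplitude < 0, "amplitude must be >= 0")
  shape <- as.integer(shape)
  if (amplitude == 0) return(zero_field(shape))
  comps <- with_seed(seed, {
    lapply(1:3, function(c_) array(rnorm(prod(shape)), dim = shape))
  })
  comps <- lapply(comps, gaussian_smooth3, sigma = smoothness)
  v <- array(0, dim = c(shape, 3))
  for (c_ in 1:3) v[, , , c_] <- comps[[c_]]
  nrm <- sqrt(rowSums(matrix(v, ncol = 3)^2))
  v <- v * (amplitude / max(nrm))
  disp_field(v)
}

ellipsoid_inside <- function(shape, center, semi) {
  gc_ <- grid_coords(shape)
  q <- ((gc_[, 1] - center[1]) / semi[1])^2 +
    ((gc_[, 2] - center[2]) / semi[2])^2 +
    ((gc_[, 3] - center[3]) / semi[3])^2
  array(q <= 1, dim = shape)
}

# per-cluster anisotropic scaling coefficients of the cluster deformation
# u(x) = d * (x - center): clusters differ by which axis is elongated,
# which separates them cleanly in NCC while keeping the displacement
# gradient small (|d| <= 0.22, far inside the invertibility regime)
cluster_scale_coeffs <- function(k) {
  base <- list(c(-0.24, 0.20, 0.05), c(0.20, -0.24, 0.05), c(0.04, 0.04, -0.20))
  d <- base[[((k - 1) %% 3) + 1]]
  extra <- (k - 1) %/% 3
  if (extra > 0) d <- d + 0.05 * extra * c(1, -1, 0.5)
  d
}

# known large cluster deformation: pure anisotropic scaling about the
# grid center (negative coefficients expand the anatomy along that axis)
cluster_deformation <- function(cluster_index, shape) {
  center <- (shape + 1) / 2
  d <- cluster_scale_coeffs(cluster_index)
  gc_ <- grid_coords(shape)
  v <- array(0, dim = c(shape, 3))
  for (c_ in 1:3) v[, , , c_] <- array((gc_[, c_] - center[c_]) * d[c_], dim = shape)
  disp_field(v)
}

#' Base anatomy shared by all clusters
#'
#' Nested ellipsoids — an outer CSF shell (label 1, intensity 0.25), a GM
#' shell (label 2, 0.6), a WM core (label 3, 0.95) and a small interior
#' blob standing in for the hippocampus (label 4, 0.75) — overlaid with a
#' deterministic smooth intra-tissue texture. The texture emulates the
#' appearance richness of real anatomy: without it, intensity gradients
#' exist only at compartment boundaries and local displacement is
#' observable only along the boundary normal. The intensity image is
#' lightly smoothed and thresholded so the background is exactly zero, as
#' in skull-stripped data; labels follow the crisp geometry.
#'
#' @param spec a [phantom_cohort_spec()].
#' @return list with elements `volume` ([volume()]) and `labels`
#'   ([label_volume()]).
#' @export
make_base_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  center <- (shape + 1) / 2
  outer_semi <- c(1.05, 0.95, 1.0) * (shape / 2 - 7)
  gm_semi <- outer_semi * 0.82
  wm_semi <- outer_semi * 0.58
  hip_center <- center + c(0.30, 0.12, -0.10) * wm_semi
  hip_semi <- pmax(shape / 16, 2.2)
  in_outer <- ellipsoid_inside(shape, center, outer_semi)
  in_gm <- ellipsoid_inside(shape, center, gm_semi)
  in_wm <- ellipsoid_inside(shape, center, wm_semi)
  in_hip <- ellipsoid_inside(shape, hip_center, hip_semi) & in_wm
  labels <- array(0L, dim = shape)
  labels[in_outer] <- 1L
  labels[in_gm] <- 2L
  labels[in_wm] <- 3L
  labels[in_hip] <- 4L
  intens <- c(0, 0.25, 0.6, 0.95, 0.75)[labels + 1L]
  img <- gaussian_smooth3(array(intens, dim = shape), sigma = 0.8)
  tex <- with_seed((spec$seed * 50021L + 97L) %% 2147483647L,
                   array(rnorm(prod(shape)), dim = shape))
  tex <- gaussian_smooth3(tex, sigma = 2)
  tex <- tex / max(abs(tex))
  img <- img * (1 + 0.35 * tex)
  img[img < 5e-3] <- 0
  list(volume = volume(img),
       labels = label_volume(labels,
                             label_names = c(`1` = "csf", `2` = "gm",
                                             `3` = "wm", `4` = "hippocampus")))
}

#' Deterministic cluster prototype phantom
#'
#' The shared base anatomy ([make_base_anatomy()]) warped by the cluster's
#' known anisotropic-scaling deformation. Prototypes of different clusters
#' therefore differ by known large smooth fields, and their pairwise NCC is
#' strictly lower than the within-cluster NCC at the spec's individual
#' deformation amplitude.
#'
#' @param cluster_index 1-based cluster index, `<= spec$n_clusters`.
#' @param spec a [phantom_cohort_spec()].
#' @return list with elements `volume`, `labels` and `field` (the cluster
#'   deformation, a [disp_field()]).
#' @export
make_prototype <- function(cluster_index, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  stop_if(cluster_index < 1 || cluster_index > spec$n_clusters,
          "cluster_index out of range")
  base <- make_base_anatomy(spec)
  D <- cluster_deformation(cluster_index, spec$shape)
  list(volume = warp(base$volume, D), labels = warp(base$labels, D), field = D)
}

# individual deformation: random combination of shared population modes
# plus an image-specific residual, rescaled to the spec amplitude
individual_field <- function(spec, i) {
  if (spec$deform_amplitude == 0) return(zero_field(spec$shape))
  v <- spec$deform_residual *
    random_smooth_field(spec$shape, 1, spec$deform_smoothness,
                        seed = (spec$seed * 10007L + i) %% 2147483647L)$vectors
  if (spec$n_deform_modes > 0) {
    coefs <- with_seed((spec$seed * 40031L + i) %% 2147483647L,
                       rnorm(spec$n_deform_modes))
    for (m in seq_len(spec$n_deform_modes)) {
      mode <- random_smooth_field(spec$shape, 1, spec$deform_smoothness,
                                  seed = (spec$seed * 30013L + m) %% 2147483647L)
      v <- v + (1 - spec$deform_residual) * coefs[m] * mode$vectors /
        sqrt(spec$n_deform_modes)
    }
  }
  if (max(abs(v)) == 0) return(zero_field(spec$shape))
  nrm <- sqrt(rowSums(matrix(v, ncol = 3)^2))
  disp_field(v * (spec$deform_amplitude / max(nrm)))
}

#' Generate a seeded synthetic cohort with known structure
#'
#' Images are assigned to clusters round-robin. Image `i` of cluster `k`
#' is the base anatomy warped by the total field
#' `F_i = compose(D_k, f_i)` — the cluster deformation followed by the
#' individual field — with labels warped by the same field
#' (nearest-neighbour) and Gaussian intensity noise added inside the head
#' region. The total fields are returned, so ground truth exists for every
#' subject-to-subject registration (`compose(invert(F_i), F_j)`), and
#' oracle backends and endpoint-error evaluation are exact for all pairs.
#'
#' @param spec a [phantom_cohort_spec()].
#' @return an object of class `"phantom_cohort"`: named lists `images`,
#'   `labels`, `true_fields` (total fields from the base anatomy) plus
#'   `true_clusters` (named integer vector), `base`, `prototypes` and
#'   `spec`. Ids are `img01`, `img02`, ...
#' @export
make_cohort <- function(spec = phantom_cohort_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  base <- make_base_anatomy(spec)
  ids <- sprintf("img%02d", seq_len(spec$n_images))
  clusters <- ((seq_len(spec$n_images) - 1L) %% spec$n_clusters) + 1L
  names(clusters) <- ids
  cluster_fields <- lapply(seq_len(spec$n_clusters), cluster_deformation,
                           shape = spec$shape)
  prototypes <- lapply(seq_len(spec$n_clusters), function(k) {
    list(volume = warp(base$volume, cluster_fields[[k]]),
         labels = warp(base$labels, cluster_fields[[k]]),
         field = cluster_fields[[k]])
  })
  images <- list(); labels <- list(); fields <- list()
  for (i in seq_len(spec$n_images)) {
    k <- clusters[i]
    f <- compose_fields(cluster_fields[[k]], individual_field(spec, i))
    img <- warp(base$volume, f)
    lab <- warp(base$labels, f)
    if (spec$noise_sigma > 0) {
      noise <- with_seed((spec$seed * 20011L + i) %% 2147483647L,
                         array(rnorm(prod(spec$shape), sd = spec$noise_sigma),
                               dim = spec$shape))
      d <- img$data
      head_region <- d > 0
      d[head_region] <- pmax(d[head_region] + noise[head_region], 0)
      img <- volume(d, spacing = img$spacing, origin = img$origin)
    }
    images[[ids[i]]] <- img
    labels[[ids[i]]] <- lab
    fields[[ids[i]]] <- f
  }
  structure(list(images = images, labels = labels, true_fields = fields,
                 true_clusters = clusters, base = base,
                 prototypes = prototypes, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d images, %d clusters, grid %s, amplitude %g vox\n",
              x$spec$n_images, x$spec$n_clusters,
              paste(x$spec$shape, collapse = "x"), x$spec$deform_amplitude))
  invisible(x)
}

#' Write a phantom cohort to disk in standard formats
#'
#' NIfTI volumes/labels/fields plus a JSON manifest recording ids, true
#' clusters and the generating spec.
#'
#' @param cohort a `"phantom_cohort"`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$images)) {
    write_volume(cohort$images[[id]], file.path(dir, paste0(id, ".nii.gz")))
    write_labels(cohort$labels[[id]], file.path(dir, paste0(id, "_labels.nii.gz")))
    write_field(cohort$true_fields[[id]], file.path(dir, paste0(id, "_field.nii.gz")))
  }
  jsonlite::write_json(
    list(ids = names(cohort$images),
         true_clusters = as.list(cohort$true_clusters),
         spec = unclass(cohort$spec)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
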