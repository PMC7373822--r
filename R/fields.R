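# Displacement-field algebra. All fields live on a single common grid in
# voxel units; warping is pull-back, output(x) = input(x + u(x)), with
# trilinear (images) or nearest-neighbour (labels) interpolation and
# nearest-edge extension outside the grid.

#' Warp a volume or label volume by a displacement field
#'
#' `output(x) = input(x + u(x))`. A zero field returns the input exactly
#' (no interpolation blur). Label volumes are warped with nearest-neighbour
#' interpolation, so only labels present in the input can appear.
#'
#' @param v a [volume()] or [label_volume()].
#' @param u a [disp_field()] on the same grid.
#' @param interpolation `"linear"` (default for volumes) or `"nearest"`
#'   (forced for label volumes).
#' @return a warped object of the same class as `v`.
#' @export
warp <- function(v, u, interpolation = c("linear", "nearest")) {
  stopifnot(inherits(u, "dispfield"))
  interpolation <- match.arg(interpolation)
  is_labels <- inherits(v, "labelvol")
  if (is_labels) interpolation <- "nearest"
  arr <- if (is_labels) v$labels else v$data
  stop_if(!identical(dim(arr), as.integer(u$reference_shape)) &&
            !identical(as.integer(dim(arr)), as.integer(u$reference_shape)),
          "warp: volume and field shapes differ")
  uv <- matrix(u$vectors, ncol = 3)
  if (all(uv == 0)) return(v)
  pts <- grid_coords(dim(arr)) + uv
  out <- if (interpolation == "linear") sample_trilinear(arr, pts) else sample_nearest(arr, pts)
  out <- array(out, dim = dim(arr))
  if (is_labels) {
    label_volume(out, spacing = v$spacing, origin = v$origin,
                 label_names = v$label_names)
  } else {
    volume(out, spacing = v$spacing, origin = v$origin)
  }
}

#' Compose two displacement fields
#'
#' `compose(u, v)(x) = v(x) + u(x + v(x))`: warping by `u` and then by `v`
#' equals warping once by `compose(u, v)`. `u` is sampled with trilinear
#' interpolation and nearest-edge extension.
#'
#' @param u,v [disp_field()] objects on one grid.
#' @return a [disp_field()].
#' @export
compose_fields <- function(u, v) {
  stopifnot(inherits(u, "dispfield"), inherits(v, "dispfield"))
  stop_if(!identical(u$reference_shape, v$reference_shape),
          "compose: reference shapes differ")
  shp <- u$reference_shape
  vv <- matrix(v$vectors, ncol = 3)
  pts <- grid_coords(shp) + vv
  out <- vv
  for (c_ in 1:3) {
    out[, c_] <- out[, c_] + sample_trilinear(array(u$vectors[, , , c_], dim = shp), pts)
  }
  disp_field(array(out, dim = c(shp, 3)))
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v = u^-1` via `v_{k+1}(x) = -u(x + v_k(x))`, starting from
#' `v_0 = 0`, stopping when the maximum update falls below `tol` voxels or
#' after `max_iter` iterations. The iteration is contractive when the
#' displacement gradient of `u` is below 1 (smooth fields of moderate
#' amplitude); within that class the interior residual of
#' `compose_fields(u, invert_field(u))` stays below 0.1 voxel.
#'
#' @param u a [disp_field()].
#' @param max_iter maximum iterations (default 30).
#' @param tol convergence tolerance in voxels (default 0.01).
#' @return a [disp_field()] with attribute `"converged"` (logical) and
#'   `"iterations"`.
#' @export
invert_field <- function(u, max_iter = 30, tol = 0.01) {
  stopifnot(inherits(u, "dispfield"))
  shp <- u$reference_shape
  gc_ <- grid_coords(shp)
  comp <- lapply(1:3, function(c_) array(u$vectors[, , , c_], dim = shp))
  v <- matrix(0, nrow = nrow(gc_), ncol = 3)
  converged <- FALSE
  iters <- 0L
  if (max(abs(u$vectors)) == 0) {
    out <- zero_field(shp)
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    return(out)
  }
  for (it in seq_len(max_iter)) {
    pts <- gc_ + v
    vn <- -cbind(sample_trilinear(comp[[1]], pts),
                 sample_trilinear(comp[[2]], pts),
                 sample_trilinear(comp[[3]], pts))
    delta <- max(abs(vn - v))
    v <- vn
    iters <- it
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("invert_field: fixed-point iteration did not converge within ",
            max_iter, " iterations (last update ", signif(delta, 3), " voxels)")
  }
  out <- disp_field(array(v, dim = c(shp, 3)))
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iters
  out
}

#' Set of deformation fields from one image to several templates
#'
#' @param image_id id of the moving image.
#' @param fields_by_template named list of [disp_field()] objects, one per
#'   template id, all on one grid.
#' @return an object of class `"fieldset"`.
#' @export
field_set <- function(image_id, fields_by_template) {
  stop_if(length(fields_by_template) < 1, "fieldset needs at least one template entry")
  stop_if(is.null(names(fields_by_template)) || any(names(fields_by_template) == ""),
          "fields_by_template must be named by template id")
  shapes <- lapply(fields_by_template, function(f) f$reference_shape)
  stop_if(length(unique(shapes)) != 1, "all fields must share one reference shape")
  structure(list(image_id = image_id, fields_by_template = fields_by_template),
            class = "fieldset")
}

#' Mean-inverse deformation of an image with respect to its templates
#'
#' Given the fields `u_ij` registering image i to each template j, the
#' initialization field is the inverse of the arithmetic mean of the
#' inverse fields:
#' \deqn{\bar u_i = \Big(\frac{1}{N}\sum_j u_{ij}^{-1}\Big)^{-1}.}
#' Each field is inverted, the inverses are averaged component-wise, and
#' the average is inverted again. With a single template this reduces to
#' the input field (double inversion); with two opposite translations it
#' vanishes.
#'
#' @param fs a [field_set()].
#' @param max_iter,tol passed to [invert_field()].
#' @return a [disp_field()]; attribute `"converged"` is the conjunction of
#'   all inversion convergence flags.
#' @export
mean_inverse_init <- function(fs, max_iter = 30, tol = 0.01) {
  stopifnot(inherits(fs, "fieldset"))
  shp <- fs$fields_by_template[[1]]$reference_shape
  acc <- array(0, dim = c(shp, 3))
  ok <- TRUE
  for (f in fs$fields_by_template) {
    fi <- invert_field(f, max_iter = max_iter, tol = tol)
    ok <- ok && isTRUE(attr(fi, "converged"))
    acc <- acc + fi$vectors
  }
  acc <- acc / length(fs$fields_by_template)
  ubar <- invert_field(disp_field(acc), max_iter = max_iter, tol = tol)
  converged <- ok && isTRUE(attr(ubar, "converged"))
  attr(ubar, "converged") <- converged
  ubar
}

#' Warp a cohort toward the common space via mean-inverse initialization
#'
#' For each image, queries the registration backend for the displacement
#' field to every exemplar, combines them with [mean_inverse_init()], and
#' warps the image (and its labels, when given) by the result.
#'
#' The backend is pluggable: a `function(image_id, template_id)` returning
#' a [disp_field()]. It may wrap a trained network (see
#' [regnet_backend()]), ground-truth fields from a synthetic cohort (see
#' [oracle_backend()]), or fields loaded from disk.
#'
#' @param images named list of [volume()] objects (ids = names).
#' @param predict backend `function(image_id, template_id) -> dispfield`.
#' @param exemplar_ids character vector of template ids.
#' @param labels optional named list of [label_volume()] objects.
#' @param max_iter,tol inversion parameters.
#' @return list with `warped` (named list of volumes), `warped_labels`
#'   (or NULL), `fields` (named list of [field_set()]), `init_fields`
#'   (named list of the per-image mean-inverse fields).
#' @export
initialize_cohort <- function(images, predict, exemplar_ids, labels = NULL,
                              max_iter = 30, tol = 0.01) {
  stop_if(is.null(names(images)), "images must be a named list")
  stop_if(length(exemplar_ids) < 1, "need at least one exemplar")
  warped <- list()
  warped_labels <- if (is.null(labels)) NULL else list()
  fieldsets <- list()
  init_fields <- list()
  for (id in names(images)) {
    fbt <- lapply(exemplar_ids, function(j) {
      f <- tryCatch(predict(id, j),
                    error = function(e) stop("registration backend failed for (",
                                             id, ", ", j, "): ", conditionMessage(e),
                                             call. = FALSE))
      stopifnot(inherits(f, "dispfield"))
      f
    })
    names(fbt) <- exemplar_ids
    fs <- field_set(id, fbt)
    ubar <- mean_inverse_init(fs, max_iter = max_iter, tol = tol)
    warped[[id]] <- warp(images[[id]], ubar)
    if (!is.null(labels) && !is.null(labels[[id]])) {
      warped_labels[[id]] <- warp(labels[[id]], ubar)
    }
    fieldsets[[id]] <- fs
    init_fields[[id]] <- ubar
  }
  list(warped = warped, warped_labels = warped_labels,
       fields = fieldsets, init_fields = init_fields)
}

#' Ground-truth registration backend for synthetic cohorts
#'
#' Builds the exact subject-to-template field from the generating fields of
#' a synthetic cohort: if image i arose from the base anatomy by the total
#' field `F_i` (pull-back), the field registering image i onto image j is
#' `compose(invert(F_i), F_j)`. Because every cohort image derives from
#' one base anatomy, this ground truth is exact for all pairs, including
#' across clusters.
#'
#' @param true_fields named list of the cohort's generating
#'   [disp_field()]s.
#' @param max_iter,tol inversion parameters.
#' @return a `function(image_id, template_id)` suitable for
#'   [initialize_cohort()].
#' @export
oracle_backend <- function(true_fields, max_iter = 30, tol = 0.01) {
  inv_cache <- new.env(parent = emptyenv())
  function(image_id, template_id) {
    stop_if(is.null(true_fields[[image_id]]), "no true field for ", image_id)
    stop_if(is.null(true_fields[[template_id]]), "no true field for ", template_id)
    if (is.null(inv_cache[[image_id]])) {
      inv_cache[[image_id]] <- invert_field(true_fields[[image_id]],
                                            max_iter = max_iter, tol = tol)
    }
    compose_fields(inv_cache[[image_id]], true_fields[[template_id]])
  }
}
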