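#' 3D scalar volume
#'
#' A scalar image on a regular 3D grid. Intensities are arbitrary units;
#' `spacing` is the per-axis voxel size in mm and `origin` the world
#' position (mm) of voxel (1,1,1). An optional logical `mask` of the same
#' shape marks the region of interest (e.g. the brain in a skull-stripped
#' scan). When no mask is given, downstream similarity computations default
#' to the voxels with intensity > 0.
#'
#' @param data numeric 3D array with finite values.
#' @param spacing numeric length-3, positive voxel sizes (mm).
#' @param origin numeric length-3 world coordinates of the first voxel (mm).
#' @param mask optional logical array, same shape as `data`.
#' @return an object of class `"vol3d"`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0), mask = NULL) {
  data <- as_grid3(data)
  stop_if(any(!is.finite(data)), "volume data must be finite")
  stop_if(length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0),
          "spacing must be 3 positive finite values")
  stop_if(length(origin) != 3 || any(!is.finite(origin)), "origin must be 3 finite values")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(data))
    stop_if(anyNA(mask), "mask must be logical without NAs")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mask = mask),
            class = "vol3d")
}

# Coerce to a 3D array, accepting arrays with trailing singleton dims.
as_grid3 <- function(x) {
  x <- unclass(x)
  attr(x, "pixdim") <- NULL
  attr(x, ".nifti_image_ptr") <- NULL
  d <- dim(x)
  stop_if(is.null(d), "expected an array")
  nontriv <- d[d > 1L]
  stop_if(length(d) < 3 && length(nontriv) > length(d), "expected 3 dimensions")
  if (length(d) > 3) {
    stop_if(any(d[-(1:3)] != 1L), "expected 3 non-singleton dimensions")
    x <- array(as.numeric(x), dim = d[1:3])
  } else if (length(d) < 3) {
    stop("expected 3 spatial dimensions, got ", length(d), call. = FALSE)
  } else {
    x <- array(as.numeric(x), dim = d)
  }
  x
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing (%s) mm, intensity [%.3g, %.3g]%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = ", "),
              min(x$data), max(x$data),
              if (is.null(x$mask)) "" else sprintf(", mask %d voxels", sum(x$mask))))
  invisible(x)
}

#' 3D label volume
#'
#' Integer-labelled segmentation on a regular grid. Label 0 is reserved for
#' background; positive labels index structures (e.g. CSF/GM/WM,
#' hippocampus). `label_names` optionally maps label values to names.
#'
#' @param labels integer 3D array, values >= 0.
#' @param spacing,origin as in [volume()].
#' @param label_names optional named character vector or list; names are
#'   label values, elements structure names.
#' @return an object of class `"labelvol"`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         label_names = NULL) {
  labels <- as_grid3(labels)
  stop_if(any(!is.finite(labels)), "labels must be finite")
  stop_if(any(labels < 0) || any(labels != round(labels)),
          "labels must be non-negative integers")
  stop_if(length(spacing) != 3 || any(spacing <= 0), "spacing must be 3 positive values")
  structure(list(labels = array(as.integer(round(labels)), dim = dim(labels)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 label_names = label_names),
            class = "labelvol")
}

#' @export
print.labelvol <- function(x, ...) {
  lv <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<labelvol> %s voxels, labels {%s}\n",
              paste(dim(x$labels), collapse = "x"),
              paste(lv, collapse = ", ")))
  invisible(x)
}

#' Dense displacement field
#'
#' Per-voxel displacement 3-vectors in voxel units along the grid axes,
#' stored as a 4D array whose trailing dimension has length 3. A warped
#' image reads intensities at `x + u(x)` (pull-back convention): the field
#' lives on the grid of the warp's output. Conversion to world mm happens
#' only at I/O, never inside the field algebra.
#'
#' @param vectors numeric 4D array `c(shape, 3)` with finite values.
#' @return an object of class `"dispfield"` with elements `vectors` and
#'   `reference_shape`.
#' @export
disp_field <- function(vectors) {
  d <- dim(vectors)
  stop_if(is.null(d) || length(d) != 4 || d[4] != 3,
          "displacement field must be a 4D array with trailing dimension 3")
  stop_if(any(!is.finite(vectors)), "displacement components must be finite")
  structure(list(vectors = array(as.numeric(vectors), dim = d),
                 reference_shape = d[1:3]),
            class = "dispfield")
}

#' Zero displacement field on a grid
#' @param shape integer length-3 grid dimensions.
#' @return a `"dispfield"` of zeros.
#' @export
zero_field <- function(shape) {
  disp_field(array(0, dim = c(shape, 3)))
}

#' @export
print.dispfield <- function(x, ...) {
  nrm <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat(sprintf("<dispfield> %s grid, |u| max %.3g mean %.3g voxels\n",
              paste(x$reference_shape, collapse = "x"), max(nrm), mean(nrm)))
  invisible(x)
}

#' Default mask of a volume
#'
#' The explicit mask when present, otherwise all voxels with intensity > 0
#' (appropriate for skull-stripped or background-zero images).
#' @param v a [volume()].
#' @return logical array.
#' @export
default_mask <- function(v) {
  stopifnot(inherits(v, "vol3d"))
  v$mask %||% (v$data > 0)
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_geometry <- function(img) {
  pd <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  list(spacing = as.numeric(abs(pd)), origin = as.numeric(xf[1:3, 4]))
}

write_nifti_grid <- function(arr, spacing, origin, path, datatype = "double") {
  img <- RNifti::asNifti(arr)
  m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii`/`.nii.gz` file with 3 non-singleton
#'   spatial dimensions.
#' @return a [volume()]. No resampling is performed; spacing and origin are
#'   taken from the header.
#' @export
read_volume <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  arr <- as_grid3(as.array(img))
  stop_if(any(!is.finite(arr)), "non-finite voxels in ", path)
  volume(arr, spacing = geo$spacing, origin = geo$origin)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' The data array round-trips exactly (stored as float64); spacing and
#' origin are encoded in the qform.
#' @param v a [volume()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "vol3d"))
  write_nifti_grid(v$data, v$spacing, v$origin, path)
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  arr <- as_grid3(as.array(img))
  stop_if(any(arr != round(arr)), "label file contains non-integer values: ", path)
  sidecar <- paste0(path, ".labels.json")
  nm <- NULL
  if (file.exists(sidecar)) nm <- unlist(jsonlite::read_json(sidecar))
  label_volume(arr, spacing = geo$spacing, origin = geo$origin, label_names = nm)
}

#' @rdname write_volume
#' @param l a [label_volume()]; names, when present, go to a JSON sidecar.
#' @export
write_labels <- function(l, path) {
  stopifnot(inherits(l, "labelvol"))
  write_nifti_grid(l$labels, l$spacing, l$origin, path, datatype = "int32")
  if (!is.null(l$label_names)) {
    jsonlite::write_json(as.list(l$label_names), paste0(path, ".labels.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read/write displacement fields as NIfTI vector volumes
#'
#' Fields are stored as 4D NIfTI images whose trailing dimension has
#' length 3; components are voxel-unit displacements along the grid axes
#' in array order. Round trips are exact (float64 storage).
#'
#' @param path file path.
#' @return `read_field` returns a [disp_field()].
#' @export
read_field <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 5 && d[4] == 1L) {  # NIfTI vector-intent layout
    arr <- array(arr, dim = d[c(1:3, 5)])
    d <- dim(arr)
  }
  stop_if(length(d) != 4 || d[4] != 3,
          "expected a 4D NIfTI with trailing vector dimension 3, got dims ",
          paste(d, collapse = "x"))
  disp_field(arr)
}

#' @rdname read_field
#' @param f a [disp_field()].
#' @export
write_field <- function(f, path) {
  stopifnot(inherits(f, "dispfield"))
  img <- RNifti::asNifti(f$vectors, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- Histogram matching ----------------------------------------------------

#' Match the intensity histogram of one volume to another
#'
#' Monotone quantile mapping: intensities of `moving` are remapped so that
#' its quantile function approximates the reference's, using `n_levels`
#' evenly spaced quantiles with linear interpolation in between. The
#' mapping is non-decreasing, so intensity order is preserved.
#'
#' @param moving,reference [volume()] objects; both must be non-constant.
#' @param n_levels number of quantile anchors (default 256).
#' @return a [volume()] with the moving image's grid and the reference's
#'   approximate histogram.
#' @export
histogram_match <- function(moving, reference, n_levels = 256) {
  stopifnot(inherits(moving, "vol3d"), inherits(reference, "vol3d"))
  mv <- as.vector(moving$data)
  rv <- as.vector(reference$data)
  stop_if(sd(mv) == 0 || sd(rv) == 0,
          "histogram matching is undefined for constant-intensity images")
  probs <- seq(0, 1, length.out = n_levels)
  qm <- quantile(mv, probs, names = FALSE, type = 7)
  qr <- quantile(rv, probs, names = FALSE, type = 7)
  # collapse duplicated moving quantiles, keeping the mapping monotone
  keep <- !duplicated(qm)
  qm_u <- qm[keep]
  qr_u <- cummax(qr[keep])
  out <- if (length(qm_u) < 2) {
    rep(mean(qr), length(mv))
  } else {
    approx(qm_u, qr_u, xout = mv, rule = 2, ties = "ordered")$y
  }
  volume(array(out, dim = dim(moving$data)), spacing = moving$spacing,
         origin = moving$origin, mask = moving$mask)
}
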