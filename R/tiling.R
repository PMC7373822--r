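# Patch geometry: overlapping input patches of edge `in_patch` predict
# disjoint output field patches of edge `out_patch` that tile the volume
# with step `out_patch`. The volume is padded (symmetric reflection) up to
# a multiple of the output patch plus an input margin on every side.

# symmetric (edge-inclusive) padding; applied in steps so pads larger than
# the current extent are still valid
pad_sym3 <- function(arr, lo, hi) {
  for (ax in 1:3) {
    while (lo[ax] > 0 || hi[ax] > 0) {
      d <- dim(arr)[ax]
      l <- min(lo[ax], d)
      h <- min(hi[ax], d)
      idx <- c(rev(seq_len(l)), seq_len(d), d - seq_len(h) + 1L)
      arr <- switch(ax,
                    arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
      lo[ax] <- lo[ax] - l
      hi[ax] <- hi[ax] - h
    }
  }
  arr
}

#' Tiling of a volume into network patches
#'
#' Pads each dimension up to the next multiple of `out_patch`, then by a
#' further margin of `(in_patch - out_patch)/2` on every side (symmetric
#' reflection). Output tiles are disjoint and cover the padded core
#' exactly (`ceiling(dim / out_patch)` tiles per dimension); input tiles
#' overlap by twice the margin.
#'
#' @param shape integer length-3 grid dimensions.
#' @param cfg a [regnet_config()] (only `in_patch`/`out_patch` are used).
#' @return an object of class `"patch_tiling"`: data frame `tiles` with
#'   1-based input and output corner indices in the padded grid, plus
#'   `shape`, `core_shape`, `padded_shape`, `margin`, `in_patch`,
#'   `out_patch`.
#' @export
make_tiling <- function(shape, cfg) {
  shape <- as.integer(shape)
  stop_if(length(shape) != 3 || any(shape < 1), "shape must be 3 positive dims")
  outp <- cfg$out_patch
  inp <- cfg$in_patch
  margin <- (inp - outp) %/% 2L
  nt <- as.integer(ceiling(shape / outp))
  core <- nt * outp
  padded <- core + 2L * margin
  g <- expand.grid(tx = seq_len(nt[1]), ty = seq_len(nt[2]), tz = seq_len(nt[3]))
  out_corner <- cbind(margin + (g$tx - 1L) * outp + 1L,
                      margin + (g$ty - 1L) * outp + 1L,
                      margin + (g$tz - 1L) * outp + 1L)
  in_corner <- out_corner - margin
  structure(list(tiles = data.frame(in_x = in_corner[, 1], in_y = in_corner[, 2],
                                    in_z = in_corner[, 3], out_x = out_corner[, 1],
                                    out_y = out_corner[, 2], out_z = out_corner[, 3]),
                 shape = shape, core_shape = core, padded_shape = padded,
                 margin = margin, in_patch = inp, out_patch = outp),
            class = "patch_tiling")
}

#' @export
print.patch_tiling <- function(x, ...) {
  cat(sprintf("<patch_tiling> %s -> %d tiles of %d^3 -> %d^3, margin %d\n",
              paste(x$shape, collapse = "x"), nrow(x$tiles), x$in_patch,
              x$out_patch, x$margin))
  invisible(x)
}

# pad a 3D array according to a tiling (margin + round-up padding)
pad_to_tiling <- function(arr, tiling) {
  lo <- rep(tiling$margin, 3)
  hi <- tiling$margin + (tiling$core_shape - tiling$shape)
  pad_sym3(arr, lo, hi)
}

extract_block <- function(arr, corner, size) {
  arr[corner[1]:(corner[1] + size - 1L),
      corner[2]:(corner[2] + size - 1L),
      corner[3]:(corner[3] + size - 1L), drop = FALSE]
}

#' Stitch predicted field patches back into a full-size field
#'
#' Places the disjoint output tiles into the padded core grid and crops to
#' the original shape. Tiling a field into ground-truth patches and
#' reassembling is the identity on the unpadded region.
#'
#' @param tile_outputs list of numeric arrays `c(out_patch^3, 3)` (or
#'   matrices `out_patch^3 x 3`), one per row of `tiling$tiles`, in order.
#' @param tiling a `"patch_tiling"`.
#' @return a [disp_field()] of the tiling's original shape.
#' @export
assemble_field <- function(tile_outputs, tiling) {
  stopifnot(inherits(tiling, "patch_tiling"))
  nt <- nrow(tiling$tiles)
  stop_if(length(tile_outputs) != nt,
          "expected ", nt, " tiles, got ", length(tile_outputs))
  outp <- tiling$out_patch
  core <- tiling$core_shape
  acc <- array(0, dim = c(core, 3))
  for (t in seq_len(nt)) {
    to <- tile_outputs[[t]]
    if (is.matrix(to)) to <- array(to, dim = c(outp, outp, outp, 3))
    stop_if(!identical(dim(to), as.integer(c(outp, outp, outp, 3))),
            "tile ", t, " has wrong shape")
    cx <- tiling$tiles$out_x[t] - tiling$margin
    cy <- tiling$tiles$out_y[t] - tiling$margin
    cz <- tiling$tiles$out_z[t] - tiling$margin
    acc[cx:(cx + outp - 1L), cy:(cy + outp - 1L), cz:(cz + outp - 1L), ] <- to
  }
  shp <- tiling$shape
  disp_field(acc[seq_len(shp[1]), seq_len(shp[2]), seq_len(shp[3]), , drop = FALSE])
}

# voxel-major group ids for factor-f average pooling of a cubic patch
pool_groups <- function(dims, f) {
  gc_ <- grid_coords(dims)
  gx <- ceiling(gc_[, 1] / f)
  gy <- ceiling(gc_[, 2] / f)
  gz <- ceiling(gc_[, 3] / f)
  o <- dims %/% f
  gx + o[1] * (gy - 1L) + o[1] * o[2] * (gz - 1L)
}

# average-pool a voxel-major field matrix (n x 3) by factor f and rescale
# the displacement values to the coarser grid's voxel units
downsample_field_patch <- function(mat, dims, f) {
  g <- pool_groups(dims, f)
  rowsum(mat, g, reorder = TRUE) / (f^3) / f
}
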