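# Cohort alignment evaluation: voxelwise group mean, NCC of each image to
# the mean, majority-vote reference segmentations, Dice overlap (percent)
# and robust (95th percentile) Hausdorff surface distance in mm.

#' Voxelwise group mean of a cohort
#' @param volumes list of [volume()] objects on one grid.
#' @return a [volume()].
#' @export
group_mean <- function(volumes) {
  stop_if(length(volumes) < 1, "need at least one volume")
  shp <- dim(volumes[[1]]$data)
  acc <- array(0, dim = shp)
  for (v in volumes) {
    stop_if(!identical(dim(v$data), shp), "grid mismatch in group_mean")
    acc <- acc + v$data
  }
  volume(acc / length(volumes), spacing = volumes[[1]]$spacing,
         origin = volumes[[1]]$origin)
}

#' NCC of every cohort image against the group mean
#'
#' @param volumes list (>= 2) of [volume()] objects on one grid.
#' @param mask optional mask passed to [ncc()]; default `TRUE` (full grid)
#'   because the group mean has no natural foreground mask.
#' @return list with `scores` (named numeric), `mean`, `sd`.
#' @export
ncc_to_mean <- function(volumes, mask = TRUE) {
  stop_if(length(volumes) < 2, "need at least two volumes")
  gm <- group_mean(volumes)
  scores <- vapply(volumes, function(v) ncc(v, gm, mask = mask), 0)
  names(scores) <- names(volumes) %||% sprintf("img%d", seq_along(volumes))
  list(scores = scores, mean = mean(scores), sd = sd(scores))
}

#' Majority-vote fusion of label volumes
#'
#' Per-voxel modal label across the cohort; ties break to the lowest label
#' value.
#'
#' @param label_volumes list of [label_volume()] objects on one grid.
#' @return a [label_volume()].
#' @export
majority_vote <- function(label_volumes) {
  stop_if(length(label_volumes) < 1, "need at least one label volume")
  shp <- dim(label_volumes[[1]]$labels)
  all_labels <- sort(unique(unlist(lapply(label_volumes,
                                          function(l) unique(as.vector(l$labels))))))
  counts <- matrix(0L, nrow = prod(shp), ncol = length(all_labels))
  for (l in label_volumes) {
    stop_if(!identical(dim(l$labels), shp), "grid mismatch in majority_vote")
    idx <- match(as.vector(l$labels), all_labels)
    counts[cbind(seq_len(prod(shp)), idx)] <- counts[cbind(seq_len(prod(shp)), idx)] + 1L
  }
  # max.col("first") on the ascending label order implements ties -> lowest
  win <- all_labels[max.col(counts, ties.method = "first")]
  label_volume(array(win, dim = shp), spacing = label_volumes[[1]]$spacing,
               origin = label_volumes[[1]]$origin,
               label_names = label_volumes[[1]]$label_names)
}

#' Dice overlap of one label between two segmentations
#'
#' `D = 2 |V1 n V2| / (|V1| + |V2|)`, reported in percent. Symmetric in its
#' arguments; errors if the label is absent from both.
#'
#' @param a,b [label_volume()] objects on one grid.
#' @param label the label value to compare.
#' @return Dice ratio in \[0, 100\].
#' @export
dice <- function(a, b, label) {
  stopifnot(inherits(a, "labelvol"), inherits(b, "labelvol"))
  stop_if(!identical(dim(a$labels), dim(b$labels)), "grid mismatch in dice")
  va <- a$labels == label
  vb <- b$labels == label
  n1 <- sum(va); n2 <- sum(vb)
  stop_if(n1 + n2 == 0, "label ", label, " absent from both volumes")
  200 * sum(va & vb) / (n1 + n2)
}

#' Boundary points of a labelled structure
#'
#' Centers (in mm, voxel index minus 1 times spacing plus origin) of voxels
#' carrying `label` that have at least one face-adjacent (6-connectivity)
#' voxel of a different label, or lie on the grid edge.
#'
#' @param l a [label_volume()].
#' @param label label value.
#' @return numeric matrix, one row per surface point (x, y, z in mm).
#' @export
surface_points <- function(l, label) {
  stopifnot(inherits(l, "labelvol"))
  m <- l$labels == label
  stop_if(!any(m), "label ", label, " absent")
  d <- dim(m)
  boundary <- array(FALSE, dim = d)
  # grid edges count as boundary
  boundary[c(1, d[1]), , ] <- TRUE
  boundary[, c(1, d[2]), ] <- TRUE
  boundary[, , c(1, d[3])] <- TRUE
  if (d[1] >= 2) {
    lo <- 1:(d[1] - 1); hi <- 2:d[1]
    diff1 <- m[lo, , , drop = FALSE] != m[hi, , , drop = FALSE]
    boundary[lo, , ] <- boundary[lo, , , drop = FALSE] | diff1
    boundary[hi, , ] <- boundary[hi, , , drop = FALSE] | diff1
  }
  if (d[2] >= 2) {
    lo <- 1:(d[2] - 1); hi <- 2:d[2]
    diff2 <- m[, lo, , drop = FALSE] != m[, hi, , drop = FALSE]
    boundary[, lo, ] <- boundary[, lo, , drop = FALSE] | diff2
    boundary[, hi, ] <- boundary[, hi, , drop = FALSE] | diff2
  }
  if (d[3] >= 2) {
    lo <- 1:(d[3] - 1); hi <- 2:d[3]
    diff3 <- m[, , lo, drop = FALSE] != m[, , hi, drop = FALSE]
    boundary[, , lo] <- boundary[, , lo, drop = FALSE] | diff3
    boundary[, , hi] <- boundary[, , hi, drop = FALSE] | diff3
  }
  sel <- m & boundary
  ijk <- which(sel, arr.ind = TRUE)
  sweep(sweep(ijk - 1, 2, l$spacing, `*`), 2, l$origin, `+`)
}

# min distance from each row of A to the point set B (compiled kernel)
min_dists <- function(A, B) {
  cn_min_dists(as.matrix(A), as.matrix(B))
}

# robust Hausdorff on precomputed surface point sets
hd_points <- function(R, S, percentile) {
  max(quantile(min_dists(R, S), percentile, names = FALSE, type = 7),
      quantile(min_dists(S, R), percentile, names = FALSE, type = 7))
}

#' Robust (percentile) Hausdorff distance between two segmentations
#'
#' Extracts the boundary point sets of `label` in both volumes
#' ([surface_points()]), computes the two directed nearest-neighbour
#' distance sets, and returns the maximum of their `percentile` quantiles
#' (linear interpolation between order statistics). The default 95th
#' percentile is less outlier-sensitive than the classical maximum;
#' `percentile = 1` recovers the full Hausdorff distance.
#'
#' @param r_labels,s_labels [label_volume()] objects on one grid.
#' @param label label value present in both.
#' @param percentile quantile in (0, 1], default 0.95.
#' @return distance in mm (0 for identical segmentations).
#' @export
hd95 <- function(r_labels, s_labels, label, percentile = 0.95) {
  stopifnot(inherits(r_labels, "labelvol"), inherits(s_labels, "labelvol"))
  stop_if(!identical(dim(r_labels$labels), dim(s_labels$labels)),
          "grid mismatch in hd95")
  hd_points(surface_points(r_labels, label), surface_points(s_labels, label),
            percentile)
}

#' Evaluate the alignment of a (warped) cohort
#'
#' Builds the majority-vote reference segmentation, then scores every image
#' against it with Dice (percent) and robust Hausdorff distance (mm) per
#' structure, and every intensity image against the group mean with NCC.
#' The "overall" summary pools Dice/HD values across structures.
#'
#' @param volumes named list of [volume()] objects.
#' @param labels named list of [label_volume()] objects (same ids).
#' @param structures named integer vector mapping structure name -> label
#'   value, e.g. `c(csf = 1, gm = 2, wm = 3, hippocampus = 4)`.
#' @param percentile Hausdorff percentile (default 0.95).
#' @return an object of class `"eval_report"`: data frame `per_image`
#'   (image, structure, dice, hd95), `ncc` (per-image NCC to group mean),
#'   `summary` (mean/sd rows per structure and overall), and the reference
#'   [label_volume()].
#' @export
evaluate_cohort <- function(volumes, labels, structures, percentile = 0.95) {
  stop_if(length(volumes) < 2, "need at least two images")
  stop_if(!identical(sort(names(volumes)), sort(names(labels))),
          "volumes and labels must share ids")
  ref <- majority_vote(labels[names(volumes)])
  nccs <- ncc_to_mean(volumes)
  ref_surfaces <- lapply(structures, function(lab) surface_points(ref, lab))
  rows <- list()
  for (id in names(volumes)) {
    for (s in names(structures)) {
      lab <- structures[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        image = id, structure = s,
        dice = dice(labels[[id]], ref, lab),
        hd95 = hd_points(ref_surfaces[[s]], surface_points(labels[[id]], lab),
                         percentile))
    }
  }
  per_image <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(structures), function(s) {
    d <- per_image[per_image$structure == s, ]
    data.frame(structure = s, dice_mean = mean(d$dice), dice_sd = sd(d$dice),
               hd95_mean = mean(d$hd95), hd95_sd = sd(d$hd95))
  }))
  summ <- rbind(summ, data.frame(structure = "overall",
                                 dice_mean = mean(per_image$dice),
                                 dice_sd = sd(per_image$dice),
                                 hd95_mean = mean(per_image$hd95),
                                 hd95_sd = sd(per_image$hd95)))
  structure(list(per_image = per_image, ncc = nccs, summary = summ,
                 reference = ref),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d images, NCC to mean %.4f +/- %.4f\n",
              length(x$ncc$scores), x$ncc$mean, x$ncc$sd))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report to CSV + JSON
#' @param report an `"eval_report"`.
#' @param csv_path per-image CSV destination.
#' @param json_path optional JSON summary destination.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(ncc = as.list(report$ncc$scores),
                              ncc_mean = report$ncc$mean, ncc_sd = report$ncc$sd,
                              summary = report$summary),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
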