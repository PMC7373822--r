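# Image-similarity graphs: pairwise NCC edge weights, the fully connected
# cohort graph, and central-template selection.

#' Normalized cross-correlation between two volumes
#'
#' NCC over a common voxel mask:
#' `sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))`.
#' Means and sums run over the masked voxels only. By default the mask is
#' the intersection of the two volumes' masks (see [default_mask()]); pass
#' `mask = TRUE` to use the full field of view.
#'
#' NCC is invariant under positive affine intensity rescaling of either
#' argument and lies in \[-1, 1\].
#'
#' @param a,b [volume()] objects (or bare 3D arrays) of identical shape.
#' @param mask optional logical array (same shape), or `TRUE` for all voxels.
#' @return a scalar in \[-1, 1\].
#' @export
ncc <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "vol3d")) a else volume(a)
  bv <- if (inherits(b, "vol3d")) b else volume(b)
  stop_if(!identical(dim(av$data), dim(bv$data)), "ncc: volumes differ in shape")
  m <- if (isTRUE(mask)) {
    array(TRUE, dim = dim(av$data))
  } else if (is.null(mask)) {
    default_mask(av) & default_mask(bv)
  } else {
    stop_if(!identical(dim(mask), dim(av$data)), "ncc: mask shape mismatch")
    mask
  }
  x <- av$data[m]
  y <- bv$data[m]
  stop_if(length(x) < 2, "ncc: fewer than 2 masked voxels")
  x <- x - mean(x)
  y <- y - mean(y)
  den <- sqrt(sum(x^2) * sum(y^2))
  stop_if(den == 0, "ncc: constant image over the mask (zero denominator)")
  max(-1, min(1, sum(x * y) / den))
}

#' Build the fully connected similarity graph of an image cohort
#'
#' Every unordered pair of images gets one edge, weighted by `metric`
#' (default [ncc()]); the weight matrix is exactly symmetric because each
#' pair is computed once. The diagonal is `NA` and ignored by all
#' consumers.
#'
#' @param images list of [volume()] objects, all of one shape, length >= 2.
#' @param vertex_ids character ids, one per image (defaults to list names
#'   or `img1..imgN`).
#' @param metric function of two volumes returning a scalar similarity.
#' @param level coarsening level the graph lives at (bookkeeping, default 0).
#' @return an object of class `"simgraph"`: list(vertex_ids, weights, level).
#' @export
build_graph <- function(images, vertex_ids = NULL, metric = ncc, level = 0L) {
  n <- length(images)
  stop_if(n < 2, "build_graph needs at least 2 images")
  shapes <- vapply(images, function(v) paste(dim(v$data), collapse = "x"), "")
  stop_if(length(unique(shapes)) != 1, "all images must share one shape")
  vertex_ids <- vertex_ids %||% names(images) %||% sprintf("img%d", seq_len(n))
  stop_if(length(vertex_ids) != n || anyDuplicated(vertex_ids) > 0,
          "vertex_ids must be unique, one per image")
  w <- matrix(NA_real_, n, n, dimnames = list(vertex_ids, vertex_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e <- metric(images[[i]], images[[j]])
      w[i, j] <- e
      w[j, i] <- e
    }
  }
  similarity_graph(vertex_ids, w, level)
}

#' Construct a similarity graph from an explicit weight matrix
#' @param vertex_ids character vertex identifiers.
#' @param weights symmetric numeric matrix in \[-1, 1\]; diagonal ignored.
#' @param level coarsening level (default 0).
#' @return a `"simgraph"` object.
#' @export
similarity_graph <- function(vertex_ids, weights, level = 0L) {
  n <- length(vertex_ids)
  stop_if(!is.matrix(weights) || nrow(weights) != n || ncol(weights) != n,
          "weights must be an n x n matrix")
  off <- weights[row(weights) != col(weights)]
  stop_if(any(!is.finite(off)), "off-diagonal weights must be finite")
  stop_if(any(abs(off) > 1 + 1e-12), "similarities must lie in [-1, 1]")
  stop_if(!isTRUE(all.equal(weights[row(weights) != col(weights)],
                            t(weights)[row(weights) != col(weights)],
                            tolerance = 0)),
          "weight matrix must be exactly symmetric off the diagonal")
  diag(weights) <- NA_real_
  dimnames(weights) <- list(vertex_ids, vertex_ids)
  structure(list(vertex_ids = as.character(vertex_ids), weights = weights,
                 level = as.integer(level)),
            class = "simgraph")
}

#' @export
print.simgraph <- function(x, ...) {
  off <- x$weights[row(x$weights) != col(x$weights)]
  cat(sprintf("<simgraph> level %d, %d vertices, edge weights [%.3f, %.3f]\n",
              x$level, length(x$vertex_ids), min(off), max(off)))
  invisible(x)
}

#' Select the template most similar to all other candidates
#'
#' Among `candidate_ids`, returns the one maximizing the sum of similarity
#' to all *other* candidates (self-similarity excluded). Ties break to the
#' candidate earliest in the graph's vertex order.
#'
#' @param graph a `"simgraph"`.
#' @param candidate_ids subset of vertex ids (default: all).
#' @return a single vertex id.
#' @export
select_central_template <- function(graph, candidate_ids = graph$vertex_ids) {
  stopifnot(inherits(graph, "simgraph"))
  stop_if(length(candidate_ids) == 0, "empty candidate set")
  idx <- match(candidate_ids, graph$vertex_ids)
  stop_if(anyNA(idx), "candidate ids not in graph")
  idx <- sort(idx)  # vertex order decides ties
  if (length(idx) == 1) return(graph$vertex_ids[idx])
  sub <- graph$weights[idx, idx, drop = FALSE]
  sums <- rowSums(sub, na.rm = TRUE)  # diagonal is NA == self excluded
  graph$vertex_ids[idx[which.max(sums)]]
}

#' Export / import a similarity graph as a TSV edge list
#'
#' The edge list holds one row per unordered pair (`i`, `j`, `weight`); a
#' JSON manifest alongside records the vertex order and level.
#'
#' @param graph a `"simgraph"`.
#' @param path TSV path; the manifest goes to `paste0(path, ".json")`.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "simgraph"))
  n <- length(graph$vertex_ids)
  rows <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    j <- (i + 1):n
    data.frame(i = graph$vertex_ids[i], j = graph$vertex_ids[j],
               weight = graph$weights[i, j])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(vertex_ids = graph$vertex_ids, level = graph$level),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- as.character(man$vertex_ids)
  w <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  ii <- match(as.character(tab$i), ids)
  jj <- match(as.character(tab$j), ids)
  w[cbind(ii, jj)] <- tab$weight
  w[cbind(jj, ii)] <- tab$weight
  similarity_graph(ids, w, level = man$level %||% 0L)
}
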