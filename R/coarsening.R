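# Multi-level AMG-style coarsening of the image-similarity graph.
#
# A vertex j is a *strong connection* of vertex i when |e_ij| is within a
# factor rho of i's largest absolute edge weight. Desirability psi_i counts
# how many vertices strongly depend on i (in-degree under strong
# dependence); the most desirable vertex becomes coarse and absorbs, as
# fine, every undesignated vertex that strongly depends on it.
# Coarse vertices of one level form the next level's graph, with edge
# weights inherited from the original similarity matrix (exemplars are
# always original images, never averages).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Strong connections of a vertex
#'
#' The set of vertices j (j != i) with `|e_ij| >= rho * max_k |e_ik|`.
#' Never empty for `rho <= 1` on graphs with >= 2 vertices; a single-vertex
#' graph yields the empty set.
#'
#' @param graph a `"simgraph"`.
#' @param i vertex id or 1-based index.
#' @param rho strong-connection threshold in (0, 1]; default 0.95, i.e.
#'   edges above 95% of the maximum similarity count as strong.
#' @return integer vector of vertex indices (ascending).
#' @export
strong_connections <- function(graph, i, rho = 0.95) {
  stopifnot(inherits(graph, "simgraph"))
  stop_if(!(rho > 0 && rho <= 1), "rho must lie in (0, 1]")
  if (is.character(i)) i <- match(i, graph$vertex_ids)
  stop_if(is.na(i) || i < 1 || i > length(graph$vertex_ids), "unknown vertex")
  n <- length(graph$vertex_ids)
  if (n < 2) return(integer(0))
  w <- abs(graph$weights[i, ])
  w[i] <- NA_real_
  thr <- rho * max(w, na.rm = TRUE)
  sort(unname(which(!is.na(w) & w >= thr)))
}

# strong-connection sets for all vertices at once
strong_sets <- function(graph, rho) {
  lapply(seq_along(graph$vertex_ids), function(i) strong_connections(graph, i, rho))
}

#' Coarsen one graph level into coarse and fine vertices
#'
#' Implements the selection loop: compute each vertex's desirability
#' (number of vertices that count it among their strong connections), pick
#' the undesignated vertex with maximal desirability (ties to the lowest
#' index) as coarse, designate every undesignated vertex that strongly
#' depends on it as fine (assigned to it), then update desirabilities:
#' +1 to undesignated strong connections of the newly fine vertices, -1 to
#' undesignated strong connections of the new coarse vertex. Repeat until
#' every vertex is designated. Desirabilities may go negative.
#'
#' @param graph a `"simgraph"` with >= 1 vertex.
#' @param rho strong-connection threshold, see [strong_connections()].
#' @return an object of class `"coarsening_level"`: list(graph, coarse_ids,
#'   fine_to_coarse (named character vector), desirability_trace (list of
#'   the psi vector recorded before each coarse selection; designated
#'   vertices are `NA`)).
#' @export
coarsen_level <- function(graph, rho = 0.95) {
  stopifnot(inherits(graph, "simgraph"))
  n <- length(graph$vertex_ids)
  ids <- graph$vertex_ids
  if (n == 1) {
    return(structure(list(graph = graph, coarse_ids = ids,
                          fine_to_coarse = setNames(character(0), character(0)),
                          desirability_trace = list(setNames(0, ids))),
                     class = "coarsening_level"))
  }
  S <- strong_sets(graph, rho)
  psi <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(k) k != i && i %in% S[[k]], FALSE))
  }, 0)
  undes <- rep(TRUE, n)
  coarse <- integer(0)
  fine_parent <- rep(NA_integer_, n)
  trace <- list()
  while (any(undes)) {
    snap <- psi
    snap[!undes] <- NA_real_
    trace[[length(trace) + 1L]] <- setNames(snap, ids)
    cand <- which(undes)
    c_new <- cand[which.max(psi[cand])]  # which.max ties -> first == lowest index
    undes[c_new] <- FALSE
    coarse <- c(coarse, c_new)
    newly_fine <- cand[cand != c_new & vapply(cand, function(k) c_new %in% S[[k]], FALSE)]
    if (length(newly_fine)) {
      undes[newly_fine] <- FALSE
      fine_parent[newly_fine] <- c_new
      for (f in newly_fine) {
        up <- intersect(S[[f]], which(undes))
        psi[up] <- psi[up] + 1
      }
    }
    down <- intersect(S[[c_new]], which(undes))
    psi[down] <- psi[down] - 1
  }
  fi <- which(!is.na(fine_parent))
  structure(list(graph = graph,
                 coarse_ids = ids[sort(coarse)],
                 fine_to_coarse = setNames(ids[fine_parent[fi]], ids[fi]),
                 desirability_trace = trace),
            class = "coarsening_level")
}

#' @export
print.coarsening_level <- function(x, ...) {
  cat(sprintf("<coarsening_level> %d vertices -> %d coarse, %d fine\n",
              length(x$graph$vertex_ids), length(x$coarse_ids),
              length(x$fine_to_coarse)))
  invisible(x)
}

induced_subgraph <- function(graph, keep_ids, level) {
  idx <- match(keep_ids, graph$vertex_ids)
  similarity_graph(keep_ids, graph$weights[idx, idx, drop = FALSE], level = level)
}

#' Multi-level coarsening of a similarity graph
#'
#' Repeatedly applies [coarsen_level()], carrying the coarse vertices (with
#' edge weights inherited from the input similarity matrix) to the next
#' level, until the hierarchy is stable. Stability means either (i) a level
#' designates every vertex coarse (two consecutive graphs of equal size),
#' or (ii) a level past the first would merge all surviving exemplars into
#' a single vertex. Case (ii) is treated as stability because vertices at
#' levels >= 1 are already cluster exemplars whose mutual similarities are,
#' by construction, relatively close, so the relative strong-connection
#' rule would always fuse them and erase the population structure the
#' hierarchy exists to expose. A collapse at level 0, by contrast, reflects
#' a genuinely homogeneous cohort and is accepted.
#'
#' @param graph0 the level-0 `"simgraph"`.
#' @param rho strong-connection threshold in (0, 1].
#' @return an object of class `"coarsening_result"`: list(levels, rho,
#'   exemplar_ids, assignment). `assignment` maps every original vertex id
#'   to its top-level exemplar id by composing fine-to-coarse maps through
#'   the hierarchy.
#' @export
coarsen_multilevel <- function(graph0, rho = 0.95) {
  stopifnot(inherits(graph0, "simgraph"))
  stop_if(!(rho > 0 && rho <= 1), "rho must lie in (0, 1]")
  levels <- list()
  G <- graph0
  l <- 0L
  repeat {
    stop_if(l > length(graph0$vertex_ids),
            "coarsening failed to terminate")  # cannot happen: sizes non-increasing
    L <- coarsen_level(G, rho)
    nc <- length(L$coarse_ids)
    n <- length(G$vertex_ids)
    if (nc == n) {            # all coarse: |G^l| == |G^{l-1}|, stable
      levels[[length(levels) + 1L]] <- L
      break
    }
    if (nc == 1L && l > 0L) { # would fuse all exemplars: stop before doing so
      levels[[length(levels) + 1L]] <- structure(
        list(graph = G, coarse_ids = G$vertex_ids,
             fine_to_coarse = setNames(character(0), character(0)),
             desirability_trace = list()),
        class = "coarsening_level")
      break
    }
    levels[[length(levels) + 1L]] <- L
    if (nc == 1L) {           # homogeneous cohort collapsed at level 0
      G <- induced_subgraph(G, L$coarse_ids, level = l + 1L)
      levels[[length(levels) + 1L]] <- coarsen_level(G, rho)
      break
    }
    G <- induced_subgraph(G, L$coarse_ids, level = l + 1L)
    l <- l + 1L
  }
  exemplars <- levels[[length(levels)]]$coarse_ids
  assignment <- setNames(graph0$vertex_ids, graph0$vertex_ids)
  for (L in levels) {
    assignment[] <- vapply(assignment, function(v) {
      p <- L$fine_to_coarse[v]
      if (is.na(p)) v else unname(p)
    }, "")
  }
  structure(list(levels = levels, rho = rho, exemplar_ids = exemplars,
                 assignment = assignment),
            class = "coarsening_result")
}

#' @export
print.coarsening_result <- function(x, ...) {
  cat(sprintf("<coarsening_result> %d levels, rho = %g, %d exemplar(s): %s\n",
              length(x$levels), x$rho, length(x$exemplar_ids),
              paste(x$exemplar_ids, collapse = ", ")))
  invisible(x)
}

#' Randomly selected exemplars (template-selection baseline)
#'
#' Uniform sample of `k` vertex ids without replacement, reproducible by
#' seed. Used to compare clustering-driven template selection against
#' random selection with a matched template count.
#'
#' @param vertex_ids character vector of candidate ids.
#' @param k number of exemplars, `k <= length(vertex_ids)`.
#' @param seed integer seed.
#' @return character vector of `k` ids.
#' @export
random_exemplars <- function(vertex_ids, k, seed) {
  stop_if(k > length(vertex_ids), "k exceeds the number of vertices")
  stop_if(k < 1, "k must be >= 1")
  with_seed(seed, sample(vertex_ids, k))
}
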