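# AMG coarsening: strong connections, one-level designation, hierarchy

test_that("strong connections implement the relative threshold", {
  w <- matrix(NA_real_, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.8
  w[1, 4] <- w[4, 1] <- 0.85
  w[2, 3] <- w[3, 2] <- 0.5
  w[2, 4] <- w[4, 2] <- 0.6
  w[3, 4] <- w[4, 3] <- 0.55
  g <- similarity_graph(letters[1:4], w)
  # rho = 1: exactly the argmax neighbour
  expect_identical(strong_connections(g, 1, 1), 2L)
  # threshold 0.95 * 0.9 = 0.855 keeps only the 0.9 edge
  expect_identical(strong_connections(g, 1, 0.95), 2L)
  # uniform weights: every neighbour is strong at any rho
  gu <- similarity_graph(c("x", "y", "z"), {
    m <- matrix(0.7, 3, 3); diag(m) <- NA; m
  })
  expect_identical(strong_connections(gu, 1, 0.4), c(2L, 3L))
  expect_error(strong_connections(g, 1, 0), "rho")
})

test_that("coarsen_level reproduces the hand-traced designations", {
  w <- matrix(NA_real_, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.8
  w[1, 4] <- w[4, 1] <- 0.85
  w[2, 3] <- w[3, 2] <- 0.5
  w[2, 4] <- w[4, 2] <- 0.6
  w[3, 4] <- w[4, 3] <- 0.55
  g <- similarity_graph(letters[1:4], w)
  L <- coarsen_level(g, 0.95)
  # vertex 1 is the unique strong connection of 2, 3, 4 -> psi = (3,1,0,0)
  expect_identical(unname(L$desirability_trace[[1]]), c(3, 1, 0, 0))
  expect_identical(L$coarse_ids, "a")
  expect_identical(sort(names(L$fine_to_coarse)), c("b", "c", "d"))
  expect_true(all(L$fine_to_coarse == "a"))

  # uniform complete graph: tie-break picks the first vertex
  gu <- similarity_graph(c("x", "y", "z"), {
    m <- matrix(0.7, 3, 3); diag(m) <- NA; m
  })
  Lu <- coarsen_level(gu, 0.95)
  expect_identical(Lu$coarse_ids, "x")
  expect_identical(unname(Lu$desirability_trace[[1]]), c(2, 2, 2))

  # single vertex: its own coarse
  g1 <- similarity_graph("solo", matrix(NA_real_, 1, 1))
  expect_identical(coarsen_level(g1, 0.95)$coarse_ids, "solo")
})

test_that("coarsen_level matches the literal reference on random graphs", {
  for (seed in 1:100) {
    n <- 2 + (seed %% 7)
    g <- random_graph(seed, n)
    L <- coarsen_level(g, 0.95)
    R <- ref_coarsen_level(g$weights, 0.95)
    expect_identical(match(L$coarse_ids, g$vertex_ids), sort(R$coarse),
                     info = paste("coarse sets differ at seed", seed))
    pkg_parent <- rep(NA_integer_, n)
    fi <- match(names(L$fine_to_coarse), g$vertex_ids)
    pkg_parent[fi] <- match(unname(L$fine_to_coarse), g$vertex_ids)
    expect_identical(pkg_parent, R$parent, info = paste("assignments, seed", seed))
    expect_equal(lapply(L$desirability_trace, unname), R$traces,
                 info = paste("psi traces, seed", seed))
  }
})

test_that("every vertex is designated exactly once and levels shrink monotonically", {
  for (seed in c(3, 14, 25)) {
    g <- random_graph(seed, 8)
    res <- coarsen_multilevel(g, 0.95)
    for (L in res$levels) {
      ids <- L$graph$vertex_ids
      expect_setequal(c(L$coarse_ids, names(L$fine_to_coarse)), ids)
      expect_equal(length(L$coarse_ids) + length(L$fine_to_coarse), length(ids))
    }
    sizes <- vapply(res$levels, function(L) length(L$graph$vertex_ids), 0L)
    expect_true(all(diff(sizes) <= 0))
    expect_true(all(res$assignment %in% res$exemplar_ids))
    expect_true(all(res$exemplar_ids %in% g$vertex_ids))
    # determinism, bit for bit
    expect_identical(res, coarsen_multilevel(g, 0.95))
  }
})

test_that("the hierarchy separates well-separated blocks and collapses uniform graphs", {
  wb <- matrix(0.1, 6, 6)
  wb[1:3, 1:3] <- 0.9
  wb[4:6, 4:6] <- 0.9
  diag(wb) <- NA
  gb <- similarity_graph(sprintf("v%d", 1:6), wb)
  res <- coarsen_multilevel(gb, 0.95)
  expect_length(res$exemplar_ids, 2)
  expect_identical(unname(res$assignment[1:3]), rep(res$assignment[[1]], 3))
  expect_identical(unname(res$assignment[4:6]), rep(res$assignment[[4]], 3))
  expect_false(res$assignment[[1]] == res$assignment[[4]])

  gu <- similarity_graph(sprintf("u%d", 1:6), {
    m <- matrix(0.8, 6, 6); diag(m) <- NA; m
  })
  ru <- coarsen_multilevel(gu, 0.95)
  expect_identical(ru$exemplar_ids, "u1")
  expect_true(all(ru$assignment == "u1"))

  g1 <- similarity_graph("one", matrix(NA_real_, 1, 1))
  r1 <- coarsen_multilevel(g1, 0.95)
  expect_identical(r1$exemplar_ids, "one")
})

test_that("smaller rho never enlarges the first-level coarse set", {
  for (seed in c(2, 9, 31, 44, 77)) {
    g <- random_graph(seed, 8)
    sizes <- vapply(c(1, 0.95, 0.7, 0.4, 0.1), function(r) {
      length(coarsen_level(g, r)$coarse_ids)
    }, 0L)
    expect_true(all(diff(sizes) <= 0), info = paste("seed", seed))
  }
})

test_that("random exemplar selection is seeded, uniform, and bounded", {
  ids <- sprintf("t%02d", 1:10)
  expect_setequal(random_exemplars(ids, 10, 1), ids)
  expect_identical(random_exemplars(ids, 3, 42), random_exemplars(ids, 3, 42))
  expect_error(random_exemplars(ids, 11, 1), "exceeds")
  # sampling distribution: every id appears ~uniformly over repeated draws
  draws <- table(unlist(lapply(1:2000, function(s) random_exemplars(ids, 3, s))))
  expect_gt(stats::chisq.test(draws)$p.value, 0.01)
})
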