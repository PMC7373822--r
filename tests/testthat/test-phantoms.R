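# Synthetic cohort generator: determinism, field properties, cluster structure

test_that("random smooth fields are seeded, normed, and invertible", {
  expect_identical(random_smooth_field(c(16, 16, 16), 0, 4, 1)$vectors,
                   zero_field(c(16, 16, 16))$vectors)
  a <- random_smooth_field(c(16, 16, 16), 2, 4, 7)
  b <- random_smooth_field(c(16, 16, 16), 2, 4, 7)
  expect_identical(a$vectors, b$vectors)
  u <- random_smooth_field(c(48, 48, 48), 3, 6, 17)
  nrm <- sqrt(rowSums(matrix(u$vectors, ncol = 3)^2))
  expect_equal(max(nrm), 3, tolerance = 1e-9)
  res <- compose_fields(u, invert_field(u))
  rn <- sqrt(rowSums(matrix(res$vectors, ncol = 3)^2))
  expect_lt(max(rn[as.vector(interior_mask(c(48, 48, 48), 5))]), 0.1)
})

test_that("prototypes are deterministic with the documented label set", {
  spec <- phantom_cohort_spec()
  p1 <- make_prototype(1, spec)
  p2 <- make_prototype(1, spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(sort(unique(as.vector(p1$labels$labels))), 0:4)
  expect_s3_class(p1$field, "dispfield")
  expect_error(make_prototype(5, spec), "range")
})

test_that("a noiseless zero-amplitude cohort reproduces its prototypes exactly", {
  spec <- phantom_cohort_spec(n_images = 3, n_clusters = 3, shape = c(24, 24, 24),
                              deform_amplitude = 0, noise_sigma = 0, seed = 2)
  co <- make_cohort(spec)
  for (i in 1:3) {
    expect_identical(co$images[[i]]$data, co$prototypes[[i]]$volume$data)
    expect_identical(co$labels[[i]]$labels, co$prototypes[[i]]$labels$labels)
  }
})

test_that("cohorts are bit-reproducible and geometrically consistent", {
  spec <- phantom_cohort_spec(n_images = 4, n_clusters = 2, shape = c(24, 24, 24),
                              deform_amplitude = 2, deform_smoothness = 5,
                              noise_sigma = 0.02, seed = 5)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_identical(lapply(a$images, `[[`, "data"), lapply(b$images, `[[`, "data"))
  expect_identical(a$true_clusters, b$true_clusters)
  # labels are the base-anatomy labels warped by the image's total field
  for (id in names(a$images)) {
    expect_identical(a$labels[[id]]$labels,
                     warp(a$base$labels, a$true_fields[[id]])$labels)
  }
})

test_that("NCC cluster structure is unambiguous at the default settings", {
  co <- make_cohort(phantom_cohort_spec(seed = 3))
  g <- build_graph(co$images)
  cl <- co$true_clusters
  w <- g$weights
  same <- outer(cl, cl, `==`) & upper.tri(w)
  diff <- outer(cl, cl, `!=`) & upper.tri(w)
  expect_gt(min(w[same]), max(w[diff]))
})
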