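# Displacement-field algebra: warp, compose, invert, mean-inverse

shift_field <- function(shape, t) {
  v <- array(0, dim = c(shape, 3))
  for (c_ in 1:3) v[, , , c_] <- t[c_]
  disp_field(v)
}

test_that("warping follows the pull-back convention with exact identity at zero", {
  img <- volume(array(seq_len(5^3), dim = c(5, 5, 5)))
  expect_identical(warp(img, zero_field(c(5, 5, 5)))$data, img$data)
  w <- warp(img, shift_field(c(5, 5, 5), c(1, 0, 0)))
  for (x in 1:4) for (y in 1:5) for (z in 1:5) {
    expect_equal(w$data[x, y, z], img$data[x + 1, y, z])
  }
  lab <- label_volume(array(sample(c(0L, 3L, 7L), 5^3, TRUE), dim = c(5, 5, 5)))
  wl <- warp(lab, random_smooth_field(c(5, 5, 5), 1, 2, seed = 1))
  expect_true(all(unique(as.vector(wl$labels)) %in% unique(as.vector(lab$labels))))
  expect_error(warp(img, zero_field(c(4, 4, 4))), "shape")
})

test_that("composition has the identity element and adds translations", {
  shp <- c(10, 10, 10)
  u <- random_smooth_field(shp, 1.5, 3, seed = 2)
  z <- zero_field(shp)
  expect_equal(compose_fields(u, z)$vectors, u$vectors, tolerance = 1e-12)
  expect_equal(compose_fields(z, u)$vectors, u$vectors, tolerance = 1e-12)
  a <- shift_field(shp, c(1, 0.5, 0))
  b <- shift_field(shp, c(0.5, 1, 0.25))
  comp <- compose_fields(a, b)
  inner <- interior_mask(shp, 3)
  for (c_ in 1:3) {
    expect_equal(max(abs(comp$vectors[, , , c_][inner] - (a$vectors[1, 1, 1, c_] +
                                                            b$vectors[1, 1, 1, c_]))), 0,
                 tolerance = 1e-12)
  }
})

test_that("compose matches a pointwise brute-force sampler", {
  shp <- c(16, 16, 16)
  u <- random_smooth_field(shp, 2, 4, seed = 3)
  v <- random_smooth_field(shp, 2, 4, seed = 4)
  comp <- compose_fields(u, v)
  set.seed(5)
  for (rep in 1:25) {
    p <- sapply(shp, function(d) sample(d, 1))
    expect_equal(comp$vectors[p[1], p[2], p[3], ],
                 ref_compose_at(u$vectors, v$vectors, p[1], p[2], p[3]),
                 tolerance = 1e-10)
  }
})

test_that("inversion satisfies the residual guarantee on smooth fields", {
  expect_equal(invert_field(zero_field(c(8, 8, 8)))$vectors,
               zero_field(c(8, 8, 8))$vectors)
  shp <- c(20, 20, 20)
  t_ <- c(1.2, -0.8, 0.5)
  vi <- invert_field(shift_field(shp, t_))
  inner <- interior_mask(shp, 4)
  for (c_ in 1:3) {
    expect_lt(max(abs(vi$vectors[, , , c_][inner] + t_[c_])), 0.01)
  }
  # seeded smooth fields: interior residual of u o u^-1 below 0.1 voxel
  shp <- c(48, 48, 48)
  inner <- as.vector(interior_mask(shp, 5))
  for (seed in 1:3) {
    u <- random_smooth_field(shp, 3, 6, seed = seed)
    ui <- invert_field(u)
    expect_true(isTRUE(attr(ui, "converged")))
    res <- compose_fields(u, ui)
    nrm <- sqrt(rowSums(matrix(res$vectors, ncol = 3)^2))
    expect_lt(max(nrm[inner]), 0.1)
    # double inversion returns close to the original field
    uii <- invert_field(ui)
    dev <- sqrt(rowSums(matrix(uii$vectors - u$vectors, ncol = 3)^2))
    expect_lt(max(dev[inner]), 0.1)
  }
})

test_that("mean-inverse initialization reduces to known closed forms", {
  shp <- c(32, 32, 32)
  inner <- as.vector(interior_mask(shp, 5))
  # single template: double inversion reproduces the field
  u <- random_smooth_field(shp, 2.5, 6, seed = 9)
  ubar <- mean_inverse_init(field_set("i", list(t1 = u)))
  dev <- sqrt(rowSums(matrix(ubar$vectors - u$vectors, ncol = 3)^2))
  expect_lt(max(dev[inner]), 0.1)
  # two opposite translations cancel
  plus <- shift_field(shp, c(2, 0, 0))
  minus <- shift_field(shp, c(-2, 0, 0))
  ubar2 <- mean_inverse_init(field_set("i", list(a = plus, b = minus)))
  nrm <- sqrt(rowSums(matrix(ubar2$vectors, ncol = 3)^2))
  expect_lt(max(nrm[inner]), 0.05)
})

test_that("mean_inverse_init equals an independently chained invert/average/invert", {
  shp <- c(32, 32, 32)
  fs <- field_set("img", list(a = random_smooth_field(shp, 2, 6, seed = 11),
                              b = random_smooth_field(shp, 2, 6, seed = 12),
                              c = random_smooth_field(shp, 2, 6, seed = 13)))
  got <- mean_inverse_init(fs)
  acc <- array(0, dim = c(shp, 3))
  for (f in fs$fields_by_template) acc <- acc + invert_field(f)$vectors
  want <- invert_field(disp_field(acc / 3))
  expect_equal(got$vectors, want$vectors, tolerance = 1e-12)
})

test_that("initialize_cohort tightens a synthetic cohort around its prototypes", {
  spec <- phantom_cohort_spec(n_images = 6, n_clusters = 2, shape = c(32, 32, 32),
                              deform_amplitude = 2.5, deform_smoothness = 6,
                              noise_sigma = 0.01, seed = 21)
  co <- make_cohort(spec)
  backend <- oracle_backend(co$true_fields)
  exemplars <- c("img01", "img02")
  init <- initialize_cohort(co$images, backend, exemplars, labels = co$labels)
  expect_named(init$warped, names(co$images))
  before <- ncc_to_mean(co$images)$mean
  after <- ncc_to_mean(init$warped)$mean
  expect_gt(after, before)
  # zero-field backend is a no-op
  zb <- function(i, j) zero_field(c(32, 32, 32))
  noop <- initialize_cohort(co$images["img01"], zb, "img02")
  expect_identical(noop$warped$img01$data, co$images$img01$data)
})
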