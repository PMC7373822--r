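# Patch tiling geometry and field assembly

test_that("tile counts and margins follow the geometry contract", {
  cfg <- regnet_config()  # 64 -> 24
  t72 <- make_tiling(c(72, 72, 72), cfg)
  expect_equal(nrow(t72$tiles), 27)
  expect_equal(t72$margin, 20)
  expect_equal(t72$core_shape, c(72, 72, 72))
  t70 <- make_tiling(c(70, 70, 70), cfg)
  expect_equal(nrow(t70$tiles), 27)
  expect_equal(t70$core_shape, c(72, 72, 72))
  expect_equal(t70$padded_shape, c(112, 112, 112))
  t24 <- make_tiling(c(24, 24, 24), cfg)
  expect_equal(nrow(t24$tiles), 1)
  # output tiles partition the core: disjoint corners, exhaustive count
  oc <- as.matrix(t72$tiles[, c("out_x", "out_y", "out_z")])
  expect_equal(nrow(unique(oc)), 27)
  expect_true(all((oc - 1 - t72$margin) %% cfg$out_patch == 0))
})

test_that("assembling tiled ground truth reproduces the field exactly", {
  cfg <- tiny_regnet_config()  # 32 -> 16
  for (shp in list(c(16, 16, 16), c(40, 40, 40), c(30, 30, 30))) {
    u <- random_smooth_field(shp, 2, 5, seed = sum(shp))
    tl <- make_tiling(shp, cfg)
    gpad <- lapply(1:3, function(c_) groupinit:::pad_to_tiling(u$vectors[, , , c_], tl))
    tiles <- lapply(seq_len(nrow(tl$tiles)), function(t) {
      oc <- c(tl$tiles$out_x[t], tl$tiles$out_y[t], tl$tiles$out_z[t])
      vapply(gpad, function(g) as.vector(groupinit:::extract_block(g, oc, cfg$out_patch)),
             numeric(cfg$out_patch^3))
    })
    re <- assemble_field(tiles, tl)
    expect_identical(re$vectors, u$vectors)
  }
})

test_that("assemble_field validates tile counts and produces block-constant layouts", {
  cfg <- tiny_regnet_config()
  tl <- make_tiling(c(32, 32, 32), cfg)  # 8 tiles
  zeros <- replicate(8, matrix(0, 16^3, 3), simplify = FALSE)
  z <- assemble_field(zeros, tl)
  expect_equal(max(abs(z$vectors)), 0)
  expect_equal(z$reference_shape, c(32, 32, 32))
  # tiles filled with their index -> block-constant assembled field
  idx_tiles <- lapply(1:8, function(t) matrix(t, 16^3, 3))
  f <- assemble_field(idx_tiles, tl)
  expect_equal(f$vectors[1, 1, 1, 1], 1)
  expect_equal(f$vectors[32, 32, 32, 1], 8)
  expect_equal(length(unique(as.vector(f$vectors))), 8)
  expect_error(assemble_field(zeros[1:7], tl), "expected")
})

test_that("downsampling ground-truth fields averages blocks and rescales units", {
  cfg <- tiny_regnet_config()
  const <- matrix(rep(c(2, -1, 0.5), each = 16^3), ncol = 3)
  mid <- groupinit:::downsample_field_patch(const, c(16, 16, 16), 2L)
  expect_equal(nrow(mid), 8^3)
  expect_equal(unique(mid[, 1]), 1)     # displacement halves with the grid
  expect_equal(unique(mid[, 2]), -0.5)
  low <- groupinit:::downsample_field_patch(const, c(16, 16, 16), 4L)
  expect_equal(unique(low[, 3]), 0.125)
})
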