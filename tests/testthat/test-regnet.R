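# Deformation-prediction network: configuration, schedule, loss, forward
# contract, split arithmetic, and a small overfitting sanity run.

test_that("configuration validation enforces the patch geometry contract", {
  expect_s3_class(regnet_config(), "regnet_config")
  expect_error(regnet_config(in_patch = 24, out_patch = 24), "exceed")
  expect_error(regnet_config(in_patch = 63, out_patch = 24), "even|divisible")
  expect_error(regnet_config(in_patch = 64, out_patch = 18), "divisible")
  expect_error(regnet_config(schedule = function(e, E) 1 - 2 * e / E), "\\[0, 1\\]")
  expect_error(regnet_config(schedule = function(e, E) e / E), "non-increasing")
})

test_that("the loss schedule is a convex combination with the stated endpoints", {
  cfg <- regnet_config(epochs = 10)
  ab0 <- loss_schedule(0, cfg)
  ab9 <- loss_schedule(9, cfg)
  expect_equal(ab0[["alpha"]], 1)
  expect_equal(ab0[["beta"]], 0)
  expect_equal(ab9[["alpha"]], 0)
  expect_equal(ab9[["beta"]], 1)
  for (e in 0:9) {
    ab <- loss_schedule(e, cfg)
    expect_equal(ab[["alpha"]] + ab[["beta"]], 1)
  }
  expect_error(loss_schedule(10, cfg), "range")
})

test_that("split arithmetic reproduces the reference cohort sizes", {
  ids69 <- sprintf("s%02d", 1:69)
  sp <- split_dataset(ids69, 0.75, seed = 1)
  expect_length(sp$train, 52)
  expect_length(sp$test, 17)
  expect_setequal(c(sp$train, sp$test), ids69)
  sp4 <- split_dataset(sprintf("x%d", 1:4), 0.75, seed = 2)
  expect_length(sp4$train, 3)
  expect_length(sp4$test, 1)
  expect_identical(split_dataset(ids69, 0.75, seed = 7),
                   split_dataset(ids69, 0.75, seed = 7))
})

test_that("forward pass honors the three-resolution shape contract deterministically", {
  cfg <- regnet_config(in_patch = 64, out_patch = 24, depth = 3,
                       base_channels = 4, seed = 2)
  net <- build_network(cfg)
  x <- matrix(0, 64^3, 2)
  fwd <- groupinit:::net_forward(net, x, train = FALSE)
  expect_equal(vapply(fwd$preds, nrow, 0), c(full = 24^3, mid = 12^3, low = 6^3))
  expect_equal(vapply(fwd$preds, ncol, 0), c(full = 3, mid = 3, low = 3))
  # deterministic rebuild and evaluation
  expect_identical(net$params, build_network(cfg)$params)
  set.seed(3)
  x2 <- matrix(rnorm(64^3 * 2), ncol = 2)
  expect_identical(groupinit:::net_forward(net, x2, train = FALSE)$preds,
                   groupinit:::net_forward(net, x2, train = FALSE)$preds)
})

test_that("the dual-guidance loss has the stated closed forms and endpoints", {
  cfg <- tiny_regnet_config(seed = 4)
  outp <- cfg$out_patch
  gt <- matrix(rep(c(1.5, 2, 0), each = outp^3), ncol = 3)  # constant field
  zero_preds <- list(full = matrix(0, outp^3, 3),
                     mid = matrix(0, (outp / 2)^3, 3),
                     low = matrix(0, (outp / 4)^3, 3))
  mv <- array(rnorm(cfg$in_patch^3), dim = rep(cfg$in_patch, 3))
  fx <- rnorm(outp^3)
  ls <- dual_guidance_loss(zero_preds, gt, mv, fx, 1, 0, cfg)
  t_norm <- sqrt(1.5^2 + 2^2)
  expect_equal(ls$loss_u_high, t_norm)
  expect_equal(ls$loss_u_mid, t_norm / 2)   # displacement rescaled with the grid
  expect_equal(ls$loss_u_low, t_norm / 4)
  expect_equal(ls$total, ls$loss_u)         # alpha = 1: image content ignored
  # alpha = 0: ground truth ignored
  ls0 <- dual_guidance_loss(zero_preds, gt * 5, mv, fx, 0, 1, cfg)
  expect_equal(ls0$total, ls0$loss_ssd)
  # perfect prediction of a zero task: zero loss
  perfect <- dual_guidance_loss(zero_preds, gt * 0, mv,
                                array(mv[groupinit:::crop_rows(cfg$in_patch, outp)],
                                      dim = rep(outp, 3)),
                                0.5, 0.5, cfg)
  expect_equal(perfect$total, 0)
  expect_error(dual_guidance_loss(zero_preds, gt, mv, fx, 0.7, 0.7, cfg), "alpha")
})

test_that("training on a degenerate zero task keeps the loss at zero", {
  shp <- c(16, 16, 16)
  img <- volume(array(rnorm(16^3)^2 + 0.1, dim = shp))
  pair <- training_pair(img, img, zero_field(shp))
  cfg <- regnet_config(in_patch = 16, out_patch = 8, depth = 2,
                       base_channels = 2, epochs = 2, seed = 6,
                       loss_u_squared = TRUE)
  fit <- train_regnet(list(pair), cfg)
  expect_equal(nrow(fit$history), 2)
  expect_lt(fit$history$loss_total[1], 0.05)
  expect_lt(tail(fit$history$loss_total, 1), 0.05)
})

test_that("a trained network overfits one pair and transfer preserves the base", {
  spec <- phantom_cohort_spec(n_images = 2, n_clusters = 1, shape = c(24, 24, 24),
                              deform_amplitude = 2, deform_smoothness = 6,
                              noise_sigma = 0, seed = 4)
  co <- make_cohort(spec)
  proto <- co$prototypes[[1]]$volume
  gt1 <- invert_field(co$true_fields[[1]])
  pair <- training_pair(co$images[[1]], proto, gt1)
  cfg <- regnet_config(in_patch = 24, out_patch = 12, depth = 2, base_channels = 8,
                       epochs = 9, schedule = function(e, E) 1, seed = 3)
  fit <- train_regnet(list(pair), cfg)
  expect_equal(nrow(fit$history), 9)
  pred <- predict_field(fit, co$images[[1]])
  expect_equal(pred$reference_shape, c(24, 24, 24))
  inner <- interior_mask(c(24, 24, 24), 4)
  init_mag <- endpoint_error(zero_field(c(24, 24, 24)), gt1, inner)
  expect_lt(endpoint_error(pred, gt1, inner), init_mag)
  # prediction is deterministic
  expect_identical(pred$vectors, predict_field(fit, co$images[[1]])$vectors)
  # transfer with zero learning rate is an exact clone; base stays intact
  gt2 <- invert_field(co$true_fields[[2]])
  pair2 <- training_pair(co$images[[2]], proto, gt2)
  snapshot <- fit$net$params
  tz <- transfer_train(fit, list(pair2), lr = 0)
  expect_identical(tz$net$params, fit$net$params)
  tr <- transfer_train(fit, list(pair2), epochs = 1)
  expect_identical(fit$net$params, snapshot)  # base unmodified
  # at lr 1e-7 the transferred network stays numerically near the base
  dev <- max(vapply(names(snapshot), function(nm) {
    max(abs(tr$net$params[[nm]] - snapshot[[nm]]))
  }, 0))
  expect_lt(dev, 1e-4)
})
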