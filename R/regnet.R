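# Patch-based deformation-prediction network.
#
# A U-Net-style 3D CNN maps a two-channel intensity patch of edge
# `in_patch` (moving image + template, one network per template) to a
# displacement-field patch of edge `out_patch` (central crop), with
# deep supervision at three resolutions (full, 1/2, 1/4 of the output) and
# a dual-guidance loss: distance to ground-truth fields from an existing
# registration method (or a synthetic generator), plus the intensity
# mismatch of the warped moving patch. Layers follow the stated contract:
# 3x3x3 convolutions each followed by ReLU and batch normalization,
# 2x2x2 max pooling, 2x2x2 deconvolutions, extra 3x3x3 convolutions
# bridging equal-depth contracting/expansive levels, and 1x1x1 output
# convolutions. Everything runs on the CPU via im2col + BLAS products.

#' Configuration of the deformation-prediction network
#'
#' @param in_patch input patch edge (voxels); must exceed `out_patch` by an
#'   even margin and be divisible by `2^depth`.
#' @param out_patch output field patch edge; step size of the non-overlapping
#'   output tiling; divisible by 4 (supervision at 1/2 and 1/4 resolution).
#' @param depth number of pooling levels (>= 2; default 3).
#' @param base_channels channels of the first level, doubled per level.
#' @param epochs training epochs (default 10).
#' @param lr_primary ADAM learning rate for the central-template network.
#' @param lr_transfer ADAM learning rate for transfer-trained networks.
#' @param schedule `"linear"` (alpha falls 1 -> 0 over the epochs) or a
#'   `function(epoch, epochs)` returning alpha in \[0, 1\], non-increasing;
#'   beta is always `1 - alpha`.
#' @param seed integer seed for weight initialization and data order.
#' @return an object of class `"regnet_config"`.
#' @export
regnet_config <- function(in_patch = 64, out_patch = 24, depth = 3,
                          base_channels = 16, epochs = 10,
                          lr_primary = 1e-2, lr_transfer = 1e-7,
                          schedule = "linear", loss_u_squared = FALSE,
                          seed = 1) {
  stop_if(in_patch <= out_patch, "in_patch must exceed out_patch")
  stop_if((in_patch - out_patch) %% 2 != 0, "in_patch - out_patch must be even")
  stop_if(depth < 2, "depth must be >= 2")
  stop_if(in_patch %% (2^depth) != 0, "in_patch must be divisible by 2^depth")
  stop_if(out_patch %% 4 != 0, "out_patch must be divisible by 4")
  stop_if(epochs < 1, "epochs must be >= 1")
  cfg <- structure(list(in_patch = as.integer(in_patch),
                        out_patch = as.integer(out_patch),
                        depth = as.integer(depth),
                        base_channels = as.integer(base_channels),
                        epochs = as.integer(epochs),
                        lr_primary = lr_primary, lr_transfer = lr_transfer,
                        schedule = schedule, seed = as.integer(seed),
                        loss_u_squared = loss_u_squared,
                        bn_eps = 1e-5, bn_momentum = 0.1),
                   class = "regnet_config")
  # reject schedules violating the convex-combination constraint up front
  ab <- vapply(seq_len(cfg$epochs) - 1L, function(e) {
    if (is.function(schedule)) schedule(e, cfg$epochs) else
      if (cfg$epochs == 1) 1 else 1 - e / (cfg$epochs - 1)
  }, 0)
  stop_if(any(ab < -1e-12 | ab > 1 + 1e-12), "schedule must keep alpha in [0, 1]")
  stop_if(any(diff(ab) > 1e-12), "schedule must be non-increasing in alpha")
  cfg
}

#' A reduced network configuration for small grids
#'
#' 32^3 -> 16^3 patches, 2 pooling levels, 8 base channels, 5 epochs:
#' suitable for desk-scale experiments on 32^3 to 48^3 volumes.
#' @param ... overrides passed to [regnet_config()].
#' @export
tiny_regnet_config <- function(...) {
  args <- list(...)
  defaults <- list(in_patch = 32, out_patch = 16, depth = 2, base_channels = 8,
                   epochs = 5)
  do.call(regnet_config, utils::modifyList(defaults, args))
}

#' Loss-weight schedule
#'
#' Returns the pair (alpha, beta) for an epoch: alpha weights the
#' field-guidance term, beta the intensity term, with `alpha + beta = 1` at
#' every epoch. The default schedule starts with full field guidance
#' (alpha = 1) and moves linearly to full intensity guidance (alpha = 0) at
#' the final epoch, so training converges quickly on the coarse guidance
#' and is then refined by image similarity.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < cfg$epochs`.
#' @param cfg a [regnet_config()].
#' @return named numeric vector `c(alpha = ..., beta = ...)`.
#' @export
loss_schedule <- function(epoch, cfg) {
  stop_if(epoch < 0 || epoch >= cfg$epochs, "epoch out of range")
  alpha <- if (is.function(cfg$schedule)) {
    cfg$schedule(epoch, cfg$epochs)
  } else if (identical(cfg$schedule, "linear")) {
    if (cfg$epochs == 1) 1 else 1 - epoch / (cfg$epochs - 1)
  } else {
    stop("unknown schedule: ", cfg$schedule, call. = FALSE)
  }
  alpha <- min(max(alpha, 0), 1)
  c(alpha = alpha, beta = 1 - alpha)
}

#' Shuffled train/test split of image ids
#'
#' Shuffles by seed and allocates `round(ratio * N)` ids to training; the
#' split is disjoint and exhaustive. With 69 ids at ratio 0.75 this yields
#' 52 training and 17 test ids.
#'
#' @param ids character vector (length >= 2).
#' @param ratio training fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors.
#' @export
split_dataset <- function(ids, ratio = 0.75, seed = 1) {
  stop_if(length(ids) < 2, "need at least 2 ids")
  stop_if(!(ratio > 0 && ratio < 1), "ratio must lie in (0, 1)")
  n_train <- round(ratio * length(ids))
  stop_if(n_train < 1 || n_train >= length(ids),
          "split leaves an empty train or test set")
  shuffled <- with_seed(seed, sample(ids))
  list(train = shuffled[seq_len(n_train)], test = shuffled[-seq_len(n_train)])
}

# ---- architecture ----------------------------------------------------------

# channel plan: enc level l has base * 2^(l-1) channels; bottleneck doubles
net_channels <- function(cfg) {
  enc <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  list(enc = enc, bott = cfg$base_channels * 2^cfg$depth)
}

init_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

#' Build an untrained deformation-prediction network
#'
#' Weights are He-initialized from the seed in `cfg`; output heads start
#' near zero so the initial prediction is (close to) the zero field. Two
#' builds with one seed are identical.
#'
#' @param cfg a [regnet_config()].
#' @return an object of class `"regnet"`: list(params, stats, cfg).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "regnet_config"))
  ch <- net_channels(cfg)
  D <- cfg$depth
  with_seed(cfg$seed, {
    p <- list()
    st <- list()
    add_cbr <- function(name, cin, cout) {
      p[[paste0(name, ".W")]] <<- init_mat(27 * cin, cout, sqrt(2 / (27 * cin)))
      p[[paste0(name, ".b")]] <<- rep(0, cout)
      p[[paste0(name, ".gamma")]] <<- rep(1, cout)
      p[[paste0(name, ".beta")]] <<- rep(0, cout)
      st[[name]] <<- list(mean = rep(0, cout), var = rep(1, cout))
    }
    cin_prev <- 2L  # input channels: moving patch + template patch
    for (l in seq_len(D)) {
      add_cbr(paste0("enc", l), cin_prev, ch$enc[l])
      cin_prev <- ch$enc[l]
    }
    add_cbr("bott", ch$enc[D], ch$bott)
    for (l in seq_len(D)) {
      deeper <- if (l == D) ch$bott else ch$enc[l + 1]
      # 2x2x2 transposed convolution: one cin x cout block per corner offset
      p[[paste0("up", l, ".W")]] <- array(rnorm(deeper * ch$enc[l] * 8,
                                                sd = sqrt(2 / deeper)),
                                          dim = c(deeper, ch$enc[l], 8))
      p[[paste0("up", l, ".b")]] <- rep(0, ch$enc[l])
      add_cbr(paste0("skip", l), ch$enc[l], ch$enc[l])
      add_cbr(paste0("merge", l), 2 * ch$enc[l], ch$enc[l])
    }
    low_ch <- if (D >= 3) ch$enc[3] else ch$bott
    p[["head_full.W"]] <- init_mat(ch$enc[1], 3, 1e-3)
    p[["head_full.b"]] <- rep(0, 3)
    p[["head_mid.W"]] <- init_mat(ch$enc[2], 3, 1e-3)
    p[["head_mid.b"]] <- rep(0, 3)
    p[["head_low.W"]] <- init_mat(low_ch, 3, 1e-3)
    p[["head_low.b"]] <- rep(0, 3)
    structure(list(params = p, stats = st, cfg = cfg), class = "regnet")
  })
}

#' @export
print.regnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<regnet> depth %d, base %d channels, %d^3 -> %d^3, %d parameters\n",
              x$cfg$depth, x$cfg$base_channels, x$cfg$in_patch, x$cfg$out_patch, np))
  invisible(x)
}

# rows of the centered size^3 block of a dims^3 patch, voxel-major
crop_rows <- function(dims, size) {
  s <- (dims - size) %/% 2L
  rows <- array(seq_len(dims^3), dim = rep(dims, 3))
  as.vector(rows[(s + 1):(s + size), (s + 1):(s + size), (s + 1):(s + size)])
}

addcol <- function(M, v) M + rep(v, each = nrow(M))

# conv(3^3, same) -> ReLU -> batch norm
cbr_fwd <- function(net, name, X, dims, train) {
  p <- net$params
  eps <- net$cfg$bn_eps
  W <- p[[paste0(name, ".W")]]
  cin <- nrow(W) %/% 27L
  C <- cn_im2col(X, dims, dims, dims)
  Z <- addcol(C %*% W, p[[paste0(name, ".b")]])
  A <- pmax(Z, 0)
  if (train) {
    mu <- colMeans(A)
    v <- colMeans(A * A) - mu^2
  } else {
    mu <- net$stats[[name]]$mean
    v <- net$stats[[name]]$var
  }
  inv <- 1 / sqrt(v + eps)
  n <- nrow(A)
  xhat <- (A - rep(mu, each = n)) * rep(inv, each = n)
  Y <- addcol(xhat * rep(p[[paste0(name, ".gamma")]], each = n),
              p[[paste0(name, ".beta")]])
  new_stats <- NULL
  if (train) {
    mom <- net$cfg$bn_momentum
    old <- net$stats[[name]]
    new_stats <- list(mean = (1 - mom) * old$mean + mom * mu,
                      var = (1 - mom) * old$var + mom * v)
  }
  list(Y = Y, cache = list(name = name, C = C, dims = dims, Z = Z,
                           xhat = xhat, inv = inv, cin = cin),
       stats = new_stats)
}

cbr_bwd <- function(net, cache, dY, grads) {
  p <- net$params
  name <- cache$name
  n <- nrow(dY)
  gamma <- p[[paste0(name, ".gamma")]]
  grads[[paste0(name, ".gamma")]] <- grads[[paste0(name, ".gamma")]] %||% 0 +
    colSums(dY * cache$xhat)
  grads[[paste0(name, ".beta")]] <- grads[[paste0(name, ".beta")]] %||% 0 + colSums(dY)
  dxhat <- dY * rep(gamma, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dA <- (dxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
    rep(cache$inv, each = n)
  dZ <- dA * (cache$Z > 0)
  grads[[paste0(name, ".W")]] <- grads[[paste0(name, ".W")]] %||% 0 +
    crossprod(cache$C, dZ)
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] %||% 0 + colSums(dZ)
  dX <- cn_col2im(dZ %*% t(p[[paste0(name, ".W")]]),
                  cache$dims, cache$dims, cache$dims, cache$cin)
  list(dX = dX, grads = grads)
}

# output row ids for the 8 corner offsets of a 2x stride-2 upsampling
upsample_indices <- function(din) {
  dout <- 2L * din
  gc_ <- grid_coords(rep(din, 3))
  idx <- vector("list", 8L)
  o <- 1L
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    idx[[o]] <- (2L * gc_[, 1] - 1L + cx) +
      dout * (2L * gc_[, 2] - 2L + cy) +
      dout * dout * (2L * gc_[, 3] - 2L + cz)
    o <- o + 1L
  }
  idx
}

deconv_fwd <- function(net, name, X, din) {
  W <- net$params[[paste0(name, ".W")]]
  b <- net$params[[paste0(name, ".b")]]
  idx <- upsample_indices(din)
  Y <- matrix(0, 8 * nrow(X), dim(W)[2])
  for (o in 1:8) Y[idx[[o]], ] <- X %*% W[, , o]
  Y <- addcol(Y, b)
  list(Y = Y, cache = list(name = name, X = X, idx = idx))
}

deconv_bwd <- function(net, cache, dY, grads) {
  W <- net$params[[paste0(cache$name, ".W")]]
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, nrow(cache$X), dim(W)[1])
  for (o in 1:8) {
    dYo <- dY[cache$idx[[o]], , drop = FALSE]
    dW[, , o] <- crossprod(cache$X, dYo)
    dX <- dX + dYo %*% t(W[, , o])
  }
  grads[[paste0(cache$name, ".W")]] <- grads[[paste0(cache$name, ".W")]] %||% 0 + dW
  grads[[paste0(cache$name, ".b")]] <- grads[[paste0(cache$name, ".b")]] %||% 0 +
    colSums(dY)
  list(dX = dX, grads = grads)
}

# Forward pass on one input patch (voxel-major n x 1 matrix).
# Returns the three supervised predictions (cropped to out, out/2, out/4)
# and, when `keep_cache`, everything the backward pass needs.
net_forward <- function(net, x, train = FALSE, keep_cache = train) {
  cfg <- net$cfg
  D <- cfg$depth
  P <- cfg$in_patch
  caches <- list()
  stats_updates <- list()
  enc_out <- vector("list", D)
  dims <- P
  cur <- x
  for (l in seq_len(D)) {
    r <- cbr_fwd(net, paste0("enc", l), cur, dims, train)
    if (!is.null(r$stats)) stats_updates[[paste0("enc", l)]] <- r$stats
    enc_out[[l]] <- r$Y
    caches[[paste0("enc", l)]] <- r$cache
    mp <- cn_maxpool(r$Y, dims, dims, dims)
    caches[[paste0("pool", l)]] <- list(idx = mp$idx, n = nrow(r$Y))
    cur <- mp$y
    dims <- dims %/% 2L
  }
  r <- cbr_fwd(net, "bott", cur, dims, train)
  if (!is.null(r$stats)) stats_updates[["bott"]] <- r$stats
  bott_out <- r$Y
  caches[["bott"]] <- r$cache
  bott_dims <- dims
  cur <- bott_out
  dec_out <- vector("list", D)
  for (l in rev(seq_len(D))) {
    din <- P %/% (2L^l)
    u <- deconv_fwd(net, paste0("up", l), cur, din)
    caches[[paste0("up", l)]] <- u$cache
    s <- cbr_fwd(net, paste0("skip", l), enc_out[[l]], 2L * din, train)
    if (!is.null(s$stats)) stats_updates[[paste0("skip", l)]] <- s$stats
    caches[[paste0("skip", l)]] <- s$cache
    cat_ <- cbind(s$Y, u$Y)
    m <- cbr_fwd(net, paste0("merge", l), cat_, 2L * din, train)
    if (!is.null(m$stats)) stats_updates[[paste0("merge", l)]] <- m$stats
    caches[[paste0("merge", l)]] <- m$cache
    dec_out[[l]] <- m$Y
    cur <- m$Y
  }
  p <- net$params
  low_feat <- if (D >= 3) dec_out[[3]] else bott_out
  low_dims <- if (D >= 3) P %/% 4L else bott_dims
  heads <- list(
    full = list(feat = dec_out[[1]], dims = P, size = cfg$out_patch),
    mid = list(feat = dec_out[[2]], dims = P %/% 2L, size = cfg$out_patch %/% 2L),
    low = list(feat = low_feat, dims = low_dims, size = cfg$out_patch %/% 4L))
  preds <- list()
  for (h in names(heads)) {
    hh <- heads[[h]]
    rows <- crop_rows(hh$dims, hh$size)
    out_full <- addcol(hh$feat %*% p[[paste0("head_", h, ".W")]],
                       p[[paste0("head_", h, ".b")]])
    preds[[h]] <- out_full[rows, , drop = FALSE]
    caches[[paste0("head_", h)]] <- list(rows = rows, n = nrow(hh$feat),
                                         dims = hh$dims)
  }
  list(preds = preds,
       cache = if (keep_cache) list(layers = caches, enc_out = enc_out,
                                    dec_out = dec_out, bott = bott_out) else NULL,
       stats_updates = stats_updates)
}

# Backward pass: dpreds is a list(full, mid, low) of gradients on the
# cropped predictions. Returns the parameter gradient list.
net_backward <- function(net, fwd, dpreds) {
  cfg <- net$cfg
  D <- cfg$depth
  P <- cfg$in_patch
  caches <- fwd$cache$layers
  p <- net$params
  grads <- list()
  d_dec <- vector("list", D)
  d_bott <- 0
  for (h in c("full", "mid", "low")) {
    hc <- caches[[paste0("head_", h)]]
    dH <- matrix(0, hc$n, 3)
    dH[hc$rows, ] <- dpreds[[h]]
    feat <- switch(h, full = fwd$cache$dec_out[[1]],
                   mid = fwd$cache$dec_out[[2]],
                   low = if (D >= 3) fwd$cache$dec_out[[3]] else fwd$cache$bott)
    grads[[paste0("head_", h, ".W")]] <- crossprod(feat, dH)
    grads[[paste0("head_", h, ".b")]] <- colSums(dH)
    dfeat <- dH %*% t(p[[paste0("head_", h, ".W")]])
    if (h == "full") {
      d_dec[[1]] <- (d_dec[[1]] %||% 0) + dfeat
    } else if (h == "mid") {
      d_dec[[2]] <- (d_dec[[2]] %||% 0) + dfeat
    } else if (D >= 3) {
      d_dec[[3]] <- (d_dec[[3]] %||% 0) + dfeat
    } else {
      d_bott <- d_bott + dfeat
    }
  }
  d_enc <- vector("list", D)
  for (l in seq_len(D)) {
    dm <- d_dec[[l]]
    if (is.null(dm)) dm <- matrix(0, nrow(fwd$cache$dec_out[[l]]), ncol(fwd$cache$dec_out[[l]]))
    r <- cbr_bwd(net, caches[[paste0("merge", l)]], dm, grads)
    grads <- r$grads
    ch_l <- ncol(fwd$cache$enc_out[[l]])
    d_sk <- r$dX[, seq_len(ch_l), drop = FALSE]
    d_up <- r$dX[, ch_l + seq_len(ch_l), drop = FALSE]
    s <- cbr_bwd(net, caches[[paste0("skip", l)]], d_sk, grads)
    grads <- s$grads
    d_enc[[l]] <- (d_enc[[l]] %||% 0) + s$dX
    u <- deconv_bwd(net, caches[[paste0("up", l)]], d_up, grads)
    grads <- u$grads
    if (l == D) d_bott <- d_bott + u$dX else d_dec[[l + 1]] <- (d_dec[[l + 1]] %||% 0) + u$dX
  }
  b <- cbr_bwd(net, caches[["bott"]], d_bott, grads)
  grads <- b$grads
  d_pooled <- b$dX
  for (l in rev(seq_len(D))) {
    pc <- caches[[paste0("pool", l)]]
    d_from_pool <- cn_maxpool_bwd(d_pooled, pc$idx, pc$n)
    dl <- d_enc[[l]]
    if (is.null(dl)) dl <- 0
    r <- cbr_bwd(net, caches[[paste0("enc", l)]], d_from_pool + dl, grads)
    grads <- r$grads
    d_pooled <- r$dX
  }
  grads
}

#' Dual-guidance training loss on one patch
#'
#' `loss_u` is the sum over the three supervised resolutions of the mean
#' per-voxel Euclidean distance between prediction and the ground-truth
#' field (average-pooled by 2 and 4 with displacement values rescaled to
#' the coarser grid's units). `loss_SSD` is the mean squared intensity
#' difference between the fixed patch and the moving patch warped by the
#' finest prediction. The total is the convex combination
#' `alpha * loss_u + beta * loss_SSD`.
#'
#' @param preds list(full, mid, low) of prediction matrices (rows voxel-major).
#' @param gt ground-truth field patch, `out_patch^3 x 3` matrix (or array).
#' @param moving_patch `in_patch^3` array of moving intensities.
#' @param fixed_patch `out_patch^3` array (or vector) of fixed intensities.
#' @param alpha,beta loss weights with `alpha + beta = 1`.
#' @param cfg the [regnet_config()].
#' @param with_grad also return gradients w.r.t. the predictions.
#' @return list(total, loss_u, loss_u_high, loss_u_mid, loss_u_low,
#'   loss_ssd, grads?).
#' @export
dual_guidance_loss <- function(preds, gt, moving_patch, fixed_patch,
                               alpha, beta, cfg, with_grad = FALSE) {
  stop_if(abs(alpha + beta - 1) > 1e-9, "alpha + beta must equal 1")
  outp <- cfg$out_patch
  if (!is.matrix(gt)) gt <- matrix(gt, ncol = 3)
  stop_if(nrow(gt) != outp^3, "ground-truth patch has wrong size")
  gts <- list(full = gt,
              mid = downsample_field_patch(gt, rep(outp, 3L), 2L),
              low = downsample_field_patch(gt, rep(outp, 3L), 4L))
  lu <- list()
  dU <- list()
  eps <- 1e-12
  squared <- isTRUE(cfg$loss_u_squared)
  for (h in names(gts)) {
    stop_if(nrow(preds[[h]]) != nrow(gts[[h]]),
            "prediction/ground-truth resolution mismatch at level ", h)
    diff <- preds[[h]] - gts[[h]]
    if (squared) {
      lu[[h]] <- mean(rowSums(diff^2))
      if (with_grad) dU[[h]] <- 2 * diff / nrow(diff)
    } else {
      en <- sqrt(rowSums(diff^2))
      lu[[h]] <- mean(en)
      if (with_grad) dU[[h]] <- diff / (pmax(en, eps) * length(en))
    }
  }
  loss_u <- lu$full + lu$mid + lu$low
  # intensity term: warp the moving patch by the finest prediction
  margin <- (cfg$in_patch - outp) %/% 2L
  out_coords <- grid_coords(rep(outp, 3L))
  pts <- out_coords + margin + preds$full
  sg <- sample_trilinear_grad(moving_patch, pts)
  resid <- sg$value - as.vector(fixed_patch)
  loss_ssd <- mean(resid^2)
  out <- list(total = alpha * loss_u + beta * loss_ssd,
              loss_u = loss_u, loss_u_high = lu$full, loss_u_mid = lu$mid,
              loss_u_low = lu$low, loss_ssd = loss_ssd)
  if (with_grad) {
    dssd <- 2 * resid * sg$grad / length(resid)
    out$grads <- list(full = alpha * dU$full + beta * dssd,
                      mid = alpha * dU$mid,
                      low = alpha * dU$low)
  }
  out
}

# ---- training --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' A training pair for the deformation network
#' @param moving,fixed [volume()] objects on one grid.
#' @param guidance a [disp_field()] registering `moving` onto `fixed`
#'   (ground truth from an external registration method or a synthetic
#'   generator).
#' @return an object of class `"training_pair"`.
#' @export
training_pair <- function(moving, fixed, guidance) {
  stopifnot(inherits(moving, "vol3d"), inherits(fixed, "vol3d"),
            inherits(guidance, "dispfield"))
  stop_if(!identical(dim(moving$data), dim(fixed$data)) ||
            !identical(as.integer(dim(moving$data)),
                       as.integer(guidance$reference_shape)),
          "moving, fixed and guidance must share one grid")
  structure(list(moving = moving, fixed = fixed, guidance = guidance),
            class = "training_pair")
}

prepare_pair <- function(pair, tiling) {
  g <- pair$guidance$vectors
  gpad <- lapply(1:3, function(c_) pad_to_tiling(g[, , , c_], tiling))
  list(moving = pad_to_tiling(pair$moving$data, tiling),
       fixed = pad_to_tiling(pair$fixed$data, tiling),
       gt = gpad)
}

extract_tile_job <- function(prep, tiling, t) {
  inp <- tiling$in_patch
  outp <- tiling$out_patch
  ic <- c(tiling$tiles$in_x[t], tiling$tiles$in_y[t], tiling$tiles$in_z[t])
  oc <- c(tiling$tiles$out_x[t], tiling$tiles$out_y[t], tiling$tiles$out_z[t])
  gt <- vapply(prep$gt, function(gcomp) as.vector(extract_block(gcomp, oc, outp)),
               numeric(outp^3))
  list(x = cbind(as.vector(extract_block(prep$moving, ic, inp)),
                 as.vector(extract_block(prep$fixed, ic, inp))),
       fixed = as.vector(extract_block(prep$fixed, oc, outp)),
       gt = gt)
}

#' Train the deformation-prediction network
#'
#' Runs `epochs` epochs of ADAM over all tiles of all training pairs with
#' the dual-guidance loss under the alpha/beta schedule; tile order is
#' reshuffled each epoch from the seed. Training is fully deterministic
#' given the configuration.
#'
#' @param pairs list of [training_pair()] objects on one grid.
#' @param cfg a [regnet_config()].
#' @param net optional pre-built or pre-trained `"regnet"` to continue from.
#' @param lr learning rate (default `cfg$lr_primary`).
#' @param epochs override of `cfg$epochs`.
#' @return an object of class `"regnet_fit"`: list(net, cfg, history) where
#'   `history` has one row per epoch with the mean loss components.
#' @export
train_regnet <- function(pairs, cfg, net = NULL, lr = NULL, epochs = NULL) {
  stop_if(length(pairs) < 1, "need at least one training pair")
  shp <- dim(pairs[[1]]$moving$data)
  for (p in pairs) stop_if(!identical(dim(p$moving$data), shp),
                           "all pairs must share one grid")
  lr <- lr %||% cfg$lr_primary
  epochs <- as.integer(epochs %||% cfg$epochs)
  tiling <- make_tiling(shp, cfg)
  preps <- lapply(pairs, prepare_pair, tiling = tiling)
  net <- net %||% build_network(cfg)
  state <- adam_init(net$params)
  nt <- nrow(tiling$tiles)
  jobs <- expand.grid(pair = seq_along(pairs), tile = seq_len(nt))
  hist <- list()
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(epochs) - 1L) {
      ab <- loss_schedule(min(epoch, cfg$epochs - 1L), cfg)
      ord <- sample(nrow(jobs))
      comp <- c(total = 0, loss_u = 0, loss_ssd = 0)
      for (jid in ord) {
        job <- extract_tile_job(preps[[jobs$pair[jid]]], tiling, jobs$tile[jid])
        fwd <- net_forward(net, job$x, train = TRUE)
        for (nm in names(fwd$stats_updates)) net$stats[[nm]] <- fwd$stats_updates[[nm]]
        mv <- array(job$x[, 1], dim = rep(cfg$in_patch, 3L))
        ls <- dual_guidance_loss(fwd$preds, job$gt, mv, job$fixed,
                                 ab[["alpha"]], ab[["beta"]], cfg,
                                 with_grad = TRUE)
        stop_if(!is.finite(ls$total),
                "training diverged (non-finite loss) at epoch ", epoch)
        grads <- net_backward(net, fwd, ls$grads)
        upd <- adam_step(net$params, grads, state, lr)
        net$params <- upd$params
        state <- upd$state
        comp <- comp + c(ls$total, ls$loss_u, ls$loss_ssd)
      }
      comp <- comp / nrow(jobs)
      hist[[epoch + 1L]] <- data.frame(epoch = epoch, alpha = ab[["alpha"]],
                                       beta = ab[["beta"]], loss_total = comp[1],
                                       loss_u = comp[2], loss_ssd = comp[3])
    }
  })
  structure(list(net = net, cfg = cfg, history = do.call(rbind, hist),
                 template = pairs[[1]]$fixed),
            class = "regnet_fit")
}

#' @export
print.regnet_fit <- function(x, ...) {
  cat(sprintf("<regnet_fit> %d epochs, final loss %.4g (u %.4g, ssd %.4g)\n",
              nrow(x$history), tail(x$history$loss_total, 1),
              tail(x$history$loss_u, 1), tail(x$history$loss_ssd, 1)))
  invisible(x)
}

#' Transfer-train a network for another template
#'
#' Clones the base network's weights and fine-tunes all of them with ADAM
#' at the (very small) transfer learning rate; the base model is left
#' untouched. All networks share one task domain, so a small rate
#' suffices and expedites training.
#'
#' @param base a `"regnet_fit"` (or bare `"regnet"`).
#' @param pairs training pairs for the new template.
#' @param cfg configuration (defaults to the base's).
#' @param lr learning rate (default `cfg$lr_transfer`).
#' @param epochs override of `cfg$epochs`.
#' @return a new `"regnet_fit"`.
#' @export
transfer_train <- function(base, pairs, cfg = NULL, lr = NULL, epochs = NULL) {
  net <- if (inherits(base, "regnet_fit")) base$net else base
  stopifnot(inherits(net, "regnet"))
  cfg <- cfg %||% net$cfg
  lr <- lr %||% cfg$lr_transfer
  if ((!is.null(lr) && lr == 0) || (!is.null(epochs) && epochs == 0)) {
    # zero steps (or zero step size): the transferred network is the base
    # network with the new template attached
    return(structure(list(net = net, cfg = cfg,
                          history = data.frame(epoch = integer(0)),
                          template = pairs[[1]]$fixed),
                     class = "regnet_fit"))
  }
  train_regnet(pairs, cfg, net = net, lr = lr, epochs = epochs)
}

#' Predict the displacement field registering a volume to the template
#'
#' Tiles the volume ([make_tiling()]), runs the network on every input
#' patch in evaluation mode (batch-norm running statistics; deterministic),
#' and assembles the finest-resolution output patches into a field of the
#' volume's shape ([assemble_field()]). Coarser heads exist for deep
#' supervision only and are ignored at inference.
#'
#' @param fit a `"regnet_fit"`; its stored template volume provides the
#'   network's second input channel.
#' @param moving a [volume()] on the template's grid.
#' @param template optional [volume()] overriding the fit's stored template.
#' @return a [disp_field()] with `reference_shape == dim(moving$data)`.
#' @export
predict_field <- function(fit, moving, template = NULL) {
  net <- if (inherits(fit, "regnet_fit")) fit$net else fit
  template <- template %||% fit$template
  stopifnot(inherits(net, "regnet"), inherits(moving, "vol3d"),
            inherits(template, "vol3d"))
  stop_if(!identical(dim(moving$data), dim(template$data)),
          "moving and template must share one grid")
  cfg <- net$cfg
  tiling <- make_tiling(dim(moving$data), cfg)
  mpad <- pad_to_tiling(moving$data, tiling)
  tpad <- pad_to_tiling(template$data, tiling)
  outs <- vector("list", nrow(tiling$tiles))
  for (t in seq_len(nrow(tiling$tiles))) {
    ic <- c(tiling$tiles$in_x[t], tiling$tiles$in_y[t], tiling$tiles$in_z[t])
    x <- cbind(as.vector(extract_block(mpad, ic, tiling$in_patch)),
               as.vector(extract_block(tpad, ic, tiling$in_patch)))
    fwd <- net_forward(net, x, train = FALSE, keep_cache = FALSE)
    outs[[t]] <- fwd$preds$full
  }
  assemble_field(outs, tiling)
}

#' Registration backend backed by per-template trained networks
#'
#' @param fits named list of `"regnet_fit"` objects, one per template id.
#' @param images named list of cohort [volume()] objects.
#' @return a `function(image_id, template_id)` for [initialize_cohort()];
#'   predictions are cached per (image, template).
#' @export
regnet_backend <- function(fits, images) {
  cache <- new.env(parent = emptyenv())
  function(image_id, template_id) {
    stop_if(is.null(fits[[template_id]]), "no trained network for template ",
            template_id)
    key <- paste(image_id, template_id, sep = "\r")
    if (is.null(cache[[key]])) {
      cache[[key]] <- predict_field(fits[[template_id]], images[[image_id]])
    }
    cache[[key]]
  }
}

#' Mean endpoint error between two displacement fields
#'
#' Mean Euclidean norm of the voxelwise difference, optionally restricted
#' to a mask (e.g. [interior_mask()]).
#' @param u,v [disp_field()] objects on one grid.
#' @param mask optional logical array.
#' @return mean endpoint error in voxels.
#' @export
endpoint_error <- function(u, v, mask = NULL) {
  stopifnot(inherits(u, "dispfield"), inherits(v, "dispfield"))
  stop_if(!identical(u$reference_shape, v$reference_shape), "shape mismatch")
  diff <- matrix(u$vectors - v$vectors, ncol = 3)
  en <- sqrt(rowSums(diff^2))
  if (!is.null(mask)) en <- en[as.vector(mask)]
  mean(en)
}
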