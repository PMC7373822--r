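# Independent reference implementations used as oracles. These are coded
# literally (explicit loops, no shared helpers with the package) so that
# agreement with the package is a genuine two-route check.

# literal step-by-step AMG coarsening of one level on a weight matrix
ref_coarsen_level <- function(W, rho) {
  n <- nrow(W)
  S <- vector("list", n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (k in seq_len(n)) if (k != i && abs(W[i, k]) > best) best <- abs(W[i, k])
    s <- integer(0)
    for (j in seq_len(n)) if (j != i && abs(W[i, j]) >= rho * best) s <- c(s, j)
    S[[i]] <- s
  }
  psi <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) if (k != i && i %in% S[[k]]) psi[i] <- psi[i] + 1
  }
  designated <- rep(FALSE, n)
  kind <- rep("", n)
  parent <- rep(NA_integer_, n)
  traces <- list()
  while (!all(designated)) {
    snap <- psi
    snap[designated] <- NA
    traces[[length(traces) + 1]] <- snap
    best_i <- NA_integer_; best_v <- -Inf
    for (i in seq_len(n)) {
      if (!designated[i] && psi[i] > best_v) { best_v <- psi[i]; best_i <- i }
    }
    c0 <- best_i
    designated[c0] <- TRUE
    kind[c0] <- "coarse"
    fines <- integer(0)
    for (k in seq_len(n)) if (!designated[k] && c0 %in% S[[k]]) fines <- c(fines, k)
    for (k in fines) { designated[k] <- TRUE; kind[k] <- "fine"; parent[k] <- c0 }
    for (f in fines) for (j in S[[f]]) if (!designated[j]) psi[j] <- psi[j] + 1
    for (j in S[[c0]]) if (!designated[j]) psi[j] <- psi[j] - 1
  }
  list(coarse = which(kind == "coarse"), parent = parent, traces = traces)
}

# brute-force NCC by explicit double sums
ref_ncc <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# brute-force Dice on label arrays
ref_dice <- function(la, lb, label) {
  v1 <- 0; v2 <- 0; ov <- 0
  for (i in seq_along(la)) {
    a <- la[i] == label
    b <- lb[i] == label
    if (a) v1 <- v1 + 1
    if (b) v2 <- v2 + 1
    if (a && b) ov <- ov + 1
  }
  200 * ov / (v1 + v2)
}

# brute-force boundary extraction (6-connectivity, grid edge = boundary)
ref_surface <- function(lab, label, spacing = c(1, 1, 1)) {
  d <- dim(lab)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (lab[i, j, k] != label) next
    nb <- FALSE
    for (off in list(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) {
        nb <- TRUE; break
      }
      if (lab[ii, jj, kk] != label) { nb <- TRUE; break }
    }
    if (nb) pts <- rbind(pts, (c(i, j, k) - 1) * spacing)
  }
  pts
}

# linear-interpolation percentile of a sorted sample, coded by hand
ref_pctile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# brute-force robust Hausdorff via all-pairs distances
ref_hd <- function(la, lb, label, percentile = 0.95, spacing = c(1, 1, 1)) {
  R <- ref_surface(la, label, spacing)
  S <- ref_surface(lb, label, spacing)
  drs <- numeric(nrow(R))
  for (i in seq_len(nrow(R))) {
    best <- Inf
    for (j in seq_len(nrow(S))) {
      dd <- sqrt(sum((R[i, ] - S[j, ])^2))
      if (dd < best) best <- dd
    }
    drs[i] <- best
  }
  dsr <- numeric(nrow(S))
  for (j in seq_len(nrow(S))) {
    best <- Inf
    for (i in seq_len(nrow(R))) {
      dd <- sqrt(sum((S[j, ] - R[i, ])^2))
      if (dd < best) best <- dd
    }
    dsr[j] <- best
  }
  max(ref_pctile(drs, percentile), ref_pctile(dsr, percentile))
}

# pointwise composition oracle with hand-rolled trilinear sampling
ref_compose_at <- function(u, v, x, y, z) {
  shp <- dim(u)[1:3]
  tri <- function(comp, px, py, pz) {
    px <- min(max(px, 1), shp[1]); py <- min(max(py, 1), shp[2]); pz <- min(max(pz, 1), shp[3])
    x0 <- min(max(floor(px), 1), shp[1] - 1)
    y0 <- min(max(floor(py), 1), shp[2] - 1)
    z0 <- min(max(floor(pz), 1), shp[3] - 1)
    fx <- px - x0; fy <- py - y0; fz <- pz - z0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
      acc <- acc + w * u[x0 + dx, y0 + dy, z0 + dz, comp]
    }
    acc
  }
  vv <- v[x, y, z, ]
  px <- x + vv[1]; py <- y + vv[2]; pz <- z + vv[3]
  vv + c(tri(1, px, py, pz), tri(2, px, py, pz), tri(3, px, py, pz))
}

# random small label volume with a couple of blob structures
random_label_volume <- function(seed, shape = c(16, 16, 16), n_labels = 2) {
  set.seed(seed)
  lab <- array(0L, dim = shape)
  for (l in seq_len(n_labels)) {
    ctr <- runif(3, 5, shape - 4)
    r <- runif(1, 2.2, 4.5)
    gc_ <- as.matrix(expand.grid(x = 1:shape[1], y = 1:shape[2], z = 1:shape[3]))
    inside <- colSums((t(gc_) - ctr)^2) <= r^2
    lab[gc_[inside, , drop = FALSE]] <- l
  }
  label_volume(lab)
}

random_graph <- function(seed, n) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, -1, 1)
  w <- w + t(w)
  diag(w) <- NA
  similarity_graph(sprintf("v%02d", seq_len(n)), w)
}
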