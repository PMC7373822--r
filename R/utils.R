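# Shared internal helpers: grid coordinates, trilinear sampling, Gaussian
# smoothing, and small numeric utilities. Displacements are voxel-unit
# vectors on the image grid throughout (see ?disp_field).

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Logical mask of interior voxels
#'
#' Voxels at least `margin` voxels away from every face of the grid. Field
#' algebra near the boundary is dominated by the nearest-edge extension
#' rule, so accuracy guarantees (e.g. inversion residuals) are stated over
#' the interior only.
#'
#' @param shape integer vector of length 3, grid dimensions.
#' @param margin non-negative integer margin in voxels.
#' @return logical array of dimension `shape`.
#' @export
interior_mask <- function(shape, margin) {
  stopifnot(length(shape) == 3, margin >= 0)
  m <- array(FALSE, dim = shape)
  lo <- pmin(margin + 1, shape)
  hi <- pmax(shape - margin, 0)
  if (all(lo <= hi)) m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# n x 3 matrix of 1-based voxel coordinates in R array order (x fastest)
grid_coords <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]), shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3]),
    rep(seq_len(shape[3]), each = shape[1] * shape[2])
  )
}

# Trilinear sampling of a 3D array at fractional 1-based coordinates
# (n x 3). Out-of-grid coordinates are clamped to the nearest edge.
sample_trilinear <- function(arr, pts) {
  d <- dim(arr)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(y), d[2] - 1L); y0 <- pmax(y0, 1L)
  z0 <- pmin(floor(z), d[3] - 1L); z0 <- pmax(z0, 1L)
  if (d[1] == 1L) x0 <- rep(1L, length(x))
  if (d[2] == 1L) y0 <- rep(1L, length(y))
  if (d[3] == 1L) z0 <- rep(1L, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  id <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
  v <- as.vector(arr)
  v[id(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[id(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    v[id(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
    v[id(x1, y1, z0)] * fx * fy * (1 - fz) +
    v[id(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    v[id(x1, y0, z1)] * fx * (1 - fy) * fz +
    v[id(x0, y1, z1)] * (1 - fx) * fy * fz +
    v[id(x1, y1, z1)] * fx * fy * fz
}

# Trilinear sampling with the spatial gradient of the interpolant,
# needed for the image-similarity term of the training loss.
# Returns list(value, grad) with grad an n x 3 matrix.
sample_trilinear_grad <- function(arr, pts) {
  d <- dim(arr)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmax(pmin(floor(x), d[1] - 1L), 1L)
  y0 <- pmax(pmin(floor(y), d[2] - 1L), 1L)
  z0 <- pmax(pmin(floor(z), d[3] - 1L), 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  id <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
  v <- as.vector(arr)
  c000 <- v[id(x0, y0, z0)]; c100 <- v[id(x1, y0, z0)]
  c010 <- v[id(x0, y1, z0)]; c110 <- v[id(x1, y1, z0)]
  c001 <- v[id(x0, y0, z1)]; c101 <- v[id(x1, y0, z1)]
  c011 <- v[id(x0, y1, z1)]; c111 <- v[id(x1, y1, z1)]
  val <- c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy * (1 - fz) + c110 * fx * fy * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz + c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy * fz + c111 * fx * fy * fz
  gx <- (c100 - c000) * (1 - fy) * (1 - fz) + (c110 - c010) * fy * (1 - fz) +
    (c101 - c001) * (1 - fy) * fz + (c111 - c011) * fy * fz
  gy <- (c010 - c000) * (1 - fx) * (1 - fz) + (c110 - c100) * fx * (1 - fz) +
    (c011 - c001) * (1 - fx) * fz + (c111 - c101) * fx * fz
  gz <- (c001 - c000) * (1 - fx) * (1 - fy) + (c101 - c100) * fx * (1 - fy) +
    (c011 - c010) * (1 - fx) * fy + (c111 - c110) * fx * fy
  list(value = val, grad = cbind(gx, gy, gz))
}

# Nearest-neighbour sampling (labels); coordinates clamped to the grid.
sample_nearest <- function(arr, pts) {
  d <- dim(arr)
  i <- pmin(pmax(round(pts[, 1]), 1), d[1])
  j <- pmin(pmax(round(pts[, 2]), 1), d[2])
  k <- pmin(pmax(round(pts[, 3]), 1), d[3])
  as.vector(arr)[i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)]
}

# Separable Gaussian smoothing of a 3D array via per-axis dense
# convolution matrices with reflected boundaries. Exact and fast for the
# modest grids used here.
gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  D <- outer(idx, idx, function(i, j) abs(i - j))
  K <- exp(-D^2 / (2 * sigma^2))
  K / rowSums(K)  # row-normalized: constant fields are preserved
}

gaussian_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  if (sigma <= 0) return(arr)
  K1 <- gaussian_kernel_matrix(d[1], sigma)
  K2 <- gaussian_kernel_matrix(d[2], sigma)
  K3 <- gaussian_kernel_matrix(d[3], sigma)
  m <- matrix(arr, nrow = d[1])
  m <- K1 %*% m
  a <- array(m, dim = d)
  a <- aperm(a, c(2, 1, 3))
  m <- K2 %*% matrix(a, nrow = d[2])
  a <- aperm(array(m, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  m <- K3 %*% matrix(a, nrow = d[3])
  aperm(array(m, dim = d[c(3, 2, 1)]), c(3, 2, 1))
}

# Adjusted Rand index between two labelings (same length).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
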