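# Internal helpers shared across modules. Array convention throughout the
# package: intensity arrays are indexed [z, x, y] with z the axial (depth)
# index, x the fast lateral axis and y the slow (B-scan) axis. Depths are
# 0-based voxel-center positions: depth_um = (z - 0.5) * dzUm.

clampv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

oddize <- function(k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k + 1L else k
}

# circular 2D shift: positive dz moves content toward larger row index
# (deeper), positive dx toward larger column index
circShift2D <- function(m, dz, dx) {
  nr <- nrow(m)
  nc <- ncol(m)
  dz <- ((dz %% nr) + nr) %% nr
  dx <- ((dx %% nc) + nc) %% nc
  if (dz != 0) m <- m[((seq_len(nr) - 1L - dz) %% nr) + 1L, , drop = FALSE]
  if (dx != 0) m <- m[, ((seq_len(nc) - 1L - dx) %% nc) + 1L, drop = FALSE]
  m
}

# index of first TRUE per column of a logical matrix; NA when none
firstTrue <- function(B) {
  storage.mode(B) <- "integer"
  i <- max.col(t(B), ties.method = "first")
  i[colSums(B) == 0L] <- NA_integer_
  i
}

# per-column argmax of a numeric matrix (first tie wins)
colArgmax <- function(M) max.col(t(M), ties.method = "first")

gaussKernel1D <- function(sigma, deriv = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv == 0L) return(g)
  if (deriv == 1L) return(-x / sigma^2 * g)
  (x^2 - sigma^2) / sigma^4 * g
}

# smooth each column of a matrix with a circular 1D kernel
smoothCols <- function(M, kernel) {
  out <- stats::filter(M, kernel, circular = TRUE)
  matrix(as.numeric(out), nrow = nrow(M), ncol = ncol(M))
}

# running-median smoothing of a 2D map, rows then columns
medSmoothMap <- function(M, k = 5L) {
  kr <- min(oddize(k), oddize(nrow(M) - (nrow(M) + 1L) %% 2L))
  kc <- min(oddize(k), oddize(ncol(M) - (ncol(M) + 1L) %% 2L))
  if (kr >= 3L && nrow(M) >= kr)
    M <- apply(M, 2, stats::runmed, k = kr, endrule = "median")
  if (kc >= 3L && ncol(M) >= kc)
    M <- t(apply(M, 1, stats::runmed, k = kc, endrule = "median"))
  M
}

# separable Gaussian(-derivative) filtering of a 2D image via EBImage FFT
# convolution; dx/dy are the derivative orders along rows/columns. Kernels
# are cropped to fit small images.
gaussFilter2D <- function(img, sigma, dx = 0L, dy = 0L) {
  kx <- gaussKernel1D(sigma, dx)
  ky <- gaussKernel1D(sigma, dy)
  crop <- function(k, n) {
    r <- (length(k) - 1L) %/% 2L
    rmax <- (n - 1L) %/% 2L
    if (r > rmax) k[(r - rmax + 1L):(r + rmax + 1L)] else k
  }
  kx <- crop(kx, nrow(img))
  ky <- crop(ky, ncol(img))
  EBImage::filter2(img, outer(kx, ky), boundary = "circular")
}

boxBlur2D <- function(img, r) {
  k <- matrix(1, 2L * r + 1L, 2L * r + 1L)
  k <- k / sum(k)
  EBImage::filter2(img, k, boundary = "circular")
}

# smooth radial top-hat: 1 well inside radius, 0.5 at the radius, 0 beyond
# radius + edge/2 (cosine roll-off of full width `edge`)
softDisc <- function(r, radius, edge) {
  if (radius <= 0) return(rep(0, length(r)))
  t <- (r - (radius - edge / 2)) / edge
  w <- ifelse(t <= 0, 1, ifelse(t >= 1, 0, 0.5 * (1 + cos(pi * t))))
  w
}

# circular smoothing of a 3D array along one dimension, slice by slice to
# avoid large transposition copies
smoothAlongDim <- function(A, kernel, dim) {
  d <- dim(A)
  if (dim == 2L) {
    for (y in seq_len(d[3]))
      A[, , y] <- t(smoothCols(t(A[, , y]), kernel))
  } else if (dim == 3L) {
    for (x in seq_len(d[2]))
      A[, x, ] <- t(smoothCols(t(A[, x, ]), kernel))
  } else stop("unsupported dimension")
  A
}

# per-column integer circular shift of a [z, ...] array so the reference
# surface (um depth map) sits at row fixIdx; inverse = TRUE undoes it
flattenToSurface <- function(arr, refUm, dzUm, fixIdx, inverse = FALSE) {
  d <- dim(arr)
  nz <- d[1]
  z0 <- round(as.numeric(refUm) / dzUm + 0.5) - fixIdx
  if (inverse) z0 <- -z0
  A <- arr
  dim(A) <- c(nz, length(z0))
  out <- A
  zi <- seq_len(nz) - 1L
  for (j in which(z0 != 0L))
    out[, j] <- A[((zi + z0[j]) %% nz) + 1L, j]
  dim(out) <- d
  out
}

# piecewise-linear interpolation with flat extrapolation
interpFlat <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# deterministic per-timepoint RNG stream offset (kept well below 2^31)
seedAt <- function(seed, timepoint) {
  as.integer((as.numeric(seed) + round(1000 * timepoint)) %% 2147483587)
}
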