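# Internal helpers shared across modules.

# Linear (column-major) indices of mask voxels within the grid.
maskLinearIndices <- function(mask) {
  g <- mask@gridShape
  co <- mask@coords
  (co[, 3L] - 1L) * (g[1L] * g[2L]) + (co[, 2L] - 1L) * g[1L] + co[, 1L]
}

# Voxel (1-based, R indexing) -> world mm via a NIfTI affine (0-based).
voxelToWorld <- function(coords, affine) {
  co0 <- cbind(coords - 1L, 1)
  t(affine %*% t(co0))[, 1:3, drop = FALSE]
}

# Correlations are clamped just inside (-1, 1) before arctanh so that
# degenerate perfect correlations stay finite and storable.
CLAMP_EPS <- 1e-7

clampCorrelation <- function(r) pmin(pmax(r, -1 + CLAMP_EPS), 1 - CLAMP_EPS)

# Masked time series as a voxels x frames matrix, in mask order.
maskedSeries <- function(vs, mask) {
  d <- dim(vs@data)
  matrix(vs@data, prod(d[1:3]), d[4L])[maskLinearIndices(mask), , drop = FALSE]
}

# Separable Gaussian smoothing of each frame of a 4D array, as three
# tensor-mode products with a truncated kernel matrix. Rows are scaled
# to unit L2 norm, so smoothing white noise introduces spatial
# correlation without changing the marginal voxel variance — the noise
# SD a caller sets is the SD of the smoothed field.
smoothFrames <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  d <- dim(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    n <- d[axis]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(3 * sigma)] <- 0
    K <- K / sqrt(rowSums(K * K))
    perm <- c(axis, setdiff(1:4, axis))
    a <- aperm(arr, perm)
    pd <- dim(a)
    a <- K %*% matrix(a, n)
    dim(a) <- pd
    arr <- aperm(a, order(perm))
  }
  arr
}

# Deterministic per-stage seed fan-out from a single global seed, so each
# pipeline stage is independently reproducible. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + h * 10007) %% 2147483647)
}

# Embed a per-mask-voxel vector into a full 3D grid (background 0).
maskToVolume <- function(values, mask) {
  vol <- array(0, dim = mask@gridShape)
  vol[maskLinearIndices(mask)] <- values
  vol
}

formatPct <- function(x) sprintf("%.2f%%", x)
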