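#' Fisher r-to-z transformation
#'
#' Variance-stabilising transform `z = arctanh(r)` applied to Pearson
#' correlation coefficients, used to improve the normality of GFC values
#' before group statistics. Correlations are clamped just inside
#' (-1, 1) (at 1 - 1e-7) so perfect correlations map to a large finite
#' value instead of infinity.
#'
#' @param r numeric vector of correlations in `[-1, 1]`. Values outside
#'   that range by more than 1e-9 are an error.
#' @return `arctanh(clamp(r))`, the same shape as `r`. Strictly
#'   increasing and odd.
#' @examples
#' fisherZ(c(-0.5, 0, 0.5))
#' @export
fisherZ <- function(r) {
  if (any(!is.finite(r))) stop("non-finite correlation passed to fisherZ()")
  if (any(abs(r) > 1 + 1e-9))
    stop("correlation outside [-1, 1]: ", format(r[which.max(abs(r))]))
  atanh(clampCorrelation(r))
}

#' Build a gray-matter mask by strict probability thresholding
#'
#' Retains voxels whose gray-matter probability strictly exceeds
#' `threshold` (default 0.2, the conventional SPM gray-matter cutoff used
#' to suppress voxels whose correlations would be dominated by noise).
#' Voxel ordering is deterministic: the first axis varies fastest.
#'
#' @param probabilityMap 3D array of probabilities in `[0, 1]`.
#' @param threshold probability cutoff in `[0, 1)`; strict inequality.
#' @param affine optional 4x4 voxel-to-world transform carried along for
#'   MNI coordinate reporting; defaults to identity.
#' @return a [GrayMask-class].
#' @examples
#' prob <- array(runif(64), dim = c(4, 4, 4))
#' m <- buildGrayMask(prob, 0.2)
#' maskSize(m) == sum(prob > 0.2)
#' @export
buildGrayMask <- function(probabilityMap, threshold = 0.2, affine = diag(4)) {
  if (length(dim(probabilityMap)) != 3L)
    stop("probabilityMap must be a 3D array")
  if (any(probabilityMap < 0 | probabilityMap > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  keep <- which(probabilityMap > threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stop(sprintf("empty gray-matter mask at threshold %g", threshold))
  dimnames(keep) <- NULL
  new("GrayMask", coords = keep,
      gridShape = as.integer(dim(probabilityMap)),
      threshold = threshold, affine = affine)
}

#' Drop mask voxels with (near-)constant time series
#'
#' GFC is undefined for voxels without temporal variance; this returns a
#' shrunken mask excluding voxels whose variance falls below `tol`
#' (squared intensity units) and reports how many were removed.
#'
#' @param vs a [VolumeSeries-class].
#' @param mask a [GrayMask-class] on the same grid.
#' @param tol variance tolerance; default 1e-12.
#' @return a [GrayMask-class]; errors if nothing would remain.
#' @export
dropConstantVoxels <- function(vs, mask, tol = 1e-12) {
  X <- maskedSeries(vs, mask)
  v <- rowVarsFast(X)
  drop <- v < tol
  if (all(drop)) stop("all mask voxels are constant; nothing to keep")
  if (any(drop))
    message(sum(drop), " constant voxel(s) removed from mask")
  if (!any(drop)) return(mask)
  new("GrayMask", coords = mask@coords[!drop, , drop = FALSE],
      gridShape = mask@gridShape, threshold = mask@threshold,
      affine = mask@affine)
}

rowVarsFast <- function(X) {
  n <- ncol(X)
  mu <- rowMeans(X)
  (rowSums(X * X) - n * mu * mu) / (n - 1)
}

#' Minimal optional time-series preprocessing
#'
#' The canonical input to [computeGFC()] is an already-preprocessed BOLD
#' series; this convenience stage offers per-voxel linear detrending,
#' least-squares removal of the six rigid-body motion regressors, and a
#' discrete-Fourier band-pass, applied in that fixed order. All steps are
#' off by default.
#'
#' @param vs a [VolumeSeries-class].
#' @param motion a [MotionTrace-class] with one row per frame (required
#'   when `regressMotion = TRUE`).
#' @param detrend remove a per-voxel linear trend?
#' @param bandpass `NULL`, or `c(low, high)` in Hz with
#'   `0 <= low < high < 1/(2 tr)`; frequency bins with
#'   `low <= f <= high` are kept.
#' @param regressMotion regress out the 6 motion parameters (plus
#'   intercept)?
#' @return a [VolumeSeries-class] with the same dimensions.
#' @export
preprocessMinimal <- function(vs, motion = NULL, detrend = FALSE,
                              bandpass = NULL, regressMotion = FALSE) {
  d <- dim(vs@data)
  nT <- d[4L]
  X <- t(matrix(vs@data, prod(d[1:3]), nT))  # frames x voxels

  if (detrend) {
    D <- cbind(1, seq_len(nT))
    X <- X - D %*% qr.coef(qr(D), X)
  }
  if (regressMotion) {
    if (is.null(motion)) stop("regressMotion = TRUE requires a motion trace")
    if (nrow(motion@params) != nT)
      stop("motion trace rows must equal frame count")
    M <- cbind(1, motion@params)
    X <- X - M %*% qr.coef(qr(M), X)
  }
  if (!is.null(bandpass)) {
    nyq <- 1 / (2 * vs@tr)
    lo <- bandpass[1L]; hi <- bandpass[2L]
    if (lo < 0 || lo >= hi) stop("bandpass must satisfy 0 <= low < high")
    if (hi >= nyq)
      stop(sprintf("bandpass high %g Hz must be below Nyquist %g Hz", hi, nyq))
    k <- 0:(nT - 1)
    f <- pmin(k, nT - k) / (nT * vs@tr)
    keep <- f >= lo & f <= hi
    F <- stats::mvfft(X)
    F[!keep, ] <- 0
    X <- Re(stats::mvfft(F, inverse = TRUE)) / nT
  }
  out <- vs
  out@data <- array(t(X), dim = d)
  out
}

#' Compute a voxel-wise global-brain functional connectivity map
#'
#' The GFC of a voxel is the mean Pearson correlation between its time
#' series and the series of all *other* voxels in the gray-matter mask
#' (self-correlation excluded; positive and negative correlations enter
#' the average in signed form), Fisher r-to-z transformed.
#'
#' Two z-transform orders are supported. `"z_of_mean_r"` (default)
#' averages the correlations first and transforms the mean; it admits an
#' exact O(V*T) reformulation: with each masked series standardised to
#' zero mean and unit L2 norm (`u_i`), the row sums of the correlation
#' matrix are `u_i . S` where `S = sum_j u_j`, so the self-excluded mean
#' is `(u_i . S - 1) / (V - 1)`. `"mean_of_z"` transforms every pairwise
#' correlation first and averages the z values; it is computed in voxel
#' blocks to bound memory at O(block * V).
#'
#' @param vs a [VolumeSeries-class].
#' @param mask a [GrayMask-class] on the same grid; every mask voxel must
#'   have non-zero temporal variance (see [dropConstantVoxels()]).
#' @param zOrder `"z_of_mean_r"` or `"mean_of_z"`.
#' @param blockSize voxels per block for the `"mean_of_z"` path.
#' @return a [GFCMap-class] of finite Fisher-z values in mask order.
#' @examples
#' set.seed(1)
#' vs <- new("VolumeSeries",
#'           data = array(rnorm(4 * 4 * 4 * 30), dim = c(4, 4, 4, 30)),
#'           affine = diag(4), tr = 2, subjectId = "demo")
#' m <- buildGrayMask(array(1, dim = c(4, 4, 4)), 0.2)
#' g <- computeGFC(vs, m)
#' summary(gfcValues(g))
#' @export
computeGFC <- function(vs, mask, zOrder = c("z_of_mean_r", "mean_of_z"),
                       blockSize = 512L) {
  zOrder <- match.arg(zOrder)
  if (!identical(as.integer(dim(vs@data)[1:3]), mask@gridShape))
    stop("mask grid does not match the volume grid")
  X <- maskedSeries(vs, mask)
  V <- nrow(X)
  if (V < 2L) stop("GFC needs at least 2 mask voxels")
  v <- rowVarsFast(X)
  if (any(v < 1e-12)) {
    bad <- which(v < 1e-12)
    co <- mask@coords[head(bad, 5L), , drop = FALSE]
    stop("zero-variance mask voxel(s) at: ",
         paste(apply(co, 1L, paste, collapse = ","), collapse = "; "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
         "; use dropConstantVoxels() first")
  }
  U <- X - rowMeans(X)
  U <- U / sqrt(rowSums(U * U))

  if (zOrder == "z_of_mean_r") {
    S <- colSums(U)
    meanR <- (as.vector(U %*% S) - 1) / (V - 1)
    values <- atanh(clampCorrelation(meanR))
  } else {
    selfZ <- atanh(1 - CLAMP_EPS)
    values <- numeric(V)
    start <- 1L
    while (start <= V) {
      idx <- start:min(start + blockSize - 1L, V)
      R <- tcrossprod(U[idx, , drop = FALSE], U)
      zs <- rowSums(atanh(clampCorrelation(R)))
      values[idx] <- (zs - selfZ) / (V - 1)
      start <- start + blockSize
    }
  }
  new("GFCMap", values = values, subjectId = vs@subjectId,
      zOrder = zOrder, mask = mask)
}

#' Assemble per-subject GFC maps into a GFCExperiment
#'
#' Stacks per-subject [GFCMap-class] objects (which must share one mask
#' and z-order) into a [GFCExperiment-class]: a SummarizedExperiment with
#' mask voxels as rows and subjects as columns, ready for voxel-wise
#' group inference.
#'
#' @param maps list of [GFCMap-class], one per subject.
#' @param subjects optional data.frame of per-subject covariates
#'   (`id`, `group`, ...); matched to the maps by `id` when present,
#'   otherwise taken in map order.
#' @return a [GFCExperiment-class].
#' @export
gfcExperiment <- function(maps, subjects = NULL) {
  if (!length(maps)) stop("no maps supplied")
  mask <- maps[[1L]]@mask
  zo <- maps[[1L]]@zOrder
  for (m in maps) {
    if (!identical(m@mask@coords, mask@coords))
      stop("all maps must share one mask")
    if (!identical(m@zOrder, zo)) stop("all maps must share one z-order")
  }
  ids <- vapply(maps, function(m) m@subjectId, character(1))
  mat <- vapply(maps, function(m) m@values, numeric(maskSize(mask)))
  dim(mat) <- c(maskSize(mask), length(maps))
  colnames(mat) <- ids
  cd <- if (is.null(subjects)) {
    S4Vectors::DataFrame(id = ids, row.names = ids)
  } else {
    if (!"id" %in% names(subjects)) stop("subjects table needs an 'id' column")
    if (!all(ids %in% subjects$id))
      stop("subjects table is missing map subject(s): ",
           paste(setdiff(ids, subjects$id), collapse = ", "))
    S4Vectors::DataFrame(subjects[match(ids, subjects$id), , drop = FALSE],
                         row.names = ids)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gfc = mat),
    rowData = S4Vectors::DataFrame(x = mask@coords[, 1L],
                                   y = mask@coords[, 2L],
                                   z = mask@coords[, 3L]),
    colData = cd,
    metadata = list(mask = mask, zOrder = zo,
                    gmThreshold = mask@threshold)
  )
  new("GFCExperiment", se)
}
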