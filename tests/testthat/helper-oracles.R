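# Independent oracles kept deliberately naive: each reimplements the
# textbook definition with loops / closed forms, never the package's
# fast path.

# All-pairs GFC by explicit correlation matrix (O(V^2 T)).
bruteForceGFC <- function(X, zOrder = "z_of_mean_r", eps = 1e-7) {
  R <- cor(t(X))
  V <- nrow(X)
  clamp <- function(r) pmin(pmax(r, -1 + eps), 1 - eps)
  if (zOrder == "z_of_mean_r") {
    meanR <- (rowSums(R) - 1) / (V - 1)
    atanh(clamp(meanR))
  } else {
    (rowSums(atanh(clamp(R))) - atanh(1 - eps)) / (V - 1)
  }
}

# Frame-wise displacement by an explicit per-frame loop.
fdByLoop <- function(params, radius = 50) {
  out <- numeric(nrow(params))
  for (t in 2:nrow(params)) {
    d <- params[t, ] - params[t - 1, ]
    out[t] <- sum(abs(d[1:3])) + radius * sum(abs(d[4:6]))
  }
  out
}

# Classical pooled-variance two-sample t statistic (group1 - group2).
pooledT <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Pearson r from raw sums.
pearsonBySums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Naive Freedman-Lane permutation null: explicitly form each permuted
# response and refit the full model voxel by voxel via lm-style algebra.
naiveFreedmanLaneMaxT <- function(Y, X, gcol, nPerm, seed) {
  Z <- X[, -gcol, drop = FALSE]
  Qz <- qr.Q(qr(Z))
  E <- Y - (Y %*% Qz) %*% t(Qz)
  Fit <- Y - E
  XtXi <- chol2inv(chol(crossprod(X)))
  df <- ncol(Y) - ncol(X)
  set.seed(seed)
  out <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    Yb <- Fit + E[, sample.int(ncol(Y))]
    tb <- apply(Yb, 1L, function(y) {
      beta <- XtXi %*% crossprod(X, y)
      res <- y - X %*% beta
      se <- sqrt(XtXi[gcol, gcol] * sum(res^2) / df)
      beta[gcol] / se
    })
    out[b] <- max(abs(tb))
  }
  out
}

maskLinearIndicesOracle <- function(m) {
  co <- maskCoords(m); g <- gridShape(m)
  (co[, 3] - 1) * g[1] * g[2] + (co[, 2] - 1) * g[1] + co[, 1]
}

# A small, fast synthetic study for unit tests.
smallCohortSpec <- function(seed = 1L, ...) {
  args <- list(nPatients = 6L, nControls = 6L, gridShape = c(10L, 10L, 10L),
               nFrames = 40L, nHighMotion = 1L, hubCenter = c(5L, 5L, 5L),
               hubRadius = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohortSpec, args)
}

# Wrap a voxels x subjects matrix as a GFCExperiment on a trivial mask.
matrixExperiment <- function(Y, subjects = NULL, gridShape = NULL) {
  V <- nrow(Y)
  if (is.null(gridShape)) {
    side <- ceiling(V^(1 / 3))
    gridShape <- c(side, side, ceiling(V / side^2))
  }
  prob <- array(0, dim = gridShape)
  prob[seq_len(V)] <- 0.9
  mask <- buildGrayMask(prob, 0.2)
  n <- ncol(Y)
  if (is.null(subjects))
    subjects <- data.frame(id = sprintf("s%03d", seq_len(n)),
                           group = rep(c("patient", "control"),
                                       length.out = n))
  maps <- lapply(seq_len(n), function(i)
    new("GFCMap", values = Y[, i], subjectId = subjects$id[i],
        zOrder = "z_of_mean_r", mask = mask))
  gfcExperiment(maps, subjects)
}

randomVolumeSeries <- function(dims, seed, tr = 2) {
  set.seed(seed)
  new("VolumeSeries", data = array(rnorm(prod(dims)), dim = dims),
      affine = diag(4), tr = tr, subjectId = sprintf("rand-%d", seed))
}
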