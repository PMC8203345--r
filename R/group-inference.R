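#' Build the voxel-wise design matrix
#'
#' Columns: intercept, group indicator (patient = 1, control = 0), then
#' the requested nuisance covariates. Continuous covariates are centered
#' so the intercept stays interpretable; `sex` is coded 0/1 (first level
#' alphabetically = 0) and then centered like the rest.
#'
#' @param subjects data.frame with at least `id` and `group`
#'   (`"patient"` / `"control"`) plus any covariate columns.
#' @param covariates character vector of covariate column names (default
#'   the study's nuisance set: age, sex, education, mean FD).
#' @return numeric matrix (subjects x columns) with column names and a
#'   `"groupColumn"` attribute marking the contrast column.
#' @export
designMatrix <- function(subjects,
                         covariates = c("age", "sex", "education", "mean_fd")) {
  if (!all(c("id", "group") %in% names(subjects)))
    stop("subjects table needs 'id' and 'group' columns")
  grp <- as.character(subjects$group)
  if (!all(grp %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  if (length(unique(grp)) < 2L)
    stop("design needs both groups present")
  X <- cbind(intercept = 1, group = as.numeric(grp == "patient"))
  for (cv in covariates) {
    if (!cv %in% names(subjects))
      stop("covariate column missing from subjects table: ", cv)
    v <- subjects[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, scale(v, scale = FALSE)[, 1L])
    colnames(X)[ncol(X)] <- cv
  }
  rownames(X) <- subjects$id
  attr(X, "groupColumn") <- 2L
  X
}

checkDesignRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(q)
}

# Shared core: group-contrast t statistics for a V x N response matrix.
# Uses the identity RSS = rowSums(Y^2) - rowSums((YQ)^2) with Q the thin
# orthonormal basis of the design, and the contrast estimate Y a with
# a = X (X'X)^-1 e_g, so each permutation costs two tall-thin products.
glmTStats <- function(Y, X, gcol, Q = NULL, a = NULL, vfac = NULL) {
  n <- ncol(Y); p <- ncol(X); df <- n - p
  if (is.null(Q)) Q <- qr.Q(qr(X))
  if (is.null(a) || is.null(vfac)) {
    XtXi <- chol2inv(chol(crossprod(X)))
    a <- as.vector(X %*% XtXi[, gcol])
    vfac <- XtXi[gcol, gcol]
  }
  est <- as.vector(Y %*% a)
  ss <- rowSums(Y * Y)
  rss <- pmax(ss - rowSums((Y %*% Q)^2), 0)
  # residual variance that is zero up to rounding is treated as zero; a
  # zero contrast estimate then gives t = 0 rather than 0/0
  noVar <- rss <= 1e-10 * pmax(ss, 1e-300)
  se <- sqrt(vfac * rss / df)
  t <- ifelse(!noVar, est / se,
              ifelse(abs(est) <= 1e-10 * sqrt(pmax(ss, 1)), 0,
                     sign(est) * Inf))
  list(t = t, df = df)
}

#' Voxel-wise GLM: two-sample comparison with nuisance covariates
#'
#' Ordinary least squares of each voxel's Fisher-z GFC on the design;
#' the reported t tests the group column (patients - controls), two-sided,
#' with `df = n_subjects - n_design_columns`. With an intercept-plus-group
#' design this reduces exactly to the classical pooled-variance two-sample
#' t test. Voxels where the residual variance and the contrast estimate
#' are both zero get t = 0 (p = 1) rather than 0/0.
#'
#' @param gfce a [GFCExperiment-class].
#' @param design matrix from [designMatrix()] (rows must align with the
#'   experiment's columns).
#' @return a [GFCStatMap-class].
#' @export
fitVoxelwiseGLM <- function(gfce, design) {
  Y <- SummarizedExperiment::assay(gfce, "gfc")
  if (nrow(design) != ncol(Y))
    stop("design rows must match the number of subjects in the experiment")
  if (!is.null(rownames(design)) &&
      !identical(rownames(design), colnames(Y)))
    stop("design row order does not match subject order")
  checkDesignRank(design)
  gcol <- attr(design, "groupColumn")
  if (is.null(gcol)) gcol <- match("group", colnames(design))
  fit <- glmTStats(Y, design, gcol)
  p <- 2 * pt(-abs(fit$t), fit$df)
  p[fit$t == 0] <- 1
  p <- pmax(p, .Machine$double.xmin)
  new("GFCStatMap", t = as.numeric(fit$t), p = as.numeric(p),
      df = fit$df, contrast = "patients - controls",
      mask = S4Vectors::metadata(gfce)$mask)
}

#' Family-wise-error correction for the voxel-wise t map
#'
#' `permutation_maxT` (default): Freedman-Lane scheme. The nuisance
#' part of the design (everything but the group column) is fitted and
#' its residuals permuted over subjects; each permuted response is refit
#' against the full design and the maximum |t| over the mask recorded.
#' The corrected threshold is the empirical `1 - alpha` quantile (type 1)
#' of that max-|t| null, so with `alpha = 1 - 1/B` the threshold is the
#' null's minimum. `bonferroni`: the per-voxel p threshold is
#' `alpha / n_mask_voxels`, converted to an equivalent |t| threshold.
#' Voxels with |t| strictly above the threshold are significant.
#'
#' @param stat a [GFCStatMap-class] from [fitVoxelwiseGLM()].
#' @param gfce the [GFCExperiment-class] the map was fit on.
#' @param design the same design matrix.
#' @param method `"permutation_maxT"` or `"bonferroni"`.
#' @param alpha family-wise error rate, in (0, 1).
#' @param nPermutations permutations for the maxT null (>= 100).
#' @param seed RNG seed; the permutation schedule is a pure function of
#'   it.
#' @return an [FweResult-class].
#' @export
fweCorrect <- function(stat, gfce, design,
                       method = c("permutation_maxT", "bonferroni"),
                       alpha = 0.05, nPermutations = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  tobs <- stat@t
  if (method == "bonferroni") {
    thr <- qt(1 - (alpha / length(tobs)) / 2, stat@df)
    return(new("FweResult", method = method, nPermutations = 0L,
               alpha = alpha, threshold = thr,
               significant = abs(tobs) > thr, maxT = numeric(),
               seed = as.integer(seed)))
  }
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L)
    stop("permutation maxT needs at least 100 permutations")
  Y <- SummarizedExperiment::assay(gfce, "gfc")
  gcol <- attr(design, "groupColumn")
  if (is.null(gcol)) gcol <- match("group", colnames(design))
  n <- ncol(Y)
  df <- n - ncol(design)
  Z <- design[, -gcol, drop = FALSE]
  Qz <- qr.Q(qr(Z))
  A <- Y %*% Qz                    # nuisance fit is the rank-pz product A Qz'
  E <- Y - A %*% t(Qz)             # nuisance residuals, permuted over subjects
  Q <- qr.Q(qr(design))
  XtXi <- chol2inv(chol(crossprod(design)))
  a <- as.vector(design %*% XtXi[, gcol])
  vfac <- XtXi[gcol, gcol]
  pz <- ncol(Qz); p <- ncol(Q)

  # Permutation-invariant pieces. For permuted data Y* = A Qz' + E P the
  # contrast estimate, the projection onto the design and the row sums of
  # squares all reduce to E %*% (permuted small matrices), so each
  # permutation costs a single V x n by n x (1 + p + pz) product.
  estFit <- as.vector(A %*% crossprod(Qz, a))
  CFit <- A %*% crossprod(Qz, Q)
  rsFix <- rowSums(A * A) + rowSums(E * E)  # Qz orthonormal: ||A Qz'||^2 rows

  set.seed(as.integer(seed))
  maxT <- numeric(nPermutations)
  M <- matrix(0, n, 1L + p + pz)
  for (b in seq_len(nPermutations)) {
    perm <- sample.int(n)
    M[perm, 1L] <- a
    M[perm, 2:(p + 1L)] <- Q
    M[perm, (p + 2L):(1L + p + pz)] <- Qz
    EM <- E %*% M
    est <- estFit + EM[, 1L]
    C <- CFit + EM[, 2:(p + 1L), drop = FALSE]
    rsY <- rsFix + 2 * rowSums(A * EM[, (p + 2L):(1L + p + pz),
                                      drop = FALSE])
    rss <- pmax(rsY - rowSums(C * C), 0)
    se <- sqrt(vfac * rss / df)
    tb <- ifelse(se > 0, est / se, 0)
    maxT[b] <- max(abs(tb))
  }
  thr <- as.numeric(quantile(maxT, 1 - alpha, type = 1))
  new("FweResult", method = method, nPermutations = nPermutations,
      alpha = alpha, threshold = thr, significant = abs(tobs) > thr,
      maxT = maxT, seed = as.integer(seed))
}

# 26-connected components over a voxel set; returns integer labels.
connectedComponents <- function(coords, gridShape, connectivity = 26L) {
  if (!nrow(coords)) return(integer())
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lin <- (coords[, 3L] - 1L) * (gridShape[1L] * gridShape[2L]) +
         (coords[, 2L] - 1L) * gridShape[1L] + coords[, 1L]
  idxOf <- new.env(hash = TRUE, size = nrow(coords))
  for (i in seq_len(nrow(coords))) assign(as.character(lin[i]), i, idxOf)
  labels <- integer(nrow(coords))
  comp <- 0L
  for (i in seq_len(nrow(coords))) {
    if (labels[i] > 0L) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- sweep(offs, 2L, as.numeric(coords[v, ]), `+`)
      ok <- nb[, 1L] >= 1 & nb[, 1L] <= gridShape[1L] &
            nb[, 2L] >= 1 & nb[, 2L] <= gridShape[2L] &
            nb[, 3L] >= 1 & nb[, 3L] <= gridShape[3L]
      nb <- nb[ok, , drop = FALSE]
      nlin <- (nb[, 3L] - 1) * (gridShape[1L] * gridShape[2L]) +
              (nb[, 2L] - 1) * gridShape[1L] + nb[, 1L]
      for (l in nlin) {
        j <- idxOf[[as.character(l)]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Extract supra-threshold clusters with peak MNI coordinates
#'
#' Significant voxels are partitioned into 26-connected components (6/18
#' available via `connectivity`), separately per sign of t so a positive
#' and a negative cluster can never merge. Each cluster reports its voxel
#' count, peak |t|, the peak voxel's MNI mm coordinate via the mask
#' affine (ties broken by mask order), and its direction
#' (`patients>controls` for positive t). Clusters are sorted by
#' descending peak |t|.
#'
#' @param stat a [GFCStatMap-class].
#' @param fwe an [FweResult-class] for the same map.
#' @param connectivity 26 (default), 18 or 6.
#' @return data.frame with columns `cluster_id`, `peak_x`, `peak_y`,
#'   `peak_z` (MNI mm), `n_voxels`, `peak_t`, `direction`, plus a
#'   `members` list-column of voxel-coordinate matrices. Zero rows when
#'   nothing is significant.
#' @export
extractClusters <- function(stat, fwe, connectivity = 26L) {
  mask <- stat@mask
  sig <- which(fwe@significant)
  empty <- data.frame(cluster_id = character(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      n_voxels = integer(), peak_t = numeric(),
                      direction = character())
  empty$members <- list()
  if (!length(sig)) return(empty)
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- sig[sign(stat@t[sig]) == sgn]
    if (!length(idx)) next
    co <- mask@coords[idx, , drop = FALSE]
    labels <- connectedComponents(co, mask@gridShape, connectivity)
    for (cl in seq_len(max(labels))) {
      mem <- idx[labels == cl]
      tvals <- stat@t[mem]
      peak <- mem[which.max(abs(tvals))]  # first max in mask order
      mni <- voxelToWorld(mask@coords[peak, , drop = FALSE], mask@affine)
      out[[length(out) + 1L]] <- list(
        peak_x = mni[1L], peak_y = mni[2L], peak_z = mni[3L],
        n_voxels = length(mem), peak_t = tvals[which.max(abs(tvals))],
        direction = if (sgn > 0) "patients>controls" else "patients<controls",
        members = mask@coords[mem, , drop = FALSE])
    }
  }
  ord <- order(-vapply(out, function(x) abs(x$peak_t), numeric(1)))
  out <- out[ord]
  res <- data.frame(
    cluster_id = sprintf("cluster_%02d", seq_along(out)),
    peak_x = vapply(out, `[[`, numeric(1), "peak_x"),
    peak_y = vapply(out, `[[`, numeric(1), "peak_y"),
    peak_z = vapply(out, `[[`, numeric(1), "peak_z"),
    n_voxels = vapply(out, `[[`, integer(1), "n_voxels"),
    peak_t = vapply(out, `[[`, numeric(1), "peak_t"),
    direction = vapply(out, `[[`, character(1), "direction"))
  res$members <- lapply(out, `[[`, "members")
  res
}
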