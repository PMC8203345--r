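mkSubjects <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("s%03d", seq_len(n)),
             group = rep(c("patient", "control"), length.out = n),
             age = rnorm(n, 21, 3), sex = sample(c("M", "F"), n, TRUE),
             education = rnorm(n, 14, 2), mean_fd = runif(n, 0, 0.15))
}

test_that("voxel-wise GLM without covariates equals the pooled two-sample t", {
  set.seed(2)
  n <- 24
  subj <- mkSubjects(n)
  Y <- matrix(rnorm(40 * n), 40, n)
  Y[, subj$group == "patient"] <- Y[, subj$group == "patient"] + 0.8
  ge <- matrixExperiment(Y, subj)
  X <- designMatrix(subj, covariates = character(0))
  st <- fitVoxelwiseGLM(ge, X)
  pat <- subj$group == "patient"
  want <- apply(Y, 1L, function(y) pooledT(y[pat], y[!pat]))
  expect_equal(tStatistics(st), want, tolerance = 1e-10)
  expect_equal(st@df, n - 2)
  # and p values match the t distribution
  expect_equal(pValues(st), 2 * pt(-abs(want), n - 2), tolerance = 1e-12)
})

test_that("GLM design handling: collinearity, no-variance voxels, alignment", {
  subj <- mkSubjects(12)
  Y <- matrix(rnorm(10 * 12), 10, 12)
  ge <- matrixExperiment(Y, subj)
  X <- designMatrix(subj)
  Xbad <- cbind(X, group_copy = X[, "group"])
  attr(Xbad, "groupColumn") <- 2L
  expect_error(fitVoxelwiseGLM(ge, Xbad), "collinear")
  # identical maps across subjects: t = 0 everywhere, not 0/0
  Yc <- matrix(rep(rnorm(10), 12), 10, 12)
  gec <- matrixExperiment(Yc, subj)
  stc <- fitVoxelwiseGLM(gec, X)
  expect_true(all(tStatistics(stc) == 0))
  expect_true(all(pValues(stc) == 1))
  expect_error(fitVoxelwiseGLM(ge, X[1:6, ]), "match")
})

test_that("t map is invariant to constant shifts and subject reordering,
           and flips sign under group relabelling", {
  set.seed(14)
  n <- 20
  subj <- mkSubjects(n)
  Y <- matrix(rnorm(30 * n), 30, n)
  ge <- matrixExperiment(Y, subj)
  X <- designMatrix(subj)
  t0 <- tStatistics(fitVoxelwiseGLM(ge, X))
  # constant added to every subject's map
  ge2 <- matrixExperiment(Y + 5, subj)
  expect_equal(tStatistics(fitVoxelwiseGLM(ge2, X)), t0, tolerance = 1e-9)
  # permuting subjects together with design rows changes nothing
  perm <- sample(n)
  ge3 <- matrixExperiment(Y[, perm], subj[perm, ])
  X3 <- designMatrix(subj[perm, ])
  expect_equal(tStatistics(fitVoxelwiseGLM(ge3, X3)), t0, tolerance = 1e-9)
  # swapping the group labels flips every t
  subj4 <- subj
  subj4$group <- ifelse(subj$group == "patient", "control", "patient")
  ge4 <- matrixExperiment(Y, subj4)
  X4 <- designMatrix(subj4)
  expect_equal(tStatistics(fitVoxelwiseGLM(ge4, X4)), -t0, tolerance = 1e-9)
})

test_that("permutation maxT null equals an explicit Freedman-Lane refit", {
  set.seed(6)
  n <- 18
  subj <- mkSubjects(n)
  Y <- matrix(rnorm(25 * n), 25, n)
  ge <- matrixExperiment(Y, subj)
  X <- designMatrix(subj)
  st <- fitVoxelwiseGLM(ge, X)
  fw <- fweCorrect(st, ge, X, nPermutations = 150, seed = 99)
  want <- naiveFreedmanLaneMaxT(Y, X, 2L, 150, 99)
  expect_equal(fw@maxT, want, tolerance = 1e-9)
  # threshold reproduces the significant set exactly
  expect_identical(significantVoxels(fw), abs(tStatistics(st)) > fweThreshold(fw))
})

test_that("maxT quantile boundary and Bonferroni arithmetic", {
  subj <- mkSubjects(14)
  Y <- matrix(rnorm(10 * 14), 10, 14)
  ge <- matrixExperiment(Y, subj)
  X <- designMatrix(subj)
  st <- fitVoxelwiseGLM(ge, X)
  B <- 120
  fw <- fweCorrect(st, ge, X, alpha = 1 - 1 / B, nPermutations = B, seed = 4)
  expect_equal(fweThreshold(fw), min(fw@maxT))
  # Bonferroni on a 10-voxel mask at alpha 0.05: per-voxel p < 0.005
  fb <- fweCorrect(st, ge, X, method = "bonferroni", alpha = 0.05)
  expect_equal(fb@threshold, qt(1 - 0.005 / 2, st@df))
  expect_identical(significantVoxels(fb), pValues(st) < 0.005)
  expect_error(fweCorrect(st, ge, X, alpha = 1.2), "alpha")
  expect_error(fweCorrect(st, ge, X, nPermutations = 50), "100")
  # maxT threshold always at least the uncorrected single-voxel threshold
  fw5 <- fweCorrect(st, ge, X, alpha = 0.05, nPermutations = 200, seed = 1)
  expect_gte(fweThreshold(fw5), qt(0.975, st@df))
})

test_that("cluster extraction: singletons, corner connectivity, sign split", {
  g <- c(5, 5, 5)
  prob <- array(1, dim = g)
  mask <- buildGrayMask(prob, 0.2)
  tvals <- numeric(maskSize(mask))
  lin <- function(x, y, z) (z - 1) * 25 + (y - 1) * 5 + x
  # one isolated voxel; two corner-touching voxels; one negative voxel
  tvals[lin(1, 1, 1)] <- 6
  tvals[lin(3, 3, 3)] <- 7
  tvals[lin(4, 4, 4)] <- 5.5   # touches (3,3,3) only at a corner
  tvals[lin(1, 5, 5)] <- -8
  st <- new("GFCStatMap", t = tvals, p = rep(1, length(tvals)),
            df = 10, contrast = "patients - controls", mask = mask)
  fw <- new("FweResult", method = "bonferroni", nPermutations = 0L,
            alpha = 0.05, threshold = 5, significant = abs(tvals) > 5,
            maxT = numeric(), seed = 1L)
  cl <- extractClusters(st, fw)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$peak_t[1], -8)           # sorted by descending |peak t|
  expect_equal(cl$direction[1], "patients<controls")
  corner <- cl[cl$n_voxels == 2, ]
  expect_equal(nrow(corner), 1)            # 26-connectivity joins corners
  expect_equal(corner$peak_t, 7)
  # under 6-connectivity the corner pair splits
  cl6 <- extractClusters(st, fw, connectivity = 6L)
  expect_equal(nrow(cl6), 4)
  expect_true(all(cl6$n_voxels == 1))
  # peak MNI coordinate respects the affine (identity: 0-based voxel)
  single <- cl[cl$n_voxels == 1 & cl$peak_t > 0, ]
  expect_equal(unlist(single[c("peak_x", "peak_y", "peak_z")],
                      use.names = FALSE), c(0, 0, 0))
  # empty significant set gives an empty table
  fw0 <- new("FweResult", method = "bonferroni", nPermutations = 0L,
             alpha = 0.05, threshold = 99, significant = rep(FALSE, 125),
             maxT = numeric(), seed = 1L)
  expect_equal(nrow(extractClusters(st, fw0)), 0)
})
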