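mkStudyBits <- function(n = 14, V = 30, seed = 3) {
  set.seed(seed)
  subj <- data.frame(id = sprintf("s%03d", seq_len(n)),
                     group = rep(c("patient", "control"), length.out = n))
  Y <- matrix(rnorm(V * n), V, n)
  ge <- matrixExperiment(Y, subj)
  mask <- S4Vectors::metadata(ge)$mask
  co <- maskCoords(mask)
  clusters <- data.frame(cluster_id = c("cluster_01", "cluster_02"),
                         peak_x = 0, peak_y = 0, peak_z = 0,
                         n_voxels = c(1L, 5L), peak_t = c(5, 4),
                         direction = "patients>controls")
  clusters$members <- list(co[7, , drop = FALSE], co[11:15, , drop = FALSE])
  list(subj = subj, Y = Y, ge = ge, clusters = clusters)
}

test_that("cluster means: singleton, constant map, naive-loop oracle", {
  b <- mkStudyBits()
  means <- extractClusterMeans(b$ge, b$clusters)
  expect_equal(means$cluster_01, b$Y[7, ], ignore_attr = TRUE)
  # naive double loop over subjects and member voxels
  want <- sapply(seq_len(ncol(b$Y)), function(s) mean(b$Y[11:15, s]))
  expect_equal(means$cluster_02, want, tolerance = 1e-12)
  # constant map: mean is that constant for any cluster
  Yc <- matrix(3.25, nrow(b$Y), ncol(b$Y))
  gec <- matrixExperiment(Yc, b$subj)
  mc <- extractClusterMeans(gec, b$clusters)
  expect_true(all(mc$cluster_02 == 3.25))
  # empty cluster errors
  bad <- b$clusters
  bad$members[[1]] <- bad$members[[1]][0, , drop = FALSE]
  expect_error(extractClusterMeans(b$ge, bad), "empty cluster")
})

test_that("clinical correlation screening: exact r, missing vars, families", {
  b <- mkStudyBits(n = 20)
  means <- extractClusterMeans(b$ge, b$clusters)
  subj <- b$subj
  # variable that is an exact linear function of the cluster means
  subj$lin <- 2 * means$cluster_01 - 1
  set.seed(9)
  subj$noisy <- rnorm(20)
  subj$mostly_na <- NA_real_
  subj$mostly_na[1:2] <- 1:2
  res <- suppressWarnings(
    correlateClinical(means, subj, c("lin", "noisy", "mostly_na"),
                      group = "all"))
  lin1 <- res[res$cluster == "cluster_01" & res$variable == "lin", ]
  expect_equal(lin1$r, 1, tolerance = 1e-12)
  expect_lt(lin1$p, 1e-12)
  # skipped pair (too few complete cases) drops out of the family count
  expect_false(any(res$variable == "mostly_na"))
  expect_equal(unique(res$p_threshold_bonferroni), 0.05 / nrow(res))
  w <- capture_warnings(correlateClinical(means, subj, c("mostly_na"),
                                          group = "all"))
  expect_match(w, "complete pair", all = TRUE)
  expect_length(w, 2)  # one skip per cluster
  expect_error(correlateClinical(means, subj, "absent_var"), "absent")
  # per-cluster family divides by tests within each cluster
  resc <- suppressWarnings(
    correlateClinical(means, subj, c("lin", "noisy"), group = "all",
                      family = "per_cluster"))
  expect_equal(unique(resc$p_threshold_bonferroni), 0.05 / 2)
  # shapiro normality reported per cluster
  expect_named(attr(res, "shapiro_p"), c("cluster_01", "cluster_02"))
})

test_that("r matches an independent sums formula and behaves under transforms", {
  b <- mkStudyBits(n = 16, seed = 10)
  means <- extractClusterMeans(b$ge, b$clusters)
  subj <- b$subj
  set.seed(2)
  subj$v <- rnorm(16, 50, 9)
  res <- correlateClinical(means, subj, "v", group = "all")
  want <- pearsonBySums(means$cluster_01, subj$v)
  expect_equal(res$r[res$cluster == "cluster_01"], want, tolerance = 1e-12)
  # invariance to positive affine rescaling; sign flip under negation
  subj2 <- subj; subj2$v <- 3 * subj$v + 100
  res2 <- correlateClinical(means, subj2, "v", group = "all")
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  subj3 <- subj; subj3$v <- -subj$v
  res3 <- correlateClinical(means, subj3, "v", group = "all")
  expect_equal(res3$r, -res$r, tolerance = 1e-12)
})

test_that("pairwise deletion only affects tests involving the missing variable", {
  b <- mkStudyBits(n = 18, seed = 4)
  means <- extractClusterMeans(b$ge, b$clusters)
  subj <- b$subj
  set.seed(5)
  subj$u <- rnorm(18); subj$w <- rnorm(18)
  before <- correlateClinical(means, subj, c("u", "w"), group = "all")
  subj$u[3] <- NA
  after <- correlateClinical(means, subj, c("u", "w"), group = "all")
  wU <- after$variable == "u"
  expect_true(all(after$n[wU] == 17))
  expect_equal(after$r[after$variable == "w"],
               before$r[before$variable == "w"], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(after$r[wU], before$r[wU])))
})

test_that("patients-only filtering uses only patient rows", {
  b <- mkStudyBits(n = 20, seed = 6)
  means <- extractClusterMeans(b$ge, b$clusters)
  subj <- b$subj
  set.seed(7)
  subj$v <- rnorm(20)
  subj$v[subj$group == "control"] <- NA  # controls lack clinical data
  res <- correlateClinical(means, subj, "v", group = "patient")
  expect_true(all(res$n == sum(subj$group == "patient")))
  pat <- subj$group == "patient"
  expect_equal(res$r[res$cluster == "cluster_01"],
               pearsonBySums(means$cluster_01[pat], subj$v[pat]),
               tolerance = 1e-12)
})
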