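test_that("cohort generation is bit-identical for identical specs", {
  spec <- smallCohortSpec(seed = 42L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$gmProb, b$gmProb)
  expect_identical(lapply(a$motion, function(m) m@params),
                   lapply(b$motion, function(m) m@params))
  expect_identical(lapply(a$volumes, function(v) v@data),
                   lapply(b$volumes, function(v) v@data))
  # streamed volumes match the in-memory ones exactly, in any order
  c0 <- generateCohort(spec, includeVolumes = FALSE)
  expect_identical(cohortVolume(c0, 5)@data, a$volumes[[5]]@data)
  expect_identical(cohortVolume(c0, 2)@data, a$volumes[[2]]@data)
})

test_that("invalid specs are rejected", {
  expect_error(cohortSpec(hubCenter = c(1, 8, 8), hubRadius = 3),
               "inside the grid")
  expect_error(cohortSpec(nPatients = 4, nControls = 10, nHighMotion = 4),
               "smaller than each group")
  expect_error(cohortSpec(clinicalEffects = c(TG = 1)), "< 1")
  expect_error(cohortSpec(gmFraction = 0), "gmFraction")
})

test_that("gray-matter probability map matches the requested fraction", {
  spec <- smallCohortSpec(seed = 2L)
  ch <- generateCohort(spec, includeVolumes = FALSE)
  expect_true(all(ch$gmProb > 0.2 | ch$gmProb <= 0.2))
  nGM <- sum(ch$gmProb > 0.2)
  expect_gte(nGM, round(spec@gmFraction * prod(spec@gridShape)))
  # hub voxels always inside gray matter
  expect_true(all(ch$gmProb[ch$truth$hubVoxels] > 0.2))
})

test_that("high-motion subjects and only they fail the default QC", {
  spec <- smallCohortSpec(seed = 11L, nHighMotion = 2L)
  ch <- generateCohort(spec, includeVolumes = FALSE)
  fds <- lapply(ch$motion, computeFD)
  res <- applyExclusion(fds, ch$motion)
  expect_setequal(res$excluded, ch$truth$highMotionIds)
})

test_that("the default-size roster reproduces the 38->35 retention", {
  spec <- cohortSpec(seed = 9L)  # 38 patients, 3 high-motion per group
  ch <- generateCohort(spec, includeVolumes = FALSE)
  fds <- lapply(ch$motion, computeFD)
  res <- applyExclusion(fds, ch$motion)
  keptGroups <- table(ch$subjects$group[ch$subjects$id %in% res$kept])
  expect_equal(unname(keptGroups[["patient"]]), 35L)
  expect_equal(unname(keptGroups[["control"]]), 37L)
})

test_that("planted clinical correlations converge to target with n", {
  spec <- cohortSpec(nPatients = 2000L, nControls = 10L,
                     nHighMotion = 2L, seed = 77L)
  ch <- generateCohort(spec, includeVolumes = FALSE)
  pat <- ch$subjects$group == "patient"
  cp <- ch$truth$coupling[pat]
  for (v in c("TG", "LDL_C", "RBANS_coding", "stroop_color", "CHOL")) {
    got <- cor(cp, ch$subjects[[v]][pat])
    expect_lt(abs(got - spec@clinicalEffects[[v]]), 0.05)
  }
})

test_that("null planted correlation stays within its sampling band", {
  spec <- smallCohortSpec(seed = 5L, nPatients = 40L, nControls = 5L,
                          nHighMotion = 1L,
                          clinicalEffects = c(TG = 0))
  ch <- generateCohort(spec, includeVolumes = FALSE)
  pat <- ch$subjects$group == "patient"
  r <- cor(ch$truth$coupling[pat], ch$subjects$TG[pat])
  n <- sum(pat)
  expect_lt(abs(atanh(r)), 2 / sqrt(n - 3))
})

test_that("hub voxels are mutually more correlated than background", {
  spec <- smallCohortSpec(seed = 3L, couplingPatient = 1)
  ch <- generateCohort(spec, includeVolumes = FALSE)
  vs <- cohortVolume(ch, 1)  # a patient
  g <- spec@gridShape
  flat <- matrix(vs@data, prod(g), spec@nFrames)
  lin <- function(co) (co[, 3] - 1) * g[1] * g[2] + (co[, 2] - 1) * g[1] + co[, 1]
  hubIdx <- lin(ch$truth$hubVoxels)
  set.seed(1)
  far <- setdiff(seq_len(prod(g)), hubIdx)
  hubR <- cor(t(flat[hubIdx[1:10], ]))
  bgR <- cor(t(flat[sample(far, 10), ]))
  expect_gt(mean(hubR[upper.tri(hubR)]), mean(bgR[upper.tri(bgR)]) + 0.2)
})

test_that("cohort files round-trip through the on-disk layout", {
  spec <- smallCohortSpec(seed = 13L, nPatients = 3L, nControls = 3L,
                          nFrames = 20L)
  ch <- generateCohort(spec)
  dir <- tempfile("cohort")
  writeCohort(ch, dir)
  expect_true(file.exists(file.path(dir, "gm_prob.nii.gz")))
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  back <- gfcmap:::readCohortFromDir(list(
    gm_prob = file.path(dir, "gm_prob.nii.gz"),
    subjects = file.path(dir, "subjects.tsv"),
    bold_dir = dir, motion_dir = dir), tr = spec@tr)
  expect_equal(back$subjects$id, ch$subjects$id)
  expect_equal(back$volumes[[2]]@data, ch$volumes[[2]]@data,
               tolerance = 1e-6)
  expect_equal(back$motion[[4]]@params, ch$motion[[4]]@params,
               tolerance = 1e-8)
  expect_equal(dim(back$gmProb), dim(ch$gmProb))
  expect_equal(back$affine, ch$affine, tolerance = 1e-5)
  unlink(dir, recursive = TRUE)
})
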