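# Clinical variable scales (mean, sd) used to dress synthetic values in
# plausible units: lipids in mmol/L, scales in raw scores. Values are
# synthetic fixtures, not data.
CLINICAL_SCALES <- list(
  TG = c(1.06, 0.92), CHOL = c(3.88, 1.11), HDL_C = c(1.27, 0.40),
  LDL_C = c(2.41, 0.81), blood_glucose = c(4.09, 1.04),
  HAMD17 = c(22.14, 6.95), HAMA14 = c(25.54, 8.20), YMRS = c(9.26, 6.84),
  RBANS_coding = c(56.97, 10.52), stroop_word = c(96.30, 20.84),
  stroop_color = c(68.42, 18.24), stroop_color_word = c(41.42, 8.81)
)

#' Construct a synthetic-cohort specification
#'
#' Defaults describe the package's reference study: 38 patients and 40
#' controls scanned on a 16x16x16 grid (3 mm isotropic, MNI-like origin)
#' for 150 frames at TR 2 s; a central gray-matter blob covers 25% of the
#' grid; a spherical hub of radius 3 voxels (123 voxels) is coupled to a
#' subject-specific global latent signal, more strongly in patients
#' (coupling 0.8 vs 0.25, between-subject SD 0.25, relative to
#' unit-variance smoothed noise); 3 subjects per group
#' carry excessive head motion (so the default motion QC retains
#' 35 + 37); and four clinical variables carry planted correlations with
#' the hub coupling (TG 0.45, LDL-C 0.42, RBANS coding -0.40, Stroop
#' color -0.47) while five others are null.
#'
#' @param nPatients,nControls group sizes before motion exclusion.
#' @param gridShape voxels per axis.
#' @param nFrames frames per scan.
#' @param tr repetition time, seconds.
#' @param gmFraction fraction of voxels in gray matter.
#' @param hubCenter,hubRadius hub sphere (1-based voxel units).
#' @param couplingPatient,couplingControl,couplingSD group mean and
#'   between-subject SD of the latent-signal coupling weight.
#' @param noiseSD background noise SD (BOLD a.u.).
#' @param smoothFWHM spatial smoothing of the noise field, voxels.
#' @param nHighMotion high-motion subjects per group.
#' @param clinicalEffects named numeric vector of target correlations
#'   with the true coupling.
#' @param seed integer RNG seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 38L, nControls = 40L,
                       gridShape = c(16L, 16L, 16L), nFrames = 150L,
                       tr = 2, gmFraction = 0.25,
                       hubCenter = c(8L, 8L, 8L), hubRadius = 3,
                       couplingPatient = 0.8, couplingControl = 0.25,
                       couplingSD = 0.25,
                       noiseSD = 1, smoothFWHM = 2,
                       nHighMotion = 3L,
                       clinicalEffects = c(TG = 0.45, LDL_C = 0.42,
                                           RBANS_coding = -0.40,
                                           stroop_color = -0.47,
                                           CHOL = 0, HDL_C = 0,
                                           HAMD17 = 0, HAMA14 = 0,
                                           YMRS = 0),
                       seed = 1L) {
  new("CohortSpec",
      nPatients = as.integer(nPatients), nControls = as.integer(nControls),
      gridShape = as.integer(gridShape), nFrames = as.integer(nFrames),
      tr = tr, gmFraction = gmFraction,
      hubCenter = as.integer(hubCenter), hubRadius = hubRadius,
      couplingPatient = couplingPatient, couplingControl = couplingControl,
      couplingSD = couplingSD, noiseSD = noiseSD, smoothFWHM = smoothFWHM,
      nHighMotion = as.integer(nHighMotion),
      clinicalEffects = clinicalEffects, seed = as.integer(seed))
}

cohortAffine <- function(gridShape, voxelMM = 3) {
  rbind(cbind(diag(voxelMM, 3), -voxelMM * gridShape / 2), c(0, 0, 0, 1))
}

hubVoxelSet <- function(spec) {
  g <- spec@gridShape
  co <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                              z = seq_len(g[3]), KEEP.OUT.ATTRS = FALSE))
  d2 <- (co[, 1] - spec@hubCenter[1])^2 + (co[, 2] - spec@hubCenter[2])^2 +
        (co[, 3] - spec@hubCenter[3])^2
  unname(co[d2 <= spec@hubRadius^2, , drop = FALSE])
}

# Gray-matter probability map: the gmFraction of voxels closest to the
# grid centre (a central blob, like a brain in a box) get probability
# 0.7, the rest 0.05; hub voxels are forced inside gray matter.
gmProbabilityMap <- function(spec) {
  g <- spec@gridShape
  co <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                              z = seq_len(g[3]), KEEP.OUT.ATTRS = FALSE))
  centre <- (g + 1) / 2
  d2 <- rowSums(sweep(co, 2L, centre)^2)
  k <- max(1L, round(spec@gmFraction * nrow(co)))
  prob <- rep(0.05, nrow(co))
  prob[order(d2)[seq_len(k)]] <- 0.7
  vol <- array(prob, dim = g)
  hub <- hubVoxelSet(spec)
  vol[hub] <- 0.7
  vol
}

cleanMotionTrace <- function(nFrames) {
  steps <- cbind(matrix(rnorm(3 * nFrames, sd = 0.002), ncol = 3),
                 matrix(rnorm(3 * nFrames, sd = 2e-5), ncol = 3))
  apply(steps, 2L, cumsum)
}

highMotionTrace <- function(nFrames) {
  m <- cleanMotionTrace(nFrames)
  jumpAt <- sample(seq(10L, nFrames - 10L), 1L)
  axis <- sample(1:3, 1L)
  m[jumpAt:nFrames, axis] <- m[jumpAt:nFrames, axis] + 3  # 3 mm shift
  m[, 4:6] <- m[, 4:6] + matrix(rnorm(3 * nFrames, sd = 2e-4), ncol = 3)
  m
}

#' Generate a synthetic resting-state cohort
#'
#' Draws the full synthetic study defined by a [CohortSpec-class]: a
#' gray-matter probability map (central blob > 0.2, background below),
#' per-subject 4D BOLD volumes (spatially smoothed Gaussian noise plus a
#' subject-specific global latent signal added to hub voxels only, with
#' coupling ~ Normal(group mean, couplingSD) truncated at 0), rigid-body
#' motion traces (near-zero except the designated high-motion subjects,
#' which exceed the default exclusion limits), a subject table with
#' demographics and patient clinical variables constructed to correlate
#' with the true coupling at the planted r (via
#' `x = r * standardized coupling + sqrt(1 - r^2) * noise`, rescaled to
#' plausible clinical units), and the ground truth needed to score
#' recovery. Identical specs give bit-identical cohorts.
#'
#' @param spec a [CohortSpec-class].
#' @param includeVolumes generate and keep the 4D volumes in memory
#'   (default `TRUE`); with `FALSE` volumes are omitted and can be
#'   materialised one at a time with [cohortVolume()], which is useful
#'   when streaming many subjects through [computeGFC()].
#' @return list of class `"gfc_cohort"`: `spec`, `volumes` (list of
#'   [VolumeSeries-class] or `NULL`), `gmProb` (3D array), `affine`,
#'   `motion` (list of [MotionTrace-class]), `subjects` (data.frame), and
#'   `truth` (list: `hubVoxels`, `coupling`, `plantedR`,
#'   `highMotionIds`).
#' @examples
#' spec <- cohortSpec(nPatients = 4, nControls = 4, gridShape = c(8, 8, 8),
#'                    nFrames = 40, nHighMotion = 1, hubCenter = c(4, 4, 4))
#' ch <- generateCohort(spec, includeVolumes = FALSE)
#' table(ch$subjects$group)
#' @export
generateCohort <- function(spec, includeVolumes = TRUE) {
  validObject(spec)
  np <- spec@nPatients; nc <- spec@nControls
  n <- np + nc
  ids <- sprintf("sub-%03d", seq_len(n))
  group <- rep(c("patient", "control"), c(np, nc))

  set.seed(stageSeed(spec@seed, "cohort"))
  coupling <- pmax(rnorm(n, mean = ifelse(group == "patient",
                                          spec@couplingPatient,
                                          spec@couplingControl),
                         sd = spec@couplingSD), 0)
  names(coupling) <- ids

  # demographics loosely matched between groups
  age <- round(ifelse(group == "patient", rnorm(n, 20.66, 2.51),
                      rnorm(n, 21.35, 3.16)), 1)
  age <- pmax(age, 16)
  sex <- ifelse(runif(n) < ifelse(group == "patient", 11 / 35, 17 / 37),
                "M", "F")
  education <- round(ifelse(group == "patient", rnorm(n, 13.91, 2.02),
                            rnorm(n, 14.95, 2.11)), 1)
  education <- pmax(education, 6)
  subjects <- data.frame(id = ids, group = group, age = age, sex = sex,
                         education = education)

  # patient clinical variables with planted correlations to coupling
  pidx <- which(group == "patient")
  zc <- as.numeric(scale(coupling[pidx]))
  for (v in names(spec@clinicalEffects)) {
    r <- spec@clinicalEffects[[v]]
    sc <- CLINICAL_SCALES[[v]]
    if (is.null(sc)) sc <- c(0, 1)
    xv <- r * zc + sqrt(1 - r^2) * rnorm(length(pidx))
    subjects[[v]] <- NA_real_
    subjects[[v]][pidx] <- round(sc[1] + sc[2] * xv, 3)
  }

  highMotion <- c(sample(pidx, spec@nHighMotion),
                  sample(which(group == "control"), spec@nHighMotion))
  motion <- vector("list", n)
  for (i in seq_len(n)) {
    m <- if (i %in% highMotion) highMotionTrace(spec@nFrames)
         else cleanMotionTrace(spec@nFrames)
    motion[[i]] <- new("MotionTrace", params = m, subjectId = ids[i])
  }

  truth <- list(hubVoxels = hubVoxelSet(spec), coupling = coupling,
                plantedR = spec@clinicalEffects,
                highMotionIds = ids[sort(highMotion)])
  cohort <- structure(list(
    spec = spec, volumes = NULL, gmProb = gmProbabilityMap(spec),
    affine = cohortAffine(spec@gridShape), motion = motion,
    subjects = subjects, truth = truth), class = "gfc_cohort")
  if (includeVolumes)
    cohort$volumes <- lapply(seq_len(n), function(i) cohortVolume(cohort, i))
  cohort
}

#' Materialise one subject's synthetic 4D volume
#'
#' Deterministic given the cohort's spec and the subject index: each
#' subject has an independent RNG stream derived from the cohort seed,
#' so volumes can be generated on demand (and discarded) in any order
#' with bit-identical results.
#'
#' @param cohort a `"gfc_cohort"` from [generateCohort()].
#' @param i subject index (1-based, cohort order).
#' @return a [VolumeSeries-class].
#' @export
cohortVolume <- function(cohort, i) {
  spec <- cohort$spec
  ids <- cohort$subjects$id
  set.seed(stageSeed(spec@seed, paste0("volume-", ids[i])))
  g <- spec@gridShape; nT <- spec@nFrames
  latent <- rnorm(nT)
  noise <- array(rnorm(prod(g) * nT, sd = spec@noiseSD), dim = c(g, nT))
  noise <- smoothFrames(noise, spec@smoothFWHM)
  hub <- cohort$truth$hubVoxels
  lin <- (hub[, 3L] - 1L) * (g[1L] * g[2L]) + (hub[, 2L] - 1L) * g[1L] +
         hub[, 1L]
  cp <- cohort$truth$coupling[[ids[i]]]
  frameOffsets <- (seq_len(nT) - 1L) * prod(g)
  idx <- rep(lin, times = nT) + rep(frameOffsets, each = length(lin))
  noise[idx] <- noise[idx] + cp * rep(latent, each = length(lin))
  new("VolumeSeries", data = noise, affine = cohort$affine, tr = spec@tr,
      subjectId = ids[i])
}

#' Write a synthetic cohort to disk
#'
#' Per-subject 4D NIfTI volumes (`<id>_bold.nii.gz`), the gray-matter
#' probability map (`gm_prob.nii.gz`), SPM-convention motion traces
#' (`rp_<id>.txt`), the subject table (`subjects.tsv`) and the ground
#' truth (`truth.json`). Volumes are streamed one subject at a time so
#' memory stays flat.
#'
#' @param cohort a `"gfc_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write3DNifti(cohort$gmProb, cohort$affine, file.path(dir, "gm_prob.nii.gz"))
  ids <- cohort$subjects$id
  for (i in seq_along(ids)) {
    vs <- if (!is.null(cohort$volumes)) cohort$volumes[[i]]
          else cohortVolume(cohort, i)
    writeVolumeSeries(vs, file.path(dir, paste0(ids[i], "_bold.nii.gz")))
    writeMotionTrace(cohort$motion[[i]],
                     file.path(dir, paste0("rp_", ids[i], ".txt")))
  }
  write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(hub_voxels = cohort$truth$hubVoxels,
         coupling = as.list(cohort$truth$coupling),
         planted_r = as.list(cohort$truth$plantedR),
         high_motion_ids = cohort$truth$highMotionIds),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
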