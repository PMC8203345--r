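#' @import methods
#' @importFrom stats rnorm runif rbinom quantile pt qt sd var cor cor.test
#'   shapiro.test setNames complete.cases predict
#' @importFrom utils head read.table write.table
NULL

#' Gray-matter mask over a voxel grid
#'
#' An ordered set of voxel coordinates retained from a gray-matter
#' probability map by strict thresholding (probability > threshold).
#' Ordering is fixed and deterministic: the first grid axis varies fastest,
#' then the second, then the third, so value vectors indexed against the
#' mask are reproducible.
#'
#' @slot coords integer matrix (voxels x 3) of 1-based voxel indices.
#' @slot gridShape integer(3), voxels per axis of the source grid.
#' @slot threshold numeric(1), the probability cutoff that produced the mask.
#' @slot affine 4x4 voxel-to-world (MNI mm) transform, NIfTI convention
#'   (applies to 0-based voxel indices).
#'
#' @seealso [buildGrayMask()]
#' @export
setClass("GrayMask",
  representation(
    coords = "matrix",
    gridShape = "integer",
    threshold = "numeric",
    affine = "matrix"
  )
)

setValidity("GrayMask", function(object) {
  msg <- character()
  if (nrow(object@coords) < 1L) msg <- c(msg, "mask must contain at least one voxel")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (nrow(object@coords) > 0L) {
    if (any(object@coords < 1L) ||
        any(t(object@coords) > object@gridShape))
      msg <- c(msg, "mask voxels must lie within the grid")
    lin <- maskLinearIndices(object)
    if (anyDuplicated(lin)) msg <- c(msg, "mask voxels must be unique")
  }
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  if (length(msg)) msg else TRUE
})

#' One subject's 4D BOLD series
#'
#' @slot data 4D numeric array (x, y, z, t), arbitrary BOLD units.
#' @slot affine 4x4 voxel-to-world transform (NIfTI convention).
#' @slot tr repetition time, seconds.
#' @slot subjectId subject label.
#'
#' @seealso [readVolumeSeries()], [computeGFC()]
#' @export
setClass("VolumeSeries",
  representation(
    data = "array",
    affine = "matrix",
    tr = "numeric",
    subjectId = "character"
  )
)

setValidity("VolumeSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  else if (dim(object@data)[4L] < 2L)
    msg <- c(msg, "need at least 2 frames")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "non-finite values in BOLD data")
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number (seconds)")
  if (length(msg)) msg else TRUE
})

#' Rigid-body head-motion trace
#'
#' Six realignment parameters per frame: translations along x/y/z in mm,
#' then rotations about x/y/z in radians (SPM rp_*.txt column order).
#'
#' @slot params numeric matrix (frames x 6).
#' @slot subjectId subject label.
#'
#' @seealso [readMotionTrace()], [computeFD()]
#' @export
setClass("MotionTrace",
  representation(params = "matrix", subjectId = "character")
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (ncol(object@params) != 6L)
    msg <- c(msg, "motion trace must have 6 columns (3 translations mm, 3 rotations rad)")
  if (!all(is.finite(object@params)))
    msg <- c(msg, "non-finite motion parameters")
  if (length(msg)) msg else TRUE
})

#' Per-frame frame-wise displacement series
#'
#' @slot fd numeric vector, FD per frame in mm (first frame is 0 by
#'   definition).
#' @slot meanFD arithmetic mean of the series, mm.
#' @slot subjectId subject label.
#'
#' @seealso [computeFD()]
#' @export
setClass("FDSeries",
  representation(fd = "numeric", meanFD = "numeric", subjectId = "character")
)

setValidity("FDSeries", function(object) {
  msg <- character()
  if (any(object@fd < 0)) msg <- c(msg, "FD values must be non-negative")
  if (abs(object@meanFD - mean(object@fd)) > 1e-12)
    msg <- c(msg, "meanFD must equal the arithmetic mean of the series")
  if (length(msg)) msg else TRUE
})

#' Per-subject GFC map over a gray-matter mask
#'
#' Fisher-z global-brain functional connectivity values, one per mask
#' voxel, in mask order. Background (non-mask) voxels are not stored;
#' when written to NIfTI they are encoded as 0 with the mask as sidecar.
#'
#' @slot values numeric vector, one Fisher-z value per mask voxel.
#' @slot subjectId subject label.
#' @slot zOrder `"z_of_mean_r"` (Fisher transform of the mean correlation)
#'   or `"mean_of_z"` (mean of Fisher-transformed correlations).
#' @slot mask the [GrayMask-class] the values are indexed against.
#'
#' @seealso [computeGFC()]
#' @export
setClass("GFCMap",
  representation(
    values = "numeric",
    subjectId = "character",
    zOrder = "character",
    mask = "GrayMask"
  )
)

setValidity("GFCMap", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "GFC values must be finite")
  if (length(object@values) != nrow(object@mask@coords))
    msg <- c(msg, "values must align with mask voxels")
  if (!object@zOrder %in% c("z_of_mean_r", "mean_of_z"))
    msg <- c(msg, "zOrder must be 'z_of_mean_r' or 'mean_of_z'")
  if (length(msg)) msg else TRUE
})

#' Stack of per-subject GFC maps as a SummarizedExperiment
#'
#' Rows are gray-matter mask voxels (voxel coordinates in `rowData`),
#' columns are subjects (group and covariates in `colData`), and the
#' `"gfc"` assay holds Fisher-z GFC values. The generating
#' [GrayMask-class] and the z-transform order live in `metadata()`.
#'
#' @seealso [gfcExperiment()]
#' @export
#' @import SummarizedExperiment
setClass("GFCExperiment", contains = "SummarizedExperiment")

setValidity("GFCExperiment", function(object) {
  msg <- character()
  if (!"gfc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'gfc' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("x", "y", "z") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry voxel coordinates x, y, z")
  m <- S4Vectors::metadata(object)$mask
  if (is.null(m) || !is(m, "GrayMask"))
    msg <- c(msg, "metadata()$mask must be a GrayMask")
  else if (nrow(object) != nrow(m@coords))
    msg <- c(msg, "row count must equal mask size")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise group-contrast statistic map
#'
#' Per-mask-voxel t statistic and uncorrected two-sided p value from the
#' voxel-wise GLM of GFC on group plus nuisance covariates.
#'
#' @slot t numeric, t statistic per mask voxel (patients - controls).
#' @slot p numeric, uncorrected two-sided p per voxel, in (0, 1].
#' @slot df residual degrees of freedom (subjects - design columns).
#' @slot contrast contrast label.
#' @slot mask the [GrayMask-class] the statistics are indexed against.
#'
#' @seealso [fitVoxelwiseGLM()]
#' @export
setClass("GFCStatMap",
  representation(
    t = "numeric", p = "numeric", df = "numeric",
    contrast = "character", mask = "GrayMask"
  )
)

setValidity("GFCStatMap", function(object) {
  msg <- character()
  if (length(object@t) != length(object@p))
    msg <- c(msg, "t and p must have equal length")
  if (any(object@p <= 0 | object@p > 1)) msg <- c(msg, "p must lie in (0, 1]")
  if (object@df < 1) msg <- c(msg, "degrees of freedom must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Family-wise-error correction result
#'
#' @slot method `"permutation_maxT"` or `"bonferroni"`.
#' @slot nPermutations permutations used (0 for Bonferroni).
#' @slot alpha family-wise alpha.
#' @slot threshold corrected threshold on |t|; voxels with |t| strictly
#'   above it are significant.
#' @slot significant logical per mask voxel.
#' @slot maxT the permutation null distribution of max |t| (empty for
#'   Bonferroni).
#' @slot seed RNG seed used for the permutations.
#'
#' @seealso [fweCorrect()]
#' @export
setClass("FweResult",
  representation(
    method = "character", nPermutations = "integer", alpha = "numeric",
    threshold = "numeric", significant = "logical", maxT = "numeric",
    seed = "integer"
  )
)

setValidity("FweResult", function(object) {
  msg <- character()
  if (!object@method %in% c("permutation_maxT", "bonferroni"))
    msg <- c(msg, "unknown FWE method")
  if (object@method == "permutation_maxT" && object@nPermutations < 100L)
    msg <- c(msg, "permutation maxT needs at least 100 permutations")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Synthetic-cohort specification
#'
#' Fully determines a synthetic two-group resting-state study: grid and
#' scan geometry, the gray-matter fraction, a spherical connectivity hub
#' whose coupling to a subject-specific global latent signal differs
#' between groups, head-motion contamination, and clinical variables with
#' planted correlations to the hub coupling. Identical specs (including
#' `seed`) generate bit-identical cohorts.
#'
#' @slot nPatients,nControls group sizes before motion exclusion.
#' @slot gridShape integer(3), voxels per axis.
#' @slot nFrames time points per scan.
#' @slot tr repetition time, seconds.
#' @slot gmFraction fraction of grid voxels inside gray matter, (0, 1].
#' @slot hubCenter integer(3), 1-based voxel coordinate of the hub centre.
#' @slot hubRadius hub sphere radius, voxels.
#' @slot couplingPatient,couplingControl group mean coupling weight
#'   (unitless) of the shared latent signal inside the hub.
#' @slot couplingSD between-subject SD of the coupling weight (truncated
#'   at 0).
#' @slot noiseSD SD of the spatially smoothed background noise, BOLD a.u.
#' @slot smoothFWHM spatial smoothing FWHM applied to the noise, voxels.
#' @slot nHighMotion subjects per group given excessive motion.
#' @slot clinicalEffects named numeric vector: target Pearson r between
#'   each clinical variable and the subjects' true hub coupling.
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nPatients = "integer", nControls = "integer",
    gridShape = "integer", nFrames = "integer", tr = "numeric",
    gmFraction = "numeric",
    hubCenter = "integer", hubRadius = "numeric",
    couplingPatient = "numeric", couplingControl = "numeric",
    couplingSD = "numeric",
    noiseSD = "numeric", smoothFWHM = "numeric",
    nHighMotion = "integer",
    clinicalEffects = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  counts <- c(object@nPatients, object@nControls, object@nFrames)
  if (any(counts < 1L)) msg <- c(msg, "counts must be positive")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (object@gmFraction <= 0 || object@gmFraction > 1)
    msg <- c(msg, "gmFraction must lie in (0, 1]")
  if (length(object@hubCenter) != 3L)
    msg <- c(msg, "hubCenter must be a voxel coordinate (3 integers)")
  else {
    r <- ceiling(object@hubRadius)
    if (any(object@hubCenter - r < 1L) ||
        any(object@hubCenter + r > object@gridShape))
      msg <- c(msg, "hub sphere must lie fully inside the grid")
  }
  if (object@couplingPatient < 0 || object@couplingControl < 0)
    msg <- c(msg, "coupling weights must be >= 0")
  if (object@nHighMotion < 0L ||
      object@nHighMotion >= min(object@nPatients, object@nControls))
    msg <- c(msg, "nHighMotion must be smaller than each group size")
  if (length(object@clinicalEffects) &&
      any(abs(object@clinicalEffects) >= 1))
    msg <- c(msg, "planted |r| must be < 1 for every clinical effect")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be positive")
  if (length(msg)) msg else TRUE
})
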