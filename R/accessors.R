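#' Accessors for gfcmap classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `maskCoords()` returns the voxel-coordinate matrix of a mask (or of the
#' mask behind a map/experiment), `maskSize()` its voxel count,
#' `gridShape()` the grid dimensions, `gfcValues()` the Fisher-z values of
#' a [GFCMap-class], `subjectId()` the subject label, `tStatistics()` /
#' `pValues()` the voxel-wise statistics of a [GFCStatMap-class], and
#' `fweThreshold()` / `significantVoxels()` the corrected threshold and
#' significance indicator of an [FweResult-class].
#'
#' @param x an object of the documented classes.
#' @return See each generic's description.
#' @name gfcmap-accessors
#' @examples
#' prob <- array(0.5, dim = c(4, 4, 4))
#' m <- buildGrayMask(prob, threshold = 0.2)
#' maskSize(m)
#' head(maskCoords(m))
NULL

#' @rdname gfcmap-accessors
#' @export
setGeneric("maskCoords", function(x) standardGeneric("maskCoords"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("maskSize", function(x) standardGeneric("maskSize"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("gfcValues", function(x) standardGeneric("gfcValues"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("tStatistics", function(x) standardGeneric("tStatistics"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("fweThreshold", function(x) standardGeneric("fweThreshold"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("significantVoxels", function(x) standardGeneric("significantVoxels"))
#' @rdname gfcmap-accessors
#' @export
setGeneric("meanFD", function(x) standardGeneric("meanFD"))

#' @rdname gfcmap-accessors
#' @export
setMethod("maskCoords", "GrayMask", function(x) x@coords)
#' @rdname gfcmap-accessors
#' @export
setMethod("maskCoords", "GFCMap", function(x) x@mask@coords)
#' @rdname gfcmap-accessors
#' @export
setMethod("maskSize", "GrayMask", function(x) nrow(x@coords))
#' @rdname gfcmap-accessors
#' @export
setMethod("gridShape", "GrayMask", function(x) x@gridShape)
#' @rdname gfcmap-accessors
#' @export
setMethod("gridShape", "VolumeSeries", function(x) dim(x@data)[1:3])
#' @rdname gfcmap-accessors
#' @export
setMethod("gfcValues", "GFCMap", function(x) x@values)
#' @rdname gfcmap-accessors
#' @export
setMethod("subjectId", "GFCMap", function(x) x@subjectId)
#' @rdname gfcmap-accessors
#' @export
setMethod("subjectId", "VolumeSeries", function(x) x@subjectId)
#' @rdname gfcmap-accessors
#' @export
setMethod("subjectId", "MotionTrace", function(x) x@subjectId)
#' @rdname gfcmap-accessors
#' @export
setMethod("subjectId", "FDSeries", function(x) x@subjectId)
#' @rdname gfcmap-accessors
#' @export
setMethod("tStatistics", "GFCStatMap", function(x) x@t)
#' @rdname gfcmap-accessors
#' @export
setMethod("pValues", "GFCStatMap", function(x) x@p)
#' @rdname gfcmap-accessors
#' @export
setMethod("fweThreshold", "FweResult", function(x) x@threshold)
#' @rdname gfcmap-accessors
#' @export
setMethod("significantVoxels", "FweResult", function(x) x@significant)
#' @rdname gfcmap-accessors
#' @export
setMethod("meanFD", "FDSeries", function(x) x@meanFD)

setMethod("show", "GrayMask", function(object) {
  cat("GrayMask:", nrow(object@coords), "voxels on a",
      paste(object@gridShape, collapse = "x"),
      sprintf("grid (probability > %g)\n", object@threshold))
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries '%s': %dx%dx%d grid, %d frames, TR %g s\n",
              object@subjectId, d[1], d[2], d[3], d[4], object@tr))
})

setMethod("show", "GFCMap", function(object) {
  cat(sprintf(
    "GFCMap '%s' (%s): %d mask voxels, z range [%.3f, %.3f]\n",
    object@subjectId, object@zOrder, length(object@values),
    min(object@values), max(object@values)))
})

setMethod("show", "GFCStatMap", function(object) {
  cat(sprintf(
    "GFCStatMap (%s): %d voxels, df = %g, |t| max = %.3f\n",
    object@contrast, length(object@t), object@df, max(abs(object@t))))
})

setMethod("show", "FweResult", function(object) {
  cat(sprintf(
    "FweResult: %s, alpha = %g, |t| threshold = %.4f, %d significant voxel(s)\n",
    object@method, object@alpha, object@threshold, sum(object@significant)))
})

setMethod("show", "FDSeries", function(object) {
  cat(sprintf("FDSeries '%s': %d frames, mean FD %.4f mm\n",
              object@subjectId, length(object@fd), object@meanFD))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    paste0("CohortSpec: %d patients + %d controls, grid %s, %d frames ",
           "(TR %g s)\n  hub r=%g at (%s), coupling %g vs %g, ",
           "%d high-motion per group, seed %d\n"),
    object@nPatients, object@nControls,
    paste(object@gridShape, collapse = "x"), object@nFrames, object@tr,
    object@hubRadius, paste(object@hubCenter, collapse = ","),
    object@couplingPatient, object@couplingControl,
    object@nHighMotion, object@seed))
})
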