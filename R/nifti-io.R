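# Strip RNifti's bookkeeping attributes so affines compare as plain
# 4x4 matrices.
plainAffine <- function(x) matrix(as.numeric(x), 4L, 4L)

#' Read a 4D BOLD series from NIfTI-1
#'
#' @param path path to a `.nii` / `.nii.gz` file with 4 dimensions.
#' @param subjectId subject label; defaults to the file name stem.
#' @param tr repetition time in seconds; defaults to the NIfTI pixdim
#'   time step when present and positive.
#' @return a [VolumeSeries-class]. Non-finite voxels are an error, per
#'   the class contract.
#' @export
readVolumeSeries <- function(path, subjectId = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI volume: ", path)
  if (is.null(tr)) {
    pd <- attr(img, "pixdim")
    tr <- if (!is.null(pd) && length(pd) >= 4L && pd[4L] > 0) pd[4L] else 2
  }
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  new("VolumeSeries", data = array(as.numeric(img), dim = d),
      affine = plainAffine(RNifti::xform(img)), tr = tr,
      subjectId = subjectId)
}

#' Read a 3D probability map from NIfTI-1
#'
#' @param path path to a 3D `.nii` / `.nii.gz` file.
#' @return list with `prob` (3D array) and `affine` (4x4 matrix), ready
#'   for [buildGrayMask()].
#' @export
readProbabilityMap <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop("expected a 3D NIfTI volume: ", path)
  list(prob = array(as.numeric(img), dim = d),
       affine = plainAffine(RNifti::xform(img)))
}

#' Write a VolumeSeries to NIfTI-1
#'
#' @param vs a [VolumeSeries-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolumeSeries <- function(vs, path) {
  img <- RNifti::asNifti(vs@data)
  img <- RNifti::`sform<-`(img, structure(vs@affine, code = 4L))
  attr(img, "pixdim")[4L] <- vs@tr
  RNifti::writeNifti(img, path)
  invisible(path)
}

write3DNifti <- function(vol, affine, path) {
  img <- RNifti::asNifti(array(vol, dim = dim(vol)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 4L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a GFC map (plus JSON sidecar) to NIfTI-1
#'
#' The map is embedded in the full grid as float32 with background 0; a
#' JSON sidecar records the subject id, z-order, gray-matter threshold
#' and a checksum of the mask voxel set, so the background encoding is
#' never ambiguous.
#'
#' @param map a [GFCMap-class].
#' @param path output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
writeGFCMap <- function(map, path) {
  mask <- map@mask
  write3DNifti(maskToVolume(map@values, mask), mask@affine, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  tmp <- tempfile()
  writeLines(paste(apply(mask@coords, 1L, paste, collapse = ","),
                   collapse = ";"), tmp)
  jsonlite::write_json(
    list(subject_id = map@subjectId, z_order = map@zOrder,
         gm_threshold = mask@threshold,
         mask_n_voxels = maskSize(mask),
         mask_checksum = unname(tools::md5sum(tmp))),
    sidecar, auto_unbox = TRUE)
  unlink(tmp)
  invisible(path)
}

#' Read a rigid-body motion trace (SPM rp_*.txt convention)
#'
#' Six whitespace-delimited columns, one row per frame: translations
#' along x/y/z in mm, then rotations about x/y/z in radians. Degrees are
#' supported only behind an explicit flag; units are never guessed.
#'
#' @param path path to the text file.
#' @param subjectId subject label; defaults to the file name stem.
#' @param rotationsInDegrees set `TRUE` if the rotation columns are in
#'   degrees; they are converted to radians on load.
#' @return a [MotionTrace-class].
#' @export
readMotionTrace <- function(path, subjectId = NULL,
                            rotationsInDegrees = FALSE) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion file must have 6 columns: ", path)
  if (rotationsInDegrees) m[, 4:6] <- m[, 4:6] * pi / 180
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  new("MotionTrace", params = unname(m), subjectId = subjectId)
}

#' Write a motion trace as 6-column whitespace-delimited text
#'
#' @param trace a [MotionTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotionTrace <- function(trace, path) {
  write.table(format(trace@params, digits = 10, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
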