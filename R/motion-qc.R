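#' Frame-wise displacement from rigid-body motion parameters
#'
#' Power-style FD: for frame t >= 2,
#' `FD_t = sum |delta translation| + radius * sum |delta rotation|`,
#' with rotations (radians) converted to arc length on a sphere of
#' `sphereRadius` mm (default 50 mm, the conventional head radius). The
#' first frame's FD is defined as 0. Only frame-to-frame differences
#' enter, so FD is invariant to constant offsets of the whole trace and
#' scales linearly with the trace.
#'
#' @param trace a [MotionTrace-class] with at least 2 frames.
#' @param sphereRadius mm; default 50.
#' @return an [FDSeries-class].
#' @examples
#' tr <- new("MotionTrace", params = rbind(rep(0, 6), c(rep(0.1, 3), rep(0.001, 3))),
#'           subjectId = "s1")
#' computeFD(tr)@fd  # 0, then 0.3 + 50 * 0.003 = 0.45
#' @export
computeFD <- function(trace, sphereRadius = 50) {
  m <- trace@params
  if (nrow(m) < 2L) stop("motion trace needs at least 2 frames")
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               sphereRadius * rowSums(d[, 4:6, drop = FALSE]))
  new("FDSeries", fd = fd, meanFD = mean(fd), subjectId = trace@subjectId)
}

#' Motion-based subject exclusion
#'
#' A subject is excluded when their mean FD exceeds `meanFdLimit`, or any
#' absolute translation exceeds `maxAbsTranslation` (mm), or any absolute
#' rotation exceeds `maxAbsRotationDeg` (degrees). The defaults (0.2 mm
#' mean FD; 2 mm; 2 degrees) follow common resting-state practice; all
#' three are configurable. The kept/excluded partition is exhaustive and
#' disjoint, and the returned log records which criterion each excluded
#' subject violated.
#'
#' @param fds list of [FDSeries-class].
#' @param traces list of [MotionTrace-class], aligned with `fds`.
#' @param meanFdLimit mm.
#' @param maxAbsTranslation mm.
#' @param maxAbsRotationDeg degrees.
#' @return list with `kept` and `excluded` (character vectors of subject
#'   ids) and `log`, a data.frame with one row per subject
#'   (`id`, `mean_fd`, `max_abs_translation`, `max_abs_rotation_deg`,
#'   `excluded`, `reason`).
#' @export
applyExclusion <- function(fds, traces, meanFdLimit = 0.2,
                           maxAbsTranslation = 2, maxAbsRotationDeg = 2) {
  if (any(c(meanFdLimit, maxAbsTranslation, maxAbsRotationDeg) <= 0))
    stop("exclusion limits must be positive")
  if (length(fds) != length(traces)) stop("fds and traces must align")
  if (!length(fds))
    return(list(kept = character(), excluded = character(),
                log = data.frame(id = character(), mean_fd = numeric(),
                                 max_abs_translation = numeric(),
                                 max_abs_rotation_deg = numeric(),
                                 excluded = logical(), reason = character())))
  rows <- lapply(seq_along(fds), function(i) {
    fd <- fds[[i]]; tr <- traces[[i]]
    if (!identical(fd@subjectId, tr@subjectId))
      stop("fds and traces must be in the same subject order")
    mt <- max(abs(tr@params[, 1:3]))
    mr <- max(abs(tr@params[, 4:6])) * 180 / pi
    reasons <- c(
      if (fd@meanFD > meanFdLimit)
        sprintf("mean FD %.3f > %g mm", fd@meanFD, meanFdLimit),
      if (mt > maxAbsTranslation)
        sprintf("translation %.2f > %g mm", mt, maxAbsTranslation),
      if (mr > maxAbsRotationDeg)
        sprintf("rotation %.2f > %g deg", mr, maxAbsRotationDeg))
    data.frame(id = fd@subjectId, mean_fd = fd@meanFD,
               max_abs_translation = mt, max_abs_rotation_deg = mr,
               excluded = length(reasons) > 0L,
               reason = if (length(reasons)) paste(reasons, collapse = "; ")
                        else "")
  })
  log <- do.call(rbind, rows)
  list(kept = log$id[!log$excluded], excluded = log$id[log$excluded],
       log = log)
}
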