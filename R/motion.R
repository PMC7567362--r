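#' Framewise displacement from rigid-body motion parameters
#'
#' Summarizes head motion between consecutive volumes as the sum of absolute
#' backward differences of the six rigid-body realignment parameters, with
#' rotations (radians) converted to millimetres of arc on a 50 mm head radius.
#' The first frame has no predecessor and gets FD = 0.
#'
#' @param motion matrix or data frame with 6 columns in realignment-file
#'   order: 3 translations (mm) then 3 rotations (radians)
#' @param head_radius_mm radius used to convert rotations to displacement
#' @return numeric vector of FD values (mm), one per frame
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stopf("motion table must have 6 columns (3 translations, 3 rotations), got %d",
          ncol(motion))
  }
  if (nrow(motion) < 2L) stopf("motion table must have at least 2 frames")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Frame retention mask from an FD trace
#'
#' @param fd framewise displacement per frame (mm)
#' @param fd_threshold censoring threshold in mm; frames with FD above it are
#'   dropped from correlation estimation
#' @return logical vector, `TRUE` for retained frames
#' @export
retained_frames <- function(fd, fd_threshold = 0.5) {
  fd <= fd_threshold
}
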