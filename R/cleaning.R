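#' Temporal-cleaning configuration
#'
#' Bundles the temporal preprocessing parameters applied to voxel (or ROI)
#' time courses before correlation: nuisance regression, band-pass filtering
#' and scrubbing thresholds. Defaults follow the standard resting-state
#' white-matter FC protocol: 24-parameter motion expansion plus mean CSF
#' regression, 0.01-0.1 Hz passband, tissue-probability cutoff 0.8 and an FD
#' censoring threshold of 0.5 mm.
#'
#' @param bandpass_hz length-2 numeric, low and high passband edges in Hz
#' @param use_motion24 regress out the 24-parameter motion expansion
#' @param use_csf regress out the mean CSF signal
#' @param probability_threshold tissue-probability cutoff in (0,1) for masks
#' @param fd_threshold framewise-displacement censoring threshold (mm)
#' @return a list of class `cleaning_config`
#' @export
cleaning_config <- function(bandpass_hz = c(0.01, 0.1), use_motion24 = TRUE,
                            use_csf = TRUE, probability_threshold = 0.8,
                            fd_threshold = 0.5) {
  stopifnot(length(bandpass_hz) == 2, bandpass_hz[1] > 0,
            bandpass_hz[2] > bandpass_hz[1])
  if (probability_threshold < 0 || probability_threshold >= 1) {
    stopf("probability_threshold must be in [0, 1)")
  }
  structure(list(bandpass_hz = as.numeric(bandpass_hz),
                 use_motion24 = isTRUE(use_motion24),
                 use_csf = isTRUE(use_csf),
                 probability_threshold = probability_threshold,
                 fd_threshold = fd_threshold),
            class = "cleaning_config")
}

#' 24-parameter motion expansion
#'
#' Expands 6 rigid-body parameters into the 24-regressor set: the parameters,
#' their one-frame-lagged copies (zero-padded at the first frame), and the
#' squares of both.
#'
#' @param motion frames x 6 matrix (3 translations mm, 3 rotations radians)
#' @return frames x 24 matrix
#' @export
motion24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion table must have 6 columns")
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lag_sq"))
  out
}

# Residualize columns of x on [intercept | design], dropping collinear
# design columns via pivoted QR. Returns residuals; dropped columns reported
# through the "dropped" attribute.
#' @noRd
project_out <- function(x, design) {
  x <- as.matrix(x)
  d <- cbind(intercept = 1, as.matrix(design))
  qrD <- qr(d)
  dropped <- character(0)
  if (qrD$rank < ncol(d)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    dropped <- colnames(d)[setdiff(seq_len(ncol(d)), keep)]
    d <- d[, keep, drop = FALSE]
    qrD <- qr(d)
  }
  res <- x - d %*% qr.coef(qrD, x)
  attr(res, "dropped") <- dropped
  res
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering with a 4th-order Butterworth
#' band-pass per pass direction.
#'
#' @param x frames x series numeric matrix (or vector)
#' @param tr_seconds repetition time in seconds (sampling interval)
#' @param band length-2 passband in Hz; must sit below the Nyquist frequency
#' @param order filter order per pass
#' @return filtered matrix of the same shape
#' @export
bandpass_filter <- function(x, tr_seconds, band = c(0.01, 0.1), order = 4) {
  x <- as.matrix(x)
  nyquist <- 1 / (2 * tr_seconds)
  if (band[2] >= nyquist) {
    stopf("passband upper edge %.4f Hz must be below Nyquist %.4f Hz",
          band[2], nyquist)
  }
  bf <- signal::butter(order, band / nyquist, type = "pass")
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  matrix(out, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
}

#' @noRd
detrend_linear <- function(x) {
  x <- as.matrix(x)
  t_idx <- seq_len(nrow(x))
  project_out(x, cbind(t = t_idx))
}

#' Column-wise z-normalization
#'
#' @param x frames x series matrix
#' @return matrix with each column scaled to zero mean, unit variance;
#'   zero-variance columns become `NA`
#' @export
znormalize <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- NA_real_
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

#' Temporal cleaning of voxel or ROI time courses
#'
#' Applies, in order: linear detrending, ordinary-least-squares removal of
#' nuisance regressors (24-parameter motion expansion and/or mean CSF
#' signal), zero-phase band-pass filtering, and column-wise z-normalization.
#' Collinear nuisance columns are dropped (and named in the `dropped_nuisance`
#' attribute) rather than causing failure.
#'
#' @param x frames x series numeric matrix of raw signals
#' @param motion frames x 6 motion-parameter table, or `NULL`
#' @param csf mean CSF signal per frame, or `NULL`
#' @param tr_seconds repetition time in seconds
#' @param config a [cleaning_config()]
#' @param normalize set `FALSE` to stop before z-normalization (useful for
#'   inspecting the projection steps)
#' @return cleaned matrix, same shape as `x`
#' @export
clean_timeseries <- function(x, motion = NULL, csf = NULL, tr_seconds,
                             config = cleaning_config(), normalize = TRUE) {
  x <- as.matrix(x)
  nuisance <- NULL
  if (config$use_motion24 && !is.null(motion)) {
    if (nrow(as.matrix(motion)) != nrow(x)) {
      stopf("motion table has %d frames but signals have %d",
            nrow(as.matrix(motion)), nrow(x))
    }
    nuisance <- motion24(motion)
  }
  if (config$use_csf && !is.null(csf)) {
    nuisance <- cbind(nuisance, csf = as.numeric(csf))
  }
  out <- detrend_linear(x)
  dropped <- character(0)
  if (!is.null(nuisance)) {
    out <- project_out(out, nuisance)
    dropped <- attr(out, "dropped")
  }
  out <- bandpass_filter(out, tr_seconds, config$bandpass_hz)
  if (normalize) out <- znormalize(out)
  attr(out, "dropped_nuisance") <- dropped
  out
}
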