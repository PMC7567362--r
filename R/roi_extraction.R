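#' ROI time-series container
#'
#' @param values frames x ROIs numeric matrix
#' @param roi_order character vector of ROI abbreviations, one per column
#' @param retained logical retention mask per frame (default all `TRUE`)
#' @param tr_seconds repetition time
#' @return list of class `roi_timeseries`
#' @export
roi_timeseries <- function(values, roi_order = colnames(values),
                           retained = rep(TRUE, nrow(values)), tr_seconds = 3) {
  values <- as.matrix(values)
  if (is.null(roi_order)) roi_order <- sprintf("R%03d", seq_len(ncol(values)))
  stopifnot(length(roi_order) == ncol(values), length(retained) == nrow(values))
  colnames(values) <- roi_order
  structure(list(values = values, roi_order = roi_order,
                 retained = as.logical(retained), tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries: %d frames x %d ROIs (TR %.2fs, %d retained)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds, sum(x$retained)))
  invisible(x)
}

#' Build per-ROI voxel masks from an atlas and a tissue-probability volume
#'
#' A voxel belongs to ROI r iff its atlas label equals r's label value AND
#' its tissue probability strictly exceeds the threshold. ROIs whose masks
#' come out empty are kept (so matrix shapes never change) and flagged.
#'
#' @param labels 3D integer array (or `RNifti` image) of atlas labels
#' @param probability 3D array of tissue probabilities on the same grid.
#'   Pass the WM probability map for WM rows and the GM map for GM rows, or a
#'   combined map if one volume covers both tissues.
#' @param registry an ROI registry ([load_roi_registry()])
#' @param threshold tissue-probability cutoff (default 0.8)
#' @return named list of integer voxel (linear) index vectors, one per
#'   registry row; empty ROIs carry names in the `empty_rois` attribute
#' @export
build_masks <- function(labels, probability, registry, threshold = 0.8) {
  labels <- as.array(labels)
  probability <- as.array(probability)
  if (!identical(dim(labels), dim(probability))) {
    stopf("atlas labels and probability volume are on different grids (%s vs %s)",
          paste(dim(labels), collapse = "x"),
          paste(dim(probability), collapse = "x"))
  }
  lab_vec <- as.integer(round(as.vector(labels)))
  prob_vec <- as.vector(probability)
  ok <- prob_vec > threshold
  masks <- lapply(seq_len(nrow(registry)), function(i) {
    which(lab_vec == registry$label[i] & ok)
  })
  names(masks) <- registry$abbreviation
  empty <- names(masks)[vapply(masks, length, 0L) == 0L]
  if (length(empty) > 0) {
    warnf("empty mask for %d ROI(s): %s", length(empty),
          paste(head(empty, 10), collapse = ", "))
  }
  attr(masks, "empty_rois") <- empty
  masks
}

#' Average cleaned voxel signals within ROI masks
#'
#' Column r of the result is the unweighted mean over r's voxels, followed by
#' per-column z-normalization so every ROI time course has zero mean and unit
#' variance. Empty masks give an all-`NA` column which downstream operations
#' skip (pairwise-complete handling).
#'
#' @param voxel_ts frames x voxels matrix of cleaned signals; columns indexed
#'   by linear voxel index
#' @param masks per-ROI voxel index list from [build_masks()]
#' @param registry the registry that ordered the masks
#' @param tr_seconds repetition time recorded on the result
#' @param renormalize re-z-score each ROI mean (default `TRUE`)
#' @return a [roi_timeseries()] with one column per registry row
#' @export
extract_roi_means <- function(voxel_ts, masks, registry, tr_seconds = 3,
                              renormalize = TRUE) {
  voxel_ts <- as.matrix(voxel_ts)
  vals <- vapply(registry$abbreviation, function(ab) {
    idx <- masks[[ab]]
    if (length(idx) == 0) return(rep(NA_real_, nrow(voxel_ts)))
    rowMeans(voxel_ts[, idx, drop = FALSE])
  }, numeric(nrow(voxel_ts)))
  if (renormalize) {
    keep <- !apply(vals, 2, function(v) all(is.na(v)))
    vals[, keep] <- znormalize(vals[, keep, drop = FALSE])
  }
  roi_timeseries(vals, roi_order = registry$abbreviation,
                 tr_seconds = tr_seconds)
}

#' Read a 4D BOLD NIfTI volume as a frames x voxels matrix
#'
#' @param path path to a NIfTI-1 file (4D)
#' @return list with `values` (frames x voxels, voxels in column-major linear
#'   order of the spatial grid), `dim` (spatial dimensions) and `tr_seconds`
#'   (from the NIfTI pixdim, if present)
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stopf("expected a 4D BOLD volume, got %dD", length(dim(arr)))
  d <- dim(arr)
  values <- t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
  tr <- tryCatch(RNifti::pixdim(img)[4], error = function(e) NA_real_)
  if (!is.finite(tr) || tr <= 0) tr <- NA_real_
  list(values = values, dim = d[1:3], tr_seconds = tr)
}

#' Write an ROI time-series table as TSV
#'
#' The layout is one row per frame, one column per ROI (header = registry
#' abbreviations), plus a final `retained` column holding the frame-retention
#' mask as 0/1.
#'
#' @param ts a [roi_timeseries()]
#' @param path output path
#' @export
write_roi_timeseries <- function(ts, path) {
  df <- as.data.frame(ts$values)
  df$retained <- as.integer(ts$retained)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI time-series TSV written by [write_roi_timeseries()]
#'
#' @param path input path
#' @param tr_seconds repetition time to record
#' @return a [roi_timeseries()]
#' @export
read_roi_timeseries <- function(path, tr_seconds = 3) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  retained <- if ("retained" %in% names(df)) df$retained > 0 else rep(TRUE, nrow(df))
  df$retained <- NULL
  roi_timeseries(as.matrix(df), retained = retained, tr_seconds = tr_seconds)
}
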