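#' Load the packaged ROI registry
#'
#' The registry enumerates the 130 regions of interest used throughout the
#' pipeline: 48 deep white-matter tracts (21 per hemisphere plus 6 commissural
#' / midline tracts, following the Eve white-matter parcellation) and 82
#' gray-matter regions (41 Brodmann areas per hemisphere). Row order of the
#' registry fixes row/column order of every functional-correlation matrix.
#'
#' @param path optional path to a registry CSV; defaults to the packaged file
#' @return a `data.frame` with columns `abbreviation`, `name`, `tissue`
#'   (`"WM"`/`"GM"`), `hemisphere` (`"left"`/`"right"`/`"midline"`) and
#'   `label` (the integer label value in an atlas volume), class
#'   `roi_registry`
#' @export
load_roi_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "roi_registry.csv", package = "wmfc")
  }
  if (!file.exists(path)) stopf("registry file not found: %s", path)
  reg <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("abbreviation", "name", "tissue", "hemisphere", "label")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    stopf("registry is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  class(reg) <- c("roi_registry", "data.frame")
  reg
}

#' Validate an ROI registry file against the expected parcellation
#'
#' Checks the tissue and hemisphere bookkeeping of a registry: 48 WM entries
#' (21 left + 21 right + 6 midline) and 82 GM entries (41 left + 41 right),
#' unique abbreviations, unique labels. A count mismatch is reported naming
#' the missing or extra abbreviations relative to the packaged registry.
#'
#' @param path path to a registry CSV (or `NULL` for the packaged one)
#' @return the validated registry, invisibly classed `roi_registry`
#' @export
validate_registry <- function(path = NULL) {
  reg <- load_roi_registry(path)
  ref <- if (is.null(path)) reg else load_roi_registry(NULL)

  dup <- reg$abbreviation[duplicated(reg$abbreviation)]
  if (length(dup) > 0) {
    stopf("registry has duplicated abbreviation(s): %s",
          paste(unique(dup), collapse = ", "))
  }
  missing <- setdiff(ref$abbreviation, reg$abbreviation)
  extra <- setdiff(reg$abbreviation, ref$abbreviation)
  n_wm <- sum(reg$tissue == "WM")
  n_gm <- sum(reg$tissue == "GM")
  if (n_wm != 48L || n_gm != 82L) {
    stopf(paste0("registry must contain 48 WM and 82 GM ROIs, found %d WM / %d GM",
                 if (length(missing) > 0) "; missing: %s" else "%s",
                 if (length(extra) > 0) "; unexpected: %s" else "%s"),
          n_wm, n_gm,
          if (length(missing) > 0) paste(missing, collapse = ", ") else "",
          if (length(extra) > 0) paste(extra, collapse = ", ") else "")
  }
  wm <- reg[reg$tissue == "WM", ]
  gm <- reg[reg$tissue == "GM", ]
  if (sum(wm$hemisphere == "left") != 21L || sum(wm$hemisphere == "right") != 21L ||
      sum(wm$hemisphere == "midline") != 6L) {
    stopf("WM hemisphere breakdown must be 21 left + 21 right + 6 midline")
  }
  if (sum(gm$hemisphere == "left") != 41L || sum(gm$hemisphere == "right") != 41L) {
    stopf("GM hemisphere breakdown must be 41 left + 41 right")
  }
  if (anyDuplicated(reg$label)) stopf("registry label values must be unique")
  invisible(reg)
}

#' Build a small generic registry for toy or simulation use
#'
#' The analysis operations only need a registry with tissue classes and an
#' order; this makes one of arbitrary size for tests and small simulations.
#'
#' @param n_wm number of white-matter entries
#' @param n_gm number of gray-matter entries
#' @return a `roi_registry` data frame with `n_wm + n_gm` rows
#' @export
make_toy_registry <- function(n_wm, n_gm) {
  stopifnot(n_wm >= 1, n_gm >= 1)
  reg <- data.frame(
    abbreviation = c(sprintf("W%02d", seq_len(n_wm)), sprintf("G%02d", seq_len(n_gm))),
    name = c(sprintf("toy white-matter tract %d", seq_len(n_wm)),
             sprintf("toy gray-matter region %d", seq_len(n_gm))),
    tissue = c(rep("WM", n_wm), rep("GM", n_gm)),
    hemisphere = rep(c("left", "right"), length.out = n_wm + n_gm),
    label = seq_len(n_wm + n_gm),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("roi_registry", "data.frame")
  reg
}
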