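#' Motion-censored Pearson correlation of ROI time courses
#'
#' Computes the full ROI x ROI Pearson correlation matrix using exactly the
#' frames whose framewise displacement is at or below the threshold (and
#' which the series' own retention mask keeps). The result equals textbook
#' Pearson correlation on the physically truncated series.
#'
#' @param series a [roi_timeseries()]
#' @param fd framewise displacement per frame, or `NULL` to skip FD censoring
#' @param fd_threshold censoring threshold in mm
#' @param min_frames minimum number of retained frames; fewer raises an error
#'   of class `wmfc_too_few_frames` so callers can flag and exclude the
#'   subject
#' @return ROI x ROI correlation matrix with the retained-frame count in the
#'   `n_retained` attribute
#' @export
censored_correlation <- function(series, fd = NULL, fd_threshold = 0.5,
                                 min_frames = 10) {
  keep <- series$retained
  if (!is.null(fd)) {
    if (length(fd) != nrow(series$values)) {
      stopf("FD trace length %d does not match %d frames",
            length(fd), nrow(series$values))
    }
    keep <- keep & (fd <= fd_threshold)
  }
  n_kept <- sum(keep)
  if (n_kept < min_frames) {
    stop(structure(class = c("wmfc_too_few_frames", "error", "condition"),
                   list(message = sprintf(
                     "too few retained frames (%d < %d) after motion censoring",
                     n_kept, min_frames), call = sys.call())))
  }
  r <- suppressWarnings(cor(series$values[keep, , drop = FALSE],
                            use = "pairwise.complete.obs"))
  attr(r, "n_retained") <- n_kept
  r
}

#' Assemble a functional-correlation matrix of one kind
#'
#' Selects and orders rows/columns of a full ROI correlation matrix according
#' to the registry: `WG` takes WM rows x GM columns (48 x 82 for the packaged
#' registry), `WW` WM x WM, `GG` GM x GM.
#'
#' @param correlations full ROI x ROI correlation matrix with abbreviation
#'   dimnames (e.g. from [censored_correlation()])
#' @param registry the ROI registry fixing the order
#' @param kind one of `"WG"`, `"WW"`, `"GG"`
#' @param subject optional subject id tag
#' @return list of class `fc_matrix` with `kind`, `values`, `row_labels`,
#'   `col_labels`, `subject`, `n_retained_frames`
#' @export
assemble_fcm <- function(correlations, registry, kind = c("WG", "WW", "GG"),
                         subject = NA_character_) {
  kind <- match.arg(kind)
  wm <- registry$abbreviation[registry$tissue == "WM"]
  gm <- registry$abbreviation[registry$tissue == "GM"]
  rows <- if (kind == "GG") gm else wm
  cols <- if (kind == "WW") wm else gm
  missing_lab <- setdiff(c(rows, cols), rownames(correlations))
  if (length(missing_lab) > 0) {
    stopf("correlation matrix lacks ROI(s): %s",
          paste(head(missing_lab, 5), collapse = ", "))
  }
  vals <- correlations[rows, cols, drop = FALSE]
  structure(list(kind = kind, values = vals, row_labels = rows,
                 col_labels = cols, subject = subject,
                 n_retained_frames = attr(correlations, "n_retained") %||% NA_integer_),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix %s: %d x %d (%s, %s retained frames)\n", x$kind,
              nrow(x$values), ncol(x$values), x$subject,
              x$n_retained_frames))
  invisible(x)
}

#' Flatten a functional-correlation matrix to its element vector
#'
#' `WG` uses all row x column elements in column-major order; the symmetric
#' kinds (`WW`, `GG`) use the strict upper triangle so each pair appears
#' once. Element names are `"row|col"` abbreviation pairs.
#'
#' @param fcm an `fc_matrix`
#' @return named numeric vector (length 3936 for a packaged-registry WG,
#'   1128 for WW)
#' @export
fcm_vector <- function(fcm) {
  v <- fcm$values
  if (fcm$kind == "WG") {
    out <- as.vector(v)
    names(out) <- as.vector(outer(fcm$row_labels, fcm$col_labels, paste, sep = "|"))
  } else {
    ut <- upper.tri(v)
    out <- v[ut]
    names(out) <- outer(fcm$row_labels, fcm$col_labels, paste, sep = "|")[ut]
  }
  out
}

#' Stack per-subject FC matrices into a subjects x elements matrix
#'
#' @param fcms named list of `fc_matrix` objects of one common kind
#' @return subjects x elements numeric matrix, rownames = subject ids,
#'   colnames = element names; the kind and matrix shape travel in the
#'   `kind`, `row_labels` and `col_labels` attributes
#' @export
stack_fcms <- function(fcms) {
  stopifnot(length(fcms) > 0)
  kinds <- unique(vapply(fcms, `[[`, "", "kind"))
  if (length(kinds) != 1) stopf("cannot stack FC matrices of mixed kinds")
  mat <- do.call(rbind, lapply(fcms, fcm_vector))
  rownames(mat) <- names(fcms)
  attr(mat, "kind") <- kinds
  attr(mat, "row_labels") <- fcms[[1]]$row_labels
  attr(mat, "col_labels") <- fcms[[1]]$col_labels
  mat
}

#' Reshape one stacked element vector back into matrix form
#'
#' Inverse of [fcm_vector()] for display and tract-wise averaging: `WG`
#' vectors refill the 48 x 82 rectangle; `WW`/`GG` vectors refill a symmetric
#' matrix with `NA` on the diagonal (the self-correlation is not an element).
#'
#' @param vec element vector (one row of a stack, or any derived per-element
#'   statistic such as a p-value vector)
#' @param stack the stack the vector's layout came from (for its attributes)
#' @return matrix with ROI dimnames
#' @export
unstack_fcm <- function(vec, stack) {
  kind <- attr(stack, "kind")
  rl <- attr(stack, "row_labels")
  cl <- attr(stack, "col_labels")
  if (kind == "WG") {
    matrix(vec, length(rl), length(cl), dimnames = list(rl, cl))
  } else {
    m <- matrix(NA_real_, length(rl), length(cl), dimnames = list(rl, cl))
    m[upper.tri(m)] <- vec
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
}

#' Combine WG and WW stacks into the full WM feature matrix
#'
#' The complete white-matter FC feature set of one subject is the 3936 WM-GM
#' elements plus the 1128 distinct WM-WM elements: 5064 features for the
#' packaged registry.
#'
#' @param wg_stack subjects x elements WG stack
#' @param ww_stack subjects x elements WW stack (same subjects, same order)
#' @return subjects x features matrix with element names prefixed by kind
#' @export
fcm_features <- function(wg_stack, ww_stack) {
  stopifnot(identical(rownames(wg_stack), rownames(ww_stack)))
  out <- cbind(wg_stack, ww_stack)
  colnames(out) <- c(paste0("WG:", colnames(wg_stack)),
                     paste0("WW:", colnames(ww_stack)))
  out
}

#' Residualize FC elements on nuisance covariates across subjects
#'
#' For every FC element, fits an ordinary-least-squares model of the
#' across-subject element values on age, sex, years of education and
#' acquisition site (dummy-encoded, reference level dropped) and replaces the
#' values by residual + grand mean, so group means remain interpretable on
#' the correlation scale. Rank-deficient dummy columns are dropped with a
#' message; elements with missing entries are handled on their complete
#' subjects only.
#'
#' @param stack subjects x elements matrix ([stack_fcms()])
#' @param covariates data frame aligned with the stack rows, with columns
#'   `age`, `sex`, `education`, `site`
#' @param center_back add the grand mean back to the residuals (default
#'   `TRUE`); `FALSE` returns plain residuals
#' @return residualized stack with the same shape and attributes
#' @export
partial_out_covariates <- function(stack, covariates, center_back = TRUE) {
  stopifnot(nrow(covariates) == nrow(stack))
  design <- covariate_design(covariates)
  out <- stack
  cc <- complete.cases(design)
  full <- cc & rowSums(is.na(stack)) == 0
  # one QR for the (typical) case of no missing data anywhere
  resid_block <- function(y, d) {
    r <- project_out(y, scale(d, scale = FALSE))
    if (center_back) r <- sweep(r, 2, colMeans(y), "+")
    r
  }
  if (all(full)) {
    out[] <- resid_block(stack, design)
  } else {
    complete_elems <- colSums(is.na(stack[cc, , drop = FALSE])) == 0
    if (any(complete_elems)) {
      out[cc, complete_elems] <-
        resid_block(stack[cc, complete_elems, drop = FALSE],
                    design[cc, , drop = FALSE])
    }
    for (j in which(!complete_elems)) {
      ok <- cc & !is.na(stack[, j])
      if (sum(ok) > ncol(design) + 2) {
        out[ok, j] <- resid_block(stack[ok, j, drop = FALSE],
                                  design[ok, , drop = FALSE])
      }
    }
  }
  for (a in c("kind", "row_labels", "col_labels")) {
    attr(out, a) <- attr(stack, a)
  }
  out
}

# Dummy-encode the covariate table (site reference level dropped).
#' @noRd
covariate_design <- function(covariates) {
  needed <- c("age", "sex", "education")
  missing_cols <- setdiff(needed, names(covariates))
  if (length(missing_cols) > 0) {
    stopf("covariate table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  d <- cbind(age = as.numeric(covariates$age),
             sex = as.numeric(covariates$sex),
             education = as.numeric(covariates$education))
  if ("site" %in% names(covariates)) {
    site <- factor(covariates$site)
    if (nlevels(site) > 1) {
      dm <- stats::model.matrix(~site)[, -1, drop = FALSE]
      d <- cbind(d, dm)
    }
  }
  d
}

#' Fisher z-transform of correlation values
#'
#' Variance-stabilizing `atanh` transform. The analysis pipeline averages
#' and tests raw correlation coefficients by convention; this transform is
#' provided as an opt-in alternative (`fisher_z = TRUE` in
#' [cohort_fcm_stacks()]) and is never applied by default.
#'
#' @param r correlations in (-1, 1); values at exactly +/-1 are nudged by
#'   1e-15 to keep the transform finite
#' @return transformed values
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
}

#' Per-subject FC stacks for a whole cohort
#'
#' Convenience wrapper running motion censoring, censored correlation and
#' FCM assembly for every subject of a (typically simulated) cohort. Subjects
#' falling below the retained-frame floor are excluded and listed.
#'
#' @param cohort a [simulate_cohort()] result (or any list with the same
#'   layout)
#' @param kinds which FCM kinds to stack
#' @param fd_threshold FD censoring threshold (mm)
#' @param min_frames retained-frame floor
#' @param fisher_z apply [fisher_z()] to the stacked elements (default
#'   `FALSE`: raw correlations are averaged and tested)
#' @return list with one stack per kind, the filtered cohort `table`, and
#'   `excluded` (named character vector of excluded subject ids with reasons)
#' @export
cohort_fcm_stacks <- function(cohort, kinds = c("WG", "WW"),
                              fd_threshold = 0.5, min_frames = 10,
                              fisher_z = FALSE) {
  fcms <- lapply(kinds, function(k) list())
  names(fcms) <- kinds
  excluded <- character(0)
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    fd <- framewise_displacement(s$motion)
    r <- tryCatch(
      censored_correlation(s$series, fd, fd_threshold = fd_threshold,
                           min_frames = min_frames),
      wmfc_too_few_frames = function(e) e)
    if (inherits(r, "condition")) {
      excluded[id] <- conditionMessage(r)
      next
    }
    for (k in kinds) {
      fcms[[k]][[id]] <- assemble_fcm(r, cohort$registry, k, subject = id)
    }
  }
  kept <- setdiff(names(cohort$subjects), names(excluded))
  if (length(kept) == 0) stopf("no subjects survive motion censoring")
  stacks <- lapply(fcms, stack_fcms)
  if (isTRUE(fisher_z)) {
    stacks <- lapply(stacks, function(s) {
      s[] <- atanh(pmin(pmax(s, -1 + 1e-15), 1 - 1e-15))
      s
    })
  }
  tab <- cohort$table[match(kept, cohort$table$subject), , drop = FALSE]
  c(stacks, list(table = tab, excluded = excluded))
}
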