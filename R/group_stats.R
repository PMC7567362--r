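#' Element-wise group means of an FC stack
#'
#' @param stack subjects x elements matrix ([stack_fcms()])
#' @param labels group label per subject (factor or character)
#' @return groups x elements matrix of means (missing entries skipped, counts
#'   of skipped entries in the `n_missing` attribute)
#' @export
mean_fcm <- function(stack, labels) {
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) {
    stopf("empty group(s): %s",
          paste(levels(labels)[table(labels) == 0], collapse = ", "))
  }
  out <- t(vapply(levels(labels), function(g) {
    colMeans(stack[labels == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(stack))))
  attr(out, "n_missing") <- t(vapply(levels(labels), function(g) {
    colSums(is.na(stack[labels == g, , drop = FALSE]))
  }, numeric(ncol(stack))))
  out
}

#' Element-wise two-group permutation test on an FC stack
#'
#' The statistic for each element is the difference of group means. Labels
#' are shuffled jointly across elements within each permutation, preserving
#' the dependence structure between elements, and the two-sided p-value uses
#' the add-one correction \eqn{p = (1 + \#\{|T^*| \ge |T|\}) / (n_{perm}+1)}.
#'
#' @param stack subjects x elements matrix
#' @param labels group label per subject
#' @param contrast length-2 character, the two groups to compare (first minus
#'   second)
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed
#' @param chunk permutations per matrix-multiply block (memory knob)
#' @return list with `statistic` (observed mean difference per element) and
#'   `p` (permutation p-value per element)
#' @export
permutation_test <- function(stack, labels, contrast, n_perm = 10000,
                             seed = 1, chunk = 500) {
  labels <- as.character(labels)
  sel <- labels %in% contrast
  x <- stack[sel, , drop = FALSE]
  g <- labels[sel]
  n1 <- sum(g == contrast[1]); n2 <- sum(g == contrast[2])
  if (n1 == 0 || n2 == 0) stopf("contrast group missing from labels")
  if (n_perm < 100) warnf("n_perm = %d is very small; p-values will be coarse", n_perm)
  n <- n1 + n2
  has_na <- anyNA(x)
  x0 <- x
  if (has_na) x0[is.na(x0)] <- 0  # handled via count matrices below
  ones <- !is.na(x)
  obs <- colMeans(x[g == contrast[1], , drop = FALSE], na.rm = TRUE) -
         colMeans(x[g == contrast[2], , drop = FALSE], na.rm = TRUE)
  set.seed(seed)
  count <- numeric(ncol(x))
  done <- 0
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    # indicator matrix of permuted group-1 memberships
    W <- matrix(0, b, n)
    for (i in seq_len(b)) W[i, sample.int(n, n1)] <- 1
    if (!has_na) {
      stat <- (W %*% x0) / n1 - ((1 - W) %*% x0) / n2
    } else {
      s1 <- W %*% x0; c1 <- W %*% ones
      s2 <- (1 - W) %*% x0; c2 <- (1 - W) %*% ones
      stat <- s1 / pmax(c1, 1) - s2 / pmax(c2, 1)
    }
    count <- count + colSums(abs(stat) >= matrix(abs(obs), b, ncol(x), byrow = TRUE))
    done <- done + b
  }
  p <- (1 + count) / (n_perm + 1)
  list(statistic = obs, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values over the whole family of elements under test
#' (all elements of one FC matrix kind). A thin wrapper around
#' [stats::p.adjust()] that preserves matrix shape.
#'
#' @param p numeric vector or matrix of p-values
#' @return adjusted p-values of the same shape
#' @export
fdr_adjust <- function(p) {
  out <- p.adjust(as.numeric(p), method = "BH")
  if (!is.null(dim(p))) dim(out) <- dim(p)
  if (!is.null(names(p))) names(out) <- names(p)
  if (!is.null(dimnames(p))) dimnames(out) <- dimnames(p)
  out
}

#' Element-wise effect size (Cohen's d) between two groups
#'
#' Standardized mean difference with pooled standard deviation; the sign is
#' mean(first group) minus mean(second group). Elements with zero pooled SD
#' give `NA`.
#'
#' @inheritParams permutation_test
#' @return numeric vector of d values per element
#' @export
effect_size <- function(stack, labels, contrast) {
  labels <- as.character(labels)
  x1 <- stack[labels == contrast[1], , drop = FALSE]
  x2 <- stack[labels == contrast[2], , drop = FALSE]
  n1 <- colSums(!is.na(x1)); n2 <- colSums(!is.na(x2))
  m1 <- colMeans(x1, na.rm = TRUE); m2 <- colMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 2, var, na.rm = TRUE); v2 <- apply(x2, 2, var, na.rm = TRUE)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  d[!is.finite(d)] <- NA_real_
  d
}

#' Full two-group FC comparison bundle
#'
#' Runs the mean matrices, difference, permutation test, FDR adjustment,
#' effect sizes and the FDR-thresholded difference for one CN-vs-X contrast.
#'
#' @inheritParams permutation_test
#' @param alpha significance level for the thresholded difference
#' @return list of class `group_comparison` with `contrast`, `mean_by_group`,
#'   `difference`, `p_perm`, `p_fdr`, `effect_size`,
#'   `thresholded_difference` (difference zeroed where `p_fdr > alpha`) and
#'   `alpha`; all element-wise fields are vectors laid out like the stack
#'   columns (use [unstack_fcm()] for matrix form)
#' @export
group_comparison <- function(stack, labels, contrast, n_perm = 10000,
                             alpha = 0.05, seed = 1) {
  labels <- as.character(labels)
  sel <- labels %in% contrast
  means <- mean_fcm(stack[sel, , drop = FALSE], factor(labels[sel], levels = contrast))
  pt <- permutation_test(stack, labels, contrast, n_perm = n_perm, seed = seed)
  p_fdr <- fdr_adjust(pt$p)
  d <- effect_size(stack, labels, contrast)
  diff <- means[contrast[1], ] - means[contrast[2], ]
  thr <- diff
  thr[p_fdr > alpha | is.na(p_fdr)] <- 0
  structure(list(contrast = contrast, mean_by_group = means, difference = diff,
                 p_perm = pt$p, p_fdr = p_fdr, effect_size = d,
                 thresholded_difference = thr, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison %s vs %s: %d elements, %d significant at FDR %.2f\n",
              x$contrast[1], x$contrast[2], length(x$p_fdr),
              sum(x$p_fdr <= x$alpha, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Tract-wise FC: average each WM tract's row of an FC matrix
#'
#' For a WG matrix, each tract's value is the mean of its 82 gray-matter
#' elements; for a WW matrix, the mean of its row entries excluding the
#' self-correlation diagonal (set `include_diagonal = TRUE` for the inclusive
#' reading of the 48-element average).
#'
#' @param values an `fc_matrix`, or a plain matrix in WG/WW layout
#' @param kind matrix kind, inferred from an `fc_matrix` input
#' @param include_diagonal include the unit diagonal in WW averages
#' @return named numeric vector, one value per WM tract
#' @export
tractwise_fc <- function(values, kind = NULL, include_diagonal = FALSE) {
  if (inherits(values, "fc_matrix")) {
    kind <- values$kind
    values <- values$values
  }
  if (is.null(kind)) stopf("kind must be given for plain-matrix input")
  if (!kind %in% c("WG", "WW")) stopf("tract-wise FC is defined for WG and WW only")
  if (kind == "WW" && !include_diagonal) {
    v <- values
    diag(v) <- NA
    rowMeans(v, na.rm = TRUE)
  } else {
    rowMeans(values, na.rm = TRUE)
  }
}

#' Per-subject tract-wise FC from a stack
#'
#' @param stack subjects x elements matrix of kind WG or WW
#' @param include_diagonal see [tractwise_fc()]
#' @return subjects x tracts matrix
#' @export
tractwise_fc_stack <- function(stack, include_diagonal = FALSE) {
  kind <- attr(stack, "kind")
  t(apply(stack, 1, function(row) {
    tractwise_fc(unstack_fcm(row, stack), kind = kind,
                 include_diagonal = include_diagonal)
  }))
}

#' Tract-wise two-sample t-tests between groups
#'
#' Unpaired two-sided t-tests comparing each WM tract's per-subject FC
#' between the two contrast groups, with conventional significance stars.
#'
#' @param tract_values subjects x tracts matrix ([tractwise_fc_stack()])
#' @param labels group label per subject
#' @param contrast length-2 character
#' @param var_equal use the pooled-variance Student test (default); `FALSE`
#'   gives Welch
#' @return data frame with tract, group means/SDs, `t`, `p` and `stars`
#' @export
tract_ttest <- function(tract_values, labels, contrast, var_equal = TRUE) {
  labels <- as.character(labels)
  x1 <- tract_values[labels == contrast[1], , drop = FALSE]
  x2 <- tract_values[labels == contrast[2], , drop = FALSE]
  if (nrow(x1) < 2 || nrow(x2) < 2) stopf("need at least 2 subjects per group")
  res <- lapply(seq_len(ncol(tract_values)), function(j) {
    a <- x1[, j]; b <- x2[, j]
    tt <- tryCatch(t.test(a, b, var.equal = var_equal),
                   error = function(e) NULL)
    data.frame(tract = colnames(tract_values)[j],
               mean_1 = mean(a, na.rm = TRUE), sd_1 = sd(a, na.rm = TRUE),
               mean_2 = mean(b, na.rm = TRUE), sd_2 = sd(b, na.rm = TRUE),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$stars <- p_stars(out$p)
  names(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", contrast[1]), paste0("sd_", contrast[1]),
                                 paste0("mean_", contrast[2]), paste0("sd_", contrast[2]))
  out
}

#' Per-subject overall FC
#'
#' The mean over all elements of one subject's FC matrix of one kind (all
#' 3936 WG elements, or all distinct off-diagonal WW elements).
#'
#' @param stack subjects x elements matrix
#' @return numeric vector, one overall-FC value per subject
#' @export
overall_fc <- function(stack) {
  rowMeans(stack, na.rm = TRUE)
}

#' Normalized overall-FC trend across clinical groups
#'
#' Computes group means and SDs of overall FC, then applies the single affine
#' map that sends the CN group mean to exactly 1 and the ADD group mean to
#' exactly 0 to every group's mean and SD:
#' \eqn{x' = (x - m_{ADD}) / (m_{CN} - m_{ADD})}, SDs scaled by
#' \eqn{1/(m_{CN} - m_{ADD})}.
#'
#' @param overall per-subject overall FC ([overall_fc()])
#' @param labels group label per subject
#' @param anchor_high group mapped to 1 (default `"CN"`)
#' @param anchor_low group mapped to 0 (default `"ADD"`)
#' @return data frame with group, raw and normalized mean and SD, ordered by
#'   the label factor levels
#' @export
overall_fc_trend <- function(overall, labels, anchor_high = "CN",
                             anchor_low = "ADD") {
  labels <- as.factor(labels)
  if (!all(c(anchor_high, anchor_low) %in% levels(labels))) {
    stopf("both anchor groups (%s, %s) must be present", anchor_high, anchor_low)
  }
  m <- tapply(overall, labels, mean, na.rm = TRUE)
  s <- tapply(overall, labels, sd, na.rm = TRUE)
  scale_den <- m[[anchor_high]] - m[[anchor_low]]
  if (abs(scale_den) < 1e-15) {
    stopf("anchor group means are equal; normalization is undefined")
  }
  data.frame(group = levels(labels),
             mean = as.numeric(m), sd = as.numeric(s),
             mean_normalized = as.numeric((m - m[[anchor_low]]) / scale_den),
             sd_normalized = as.numeric(s / scale_den),
             stringsAsFactors = FALSE)
}

#' Normalize group means/SDs of any measure by the same CN/ADD anchoring
#'
#' Applies the overall-FC normalization convention to an arbitrary
#' per-subject measure (e.g. a neuropsychological score) so its group trend
#' can be drawn on the same 0-1 axis.
#'
#' @inheritParams overall_fc_trend
#' @param values per-subject values
#' @return data frame as in [overall_fc_trend()]
#' @export
normalized_group_trend <- function(values, labels, anchor_high = "CN",
                                   anchor_low = "ADD") {
  overall_fc_trend(values, labels, anchor_high, anchor_low)
}
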