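#' Element-wise correlation between FC elements and a set of scores
#'
#' For every FC element and every neuropsychological score, the Pearson
#' correlation across subjects with pairwise-complete data, its two-sided
#' p-value, the Benjamini-Hochberg adjustment over the element family of
#' that score, and a display copy with non-surviving coefficients set to
#' zero.
#'
#' @param stack subjects x elements matrix ([stack_fcms()])
#' @param scores data frame of per-subject scores (rows aligned with the
#'   stack); missing values allowed
#' @param alpha FDR level for the zeroed copy
#' @param min_pairs minimum complete pairs per element (default 3)
#' @return list of class `score_association` with per-score lists holding
#'   `r`, `p`, `p_fdr` and `r_zeroed` element vectors; scores that are
#'   constant across subjects give all-`NA` entries
#' @export
elementwise_score_correlation <- function(stack, scores, alpha = 0.05,
                                          min_pairs = 3) {
  stopifnot(nrow(scores) == nrow(stack))
  out <- list()
  for (sc in names(scores)) {
    s <- as.numeric(scores[[sc]])
    ok <- !is.na(s)
    if (sum(ok) < min_pairs || sd(s[ok]) == 0) {
      na_vec <- setNames(rep(NA_real_, ncol(stack)), colnames(stack))
      out[[sc]] <- list(r = na_vec, p = na_vec, p_fdr = na_vec,
                        r_zeroed = na_vec)
      next
    }
    x <- stack[ok, , drop = FALSE]
    n_pair <- colSums(!is.na(x))
    r <- suppressWarnings(as.numeric(cor(s[ok], x, use = "pairwise.complete.obs")))
    r[n_pair < min_pairs] <- NA_real_
    tstat <- r * sqrt((n_pair - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * pt(abs(tstat), df = n_pair - 2, lower.tail = FALSE)
    p_fdr <- fdr_adjust(p)
    rz <- r
    rz[is.na(p_fdr) | p_fdr > alpha] <- 0
    names(r) <- names(p) <- names(p_fdr) <- names(rz) <- colnames(stack)
    out[[sc]] <- list(r = r, p = p, p_fdr = p_fdr, r_zeroed = rz)
  }
  structure(out, class = "score_association", alpha = alpha,
            kind = attr(stack, "kind"),
    row_labels = attr(stack, "row_labels"),
    col_labels = attr(stack, "col_labels"))
}

#' Tract-averaged FC-score correlation coefficients
#'
#' Averages the element-wise correlation coefficients of one score along
#' each WM tract's row (over all 82 GM partners for WG; over the 47 distinct
#' WM partners for WW), conventionally applied to the FDR-zeroed coefficient
#' matrix.
#'
#' @param r element vector of correlation coefficients (e.g. the `r_zeroed`
#'   field of [elementwise_score_correlation()])
#' @param stack the stack that defined the element layout
#' @return named numeric vector, one mean coefficient per WM tract (or per
#'   GM region for a GG stack)
#' @export
tract_average_correlation <- function(r, stack) {
  m <- unstack_fcm(r, stack)
  if (attr(stack, "kind") == "WG") rowMeans(m) else rowMeans(m, na.rm = TRUE)
}

#' Random-forest regression of a score on FC features
#'
#' Predicts one neuropsychological score from FC features: random-forest
#' permutation importance, cumulative feature selection under the regression
#' criterion (cross-validated MSE), then out-of-fold predictions of a random
#' forest on the optimal feature set from 10-fold cross-validation. Reported
#' are the Pearson correlation between true and out-of-fold predicted
#' scores, its p-value, and R^2. By convention R^2 is the squared
#' true-vs-predicted correlation; `r2_method = "variance"` gives
#' 1 - SSE/SST instead.
#'
#' @param features subjects x features matrix (e.g. [fcm_features()])
#' @param score numeric score per subject; subjects with a missing score are
#'   dropped
#' @param n_trees trees per forest
#' @param chunk selection step size
#' @param folds CV folds
#' @param seed RNG seed
#' @param r2_method `"correlation"` (default) or `"variance"`
#' @param min_subjects refuse below this many scored subjects
#' @param max_size cap on the cumulative selection curve ([select_features()])
#' @return list of class `score_regression`: `predicted` (out-of-fold),
#'   `observed`, `r`, `r2`, `p`, `selection`, `subjects`
#' @export
rf_score_regression <- function(features, score, n_trees = 200, chunk = 5,
                                folds = 10, seed = 1,
                                r2_method = c("correlation", "variance"),
                                min_subjects = 20, max_size = Inf) {
  r2_method <- match.arg(r2_method)
  ok <- !is.na(score)
  if (sum(ok) < min_subjects) {
    stopf("only %d subjects have this score (need >= %d)", sum(ok), min_subjects)
  }
  x <- as.matrix(features)[ok, , drop = FALSE]
  y <- as.numeric(score[ok])
  imp <- rf_importance(x, y, n_trees = n_trees, seed = derive_seed(seed, "rimp"),
                       regression = TRUE)
  sel <- select_features(x, y, imp, chunk = chunk, folds = folds,
                         seed = derive_seed(seed, "rsel"), regression = TRUE,
                         max_size = max_size)
  xs <- x[, sel$optimal, drop = FALSE]
  fold_id <- stratified_folds(y, k = min(folds, length(y)),
                              seed = derive_seed(seed, "rcv"))
  pred <- rep(NA_real_, length(y))
  set.seed(derive_seed(seed, "rfit"))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- randomForest::randomForest(xs[tr, , drop = FALSE], y[tr],
                                      ntree = n_trees)
    pred[!tr] <- predict(fit, xs[!tr, , drop = FALSE])
  }
  ct <- stats::cor.test(y, pred)
  r <- unname(ct$estimate)
  r2 <- if (r2_method == "correlation") r^2 else {
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  structure(list(predicted = pred, observed = y, r = r, r2 = r2,
                 p = ct$p.value, selection = sel, subjects = which(ok)),
            class = "score_regression")
}

#' @export
print.score_regression <- function(x, ...) {
  cat(sprintf("score_regression: r = %.3f, R^2 = %.3f, p = %.3g (%d subjects, %d features)\n",
              x$r, x$r2, x$p, length(x$observed), x$selection$optimal_size))
  invisible(x)
}

#' Group summaries of z-scored true and predicted scores
#'
#' Z-scores the observed and the out-of-fold predicted scores over all
#' subjects and summarizes both by group, for trend plots of regression
#' quality across clinical stages.
#'
#' @param reg a [rf_score_regression()] result
#' @param groups group label per subject of the *original* feature matrix
#' @return data frame: group, mean/sd of z-scored true and predicted values
#' @export
score_regression_group_summary <- function(reg, groups) {
  g <- as.factor(groups[reg$subjects])
  z <- function(v) (v - mean(v)) / sd(v)
  zt <- z(reg$observed); zp <- z(reg$predicted)
  data.frame(group = levels(g),
             true_mean = as.numeric(tapply(zt, g, mean)),
             true_sd = as.numeric(tapply(zt, g, sd)),
             predicted_mean = as.numeric(tapply(zp, g, mean)),
             predicted_sd = as.numeric(tapply(zp, g, sd)),
             stringsAsFactors = FALSE)
}
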