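#' Random-forest permutation importance
#'
#' Out-of-bag permutation importance of each feature from a 200-tree random
#' forest: the drop in out-of-bag predictive accuracy (classification) or the
#' increase in out-of-bag MSE (regression) when the feature's values are
#' randomly permuted.
#'
#' @param x subjects x features matrix
#' @param y labels; a factor (or anything coercible with >= 2 classes) for
#'   classification, a numeric vector for regression
#' @param n_trees number of trees (default 200)
#' @param seed RNG seed
#' @param regression force regression mode (default: inferred from `y`)
#' @return named numeric vector of importances, one per feature
#' @export
rf_importance <- function(x, y, n_trees = 200, seed = 1, regression = NULL) {
  x <- as.matrix(x)
  if (is.null(regression)) regression <- is.numeric(y) && length(unique(y)) > 10
  if (!regression) {
    y <- factor(y)
    if (nlevels(y) < 2) stopf("need at least 2 classes for importance")
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees, importance = TRUE)
  imp_col <- if (regression) "%IncMSE" else "MeanDecreaseAccuracy"
  imp <- fit$importance[, imp_col]
  names(imp) <- colnames(x)
  imp
}

# Default cumulative-set evaluators: mean 10-fold CV 0/1 error for
# classification (RBF SVM with balanced class weights, default C and gamma),
# mean CV MSE for regression (random forest).
#' @noRd
cv_error_svm <- function(x, y, folds) {
  y <- factor(y)
  wts <- rev(as.numeric(table(y))) / length(y)
  names(wts) <- levels(y)
  errs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      class.weights = wts)
    mean(predict(fit, x[!tr, , drop = FALSE]) != y[!tr])
  }, 0)
  mean(errs)
}

#' @noRd
cv_error_rf <- function(x, y, folds, n_trees = 200) {
  errs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                      ntree = n_trees)
    mean((predict(fit, x[!tr, , drop = FALSE]) - y[!tr])^2)
  }, 0)
  mean(errs)
}

#' Cumulative feature selection from importance ranking
#'
#' Drops features with non-positive importance, sorts the survivors in
#' descending importance (ties broken by original order), and evaluates
#' cumulative feature sets grown five at a time (plus the final remainder) by
#' 10-fold cross-validated error of the downstream model. The optimal set is
#' the one with the lowest error (smallest set on ties).
#'
#' @param x subjects x features matrix
#' @param y labels (factor for classification, numeric for regression)
#' @param importance per-feature importance ([rf_importance()])
#' @param chunk step size of the cumulative curve (default 5)
#' @param folds number of CV folds
#' @param seed RNG seed (fold assignment and model fits)
#' @param regression evaluate with the regression criterion (CV MSE of a
#'   random forest) instead of classification error
#' @param max_size cap on the largest cumulative set evaluated (default
#'   unbounded, i.e. the curve runs to the last surviving feature); a finite
#'   cap bounds the cost when most features carry small positive importance
#' @return list of class `feature_selection` with `importance`, `ordered`
#'   (retained feature names in rank order), `curve` (data frame: size,
#'   cv_error), `optimal` (selected feature names) and `optimal_size`
#' @export
select_features <- function(x, y, importance, chunk = 5, folds = 10, seed = 1,
                            regression = NULL, max_size = Inf) {
  x <- as.matrix(x)
  if (is.null(regression)) regression <- is.numeric(y) && length(unique(y)) > 10
  keep <- which(importance > 0)
  if (length(keep) == 0) stopf("no features with positive importance survive")
  ord <- keep[order(-importance[keep], keep)]
  ordered_names <- colnames(x)[ord]
  limit <- min(length(ord), max_size)
  sizes <- unique(c(seq(min(chunk, limit), limit, by = chunk), limit))
  fold_id <- stratified_folds(if (regression) y else factor(y),
                              k = min(folds, nrow(x)), seed = seed)
  curve <- vapply(sizes, function(s) {
    xs <- x[, ord[seq_len(s)], drop = FALSE]
    set.seed(derive_seed(seed, paste0("selcurve", s)))
    if (regression) cv_error_rf(xs, y, fold_id) else cv_error_svm(xs, y, fold_id)
  }, 0)
  best <- sizes[which.min(curve)]  # which.min takes the first (smallest) on ties
  structure(list(importance = importance, ordered = ordered_names,
                 curve = data.frame(size = sizes, cv_error = curve),
                 optimal = ordered_names[seq_len(best)], optimal_size = best),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection: %d retained, optimal set %d (CV error %.3f)\n",
              length(x$ordered), x$optimal_size, min(x$curve$cv_error)))
  invisible(x)
}

#' Tune and evaluate a class-weighted RBF support vector machine
#'
#' Grid-searches C, gamma and the misclassification-penalty ratio (which
#' counteracts class imbalance) by stratified 10-fold cross-validated 0/1
#' error, then pools the out-of-fold decision values of the best
#' configuration into one ROC curve. AUC is the trapezoidal area; sensitivity
#' and specificity are read at the Youden-optimal operating point.
#'
#' @param x subjects x features matrix (typically the selected features)
#' @param y binary labels; the *first* level of `factor(y)` is treated as the
#'   control class, the second as the disease (positive) class
#' @param c_grid values of the SVM cost C
#' @param gamma_grid kernel width values; default scales 1/d by 0.1, 1, 10
#' @param weight_ratios disease-class penalty ratios to try, relative to the
#'   control class; default `c(1, n_ctrl/n_dis, 2 n_ctrl/n_dis)`
#' @param folds number of CV folds
#' @param seed RNG seed
#' @return list of class `staging_result`: `C`, `gamma`, `weight_ratio`,
#'   `cv_error`, `roc` (data frame fpr/tpr/threshold), `auc`, `sensitivity`,
#'   `specificity`, `decision_values`, `labels`
#' @export
train_svm <- function(x, y, c_grid = c(0.1, 1, 10, 100), gamma_grid = NULL,
                      weight_ratios = NULL, folds = 10, seed = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) stopf("train_svm needs exactly 2 classes")
  d <- ncol(x)
  if (is.null(gamma_grid)) gamma_grid <- (1 / d) * c(0.1, 1, 10)
  n_ctrl <- sum(y == levels(y)[1]); n_dis <- sum(y == levels(y)[2])
  if (is.null(weight_ratios)) {
    weight_ratios <- unique(c(1, n_ctrl / n_dis, 2 * n_ctrl / n_dis))
  }
  fold_id <- stratified_folds(y, k = min(folds, length(y)), seed = seed)
  grid <- expand.grid(C = c_grid, gamma = gamma_grid, w = weight_ratios)
  cv_one <- function(C, gamma, w, return_decisions = FALSE) {
    wts <- setNames(c(1, w), levels(y))
    dec <- rep(NA_real_, length(y))
    err <- 0
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = gamma, class.weights = wts,
                        decision.values = TRUE)
      pr <- predict(fit, x[!tr, , drop = FALSE], decision.values = TRUE)
      err <- err + sum(pr != y[!tr])
      dv <- drop(attr(pr, "decision.values"))
      # orient decision values so larger = more disease-like
      flip <- if (grepl(paste0("^", levels(y)[2], "/"),
                        colnames(attr(pr, "decision.values"))[1])) 1 else -1
      dec[!tr] <- flip * dv
    }
    list(error = err / length(y), decisions = if (return_decisions) dec)
  }
  set.seed(seed)
  errs <- vapply(seq_len(nrow(grid)), function(i) {
    cv_one(grid$C[i], grid$gamma[i], grid$w[i])$error
  }, 0)
  best <- which.min(errs)
  final <- cv_one(grid$C[best], grid$gamma[best], grid$w[best],
                  return_decisions = TRUE)
  roc_obj <- pROC::roc(response = y, predictor = final$decisions,
                       levels = levels(y), direction = "<", quiet = TRUE)
  best_pt <- pROC::coords(roc_obj, "best", best.method = "youden",
                          ret = c("sensitivity", "specificity"),
                          transpose = FALSE)
  if (nrow(best_pt) > 1) best_pt <- best_pt[1, , drop = FALSE]
  roc_df <- data.frame(fpr = 1 - roc_obj$specificities,
                       tpr = roc_obj$sensitivities,
                       threshold = roc_obj$thresholds)
  roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), ]
  structure(list(C = grid$C[best], gamma = grid$gamma[best],
                 weight_ratio = grid$w[best], cv_error = errs[best],
                 roc = roc_df, auc = as.numeric(pROC::auc(roc_obj)),
                 sensitivity = best_pt$sensitivity,
                 specificity = best_pt$specificity,
                 decision_values = final$decisions, labels = y),
            class = "staging_result")
}

#' @export
print.staging_result <- function(x, ...) {
  cat(sprintf("staging_result: AUC %.3f, sens %.2f, spec %.2f (C=%g, gamma=%g, w=%g, CV error %.3f)\n",
              x$auc, x$sensitivity, x$specificity, x$C, x$gamma,
              x$weight_ratio, x$cv_error))
  invisible(x)
}

#' Ordered cumulative patient contrasts for disease staging
#'
#' Builds the staged CN-vs-patients contrast list: ADD alone; lMCI+ADD;
#' MCI+lMCI+ADD; eMCI+MCI+lMCI+ADD; SMC+eMCI+MCI+lMCI+ADD. Contrasts whose
#' groups are absent from the cohort are skipped with a warning.
#'
#' @param groups character vector (or factor) of group labels present
#' @return named list of character vectors of patient-group labels, in order
#'   of increasing patient-set size
#' @export
cumulative_contrasts <- function(groups) {
  present <- unique(as.character(groups))
  stages <- c("ADD", "lMCI", "MCI", "eMCI", "SMC")
  out <- list()
  acc <- character(0)
  for (s in stages) {
    if (!s %in% present) {
      warnf("group %s absent; skipping its cumulative contrast", s)
      next
    }
    acc <- c(s, acc)
    out[[paste(acc, collapse = "+")]] <- acc
  }
  if (length(out) == 0) warnf("no patient groups present; contrast list is empty")
  out
}

#' Feature selection plus SVM staging for one CN-vs-patients contrast
#'
#' Runs the staging protocol on one binary contrast. With `nested = TRUE`
#' (default) the generalization estimate is honest: RF importance, cumulative
#' selection and SVM tuning are re-run inside each outer cross-validation
#' fold, and the pooled outer-fold decision values give the ROC. With
#' `nested = FALSE` selection and tuning are done once on all subjects and
#' the reported ROC comes from the final 10-fold CV of the tuned model (the
#' simpler classical protocol; optimistic for small samples).
#'
#' @param features subjects x features matrix (e.g. [fcm_features()])
#' @param is_patient logical vector (or 2-level factor) per subject
#' @param n_trees RF trees for importance
#' @param chunk selection step size
#' @param folds CV folds (outer folds when nested)
#' @param nested nest selection and tuning inside CV
#' @param seed RNG seed
#' @param max_size cap on the cumulative selection curve ([select_features()])
#' @return a `staging_result` (see [train_svm()]) with an added `selection`
#'   element holding the full-data [select_features()] result
#' @export
stage_classification <- function(features, is_patient, n_trees = 200,
                                 chunk = 5, folds = 10, nested = TRUE,
                                 seed = 1, max_size = Inf) {
  x <- as.matrix(features)
  y <- factor(if (is.logical(is_patient)) {
    ifelse(is_patient, "patient", "control")
  } else as.character(is_patient))
  if (nlevels(y) != 2) stopf("is_patient must define exactly 2 classes")
  y <- factor(y, levels = sort(levels(y)))  # control first alphabetically
  if ("control" %in% levels(y)) y <- stats::relevel(y, "control")

  # full-data selection, reported for interpretation in both protocols
  imp <- rf_importance(x, y, n_trees = n_trees,
                       seed = derive_seed(seed, "imp"))
  sel <- select_features(x, y, imp, chunk = chunk, folds = folds,
                         seed = derive_seed(seed, "sel"), max_size = max_size)
  if (!nested) {
    res <- train_svm(x[, sel$optimal, drop = FALSE], y, folds = folds,
                     seed = derive_seed(seed, "svm"))
    res$selection <- sel
    res$nested <- FALSE
    return(res)
  }
  fold_id <- stratified_folds(y, k = min(folds, length(y)),
                              seed = derive_seed(seed, "outer"))
  dec <- rep(NA_real_, length(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    imp_f <- rf_importance(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                           seed = derive_seed(seed, paste0("imp", f)))
    sel_f <- select_features(x[tr, , drop = FALSE], y[tr], imp_f,
                             chunk = chunk, folds = max(3, folds - 1),
                             seed = derive_seed(seed, paste0("sel", f)),
                             max_size = max_size)
    tuned <- train_svm(x[tr, sel_f$optimal, drop = FALSE], y[tr],
                       folds = max(3, folds - 1),
                       seed = derive_seed(seed, paste0("svm", f)))
    wts <- setNames(c(1, tuned$weight_ratio), levels(y))
    fit <- e1071::svm(x[tr, sel_f$optimal, drop = FALSE], y[tr],
                      kernel = "radial", cost = tuned$C, gamma = tuned$gamma,
                      class.weights = wts, decision.values = TRUE)
    pr <- predict(fit, x[!tr, sel_f$optimal, drop = FALSE],
                  decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    flip <- if (grepl(paste0("^", levels(y)[2], "/"),
                      colnames(attr(pr, "decision.values"))[1])) 1 else -1
    dec[!tr] <- flip * dv
  }
  roc_obj <- pROC::roc(response = y, predictor = dec, levels = levels(y),
                       direction = "<", quiet = TRUE)
  best_pt <- pROC::coords(roc_obj, "best", best.method = "youden",
                          ret = c("sensitivity", "specificity"),
                          transpose = FALSE)
  if (nrow(best_pt) > 1) best_pt <- best_pt[1, , drop = FALSE]
  cv_err <- mean((dec > 0) != (y == levels(y)[2]))
  roc_df <- data.frame(fpr = 1 - roc_obj$specificities,
                       tpr = roc_obj$sensitivities,
                       threshold = roc_obj$thresholds)
  roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), ]
  structure(list(C = NA_real_, gamma = NA_real_, weight_ratio = NA_real_,
                 cv_error = cv_err, roc = roc_df,
                 auc = as.numeric(pROC::auc(roc_obj)),
                 sensitivity = best_pt$sensitivity,
                 specificity = best_pt$specificity,
                 decision_values = dec, labels = y, selection = sel,
                 nested = TRUE),
            class = "staging_result")
}

#' Stage the whole cohort over the cumulative contrast ladder
#'
#' Applies [stage_classification()] to each contrast from
#' [cumulative_contrasts()], comparing CN against successively larger pooled
#' patient sets.
#'
#' @param features subjects x features matrix
#' @param groups group label per subject (must include `"CN"`)
#' @param ... passed to [stage_classification()]
#' @param seed RNG seed (one sub-seed per contrast)
#' @return named list of `staging_result`s, one per contrast
#' @export
staging_ladder <- function(features, groups, ..., seed = 1) {
  groups <- as.character(groups)
  contrasts <- cumulative_contrasts(groups)
  out <- list()
  for (nm in names(contrasts)) {
    sel <- groups == "CN" | groups %in% contrasts[[nm]]
    out[[nm]] <- stage_classification(
      features[sel, , drop = FALSE],
      is_patient = groups[sel] %in% contrasts[[nm]],
      seed = derive_seed(seed, nm), ...)
  }
  out
}
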