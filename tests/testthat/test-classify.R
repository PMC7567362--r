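test_that("permutation importance singles out the informative feature", {
  set.seed(16)
  n <- 80
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- factor(ifelse(x[, 4] > 0, "b", "a"))
  imp <- rf_importance(x, y, n_trees = 200, seed = 2)
  expect_equal(names(which.max(imp)), "f4")
  expect_gt(imp["f4"], max(imp[-4]) * 3)

  # pure noise: importances straddle zero
  y0 <- factor(rep(c("a", "b"), n / 2))
  imp0 <- rf_importance(x, y0, n_trees = 200, seed = 2)
  expect_lt(max(abs(imp0)), imp[["f4"]] / 3)

  # duplicated informative feature: both copies positive
  x2 <- cbind(x, f4copy = x[, 4] + rnorm(n, 0, 0.01))
  imp2 <- rf_importance(x2, y, n_trees = 300, seed = 2)
  expect_gt(imp2[["f4"]], 0)
  expect_gt(imp2[["f4copy"]], 0)

  expect_error(rf_importance(x, factor(rep("a", n))), "2 classes")
})

test_that("cumulative selection walks sizes in fives and drops useless features", {
  set.seed(17)
  n <- 60
  x <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- factor(ifelse(x[, 1] + x[, 2] > 0, "b", "a"))

  imp7 <- setNames(c(seq(1.2, 0.6, length.out = 7), rep(-0.1, 5)),
                   colnames(x))
  sel7 <- select_features(x, y, imp7, chunk = 5, folds = 5, seed = 1)
  expect_equal(sel7$curve$size, c(5, 7))
  expect_length(sel7$ordered, 7)

  imp12 <- setNames(seq(1.2, 0.1, length.out = 12), colnames(x))
  sel12 <- select_features(x, y, imp12, chunk = 5, folds = 5, seed = 1)
  expect_equal(sel12$curve$size, c(5, 10, 12))

  # descending order with stable tie-break on the original index
  imp_tie <- setNames(c(0.5, 0.9, 0.5, rep(-1, 9)), colnames(x))
  sel_tie <- select_features(x, y, imp_tie, chunk = 5, folds = 5, seed = 1)
  expect_equal(sel_tie$ordered, c("f2", "f1", "f3"))

  # the cap bounds the curve
  sel_cap <- select_features(x, y, imp12, chunk = 5, folds = 5, seed = 1,
                             max_size = 6)
  expect_equal(sel_cap$curve$size, c(5, 6))

  expect_error(select_features(x, y, setNames(rep(-1, 12), colnames(x))),
               "positive importance")
})

test_that("selection recovers planted features among many noise features", {
  set.seed(18)
  n <- 90
  p_noise <- 200
  planted <- paste0("sig", 1:10)
  y <- factor(rep(c("a", "b"), length.out = n))
  shift <- ifelse(y == "b", 1.0, 0)
  xs <- sapply(planted, function(i) rnorm(n) + shift)
  x <- cbind(xs, matrix(rnorm(n * p_noise), n, p_noise,
                        dimnames = list(NULL, paste0("n", 1:p_noise))))
  imp <- rf_importance(x, y, n_trees = 200, seed = 6)
  sel <- select_features(x, y, imp, chunk = 5, folds = 10, seed = 6,
                         max_size = 40)
  expect_gte(length(intersect(planted, sel$optimal)), 7)
})

test_that("the tuned SVM separates separable data and is at chance on permuted labels", {
  set.seed(19)
  n <- 200
  x <- rbind(matrix(rnorm(n / 2 * 4, 0), n / 2, 4),
             matrix(rnorm(n / 2 * 4, 4), n / 2, 4))
  colnames(x) <- paste0("f", 1:4)
  y <- factor(rep(c("control", "patient"), each = n / 2))
  res <- train_svm(x, y, folds = 5, seed = 2)
  expect_equal(res$auc, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  expect_equal(res$cv_error, 0)

  y_perm <- sample(y)
  res0 <- train_svm(x, y_perm, folds = 5, seed = 2)
  expect_gte(res0$auc, 0.35)
  expect_lte(res0$auc, 0.65)

  # ROC table covers the unit square monotonically
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_gte(min(res$roc$tpr), 0)
  expect_lte(max(res$roc$tpr), 1)
})

test_that("cumulative contrasts follow the staged ordering and skip absent groups", {
  full <- c("CN", "SMC", "eMCI", "MCI", "lMCI", "ADD")
  cc <- cumulative_contrasts(full)
  expect_length(cc, 5)
  expect_equal(cc[[1]], "ADD")
  expect_equal(cc[[2]], c("lMCI", "ADD"))
  expect_equal(cc[[5]], c("SMC", "eMCI", "MCI", "lMCI", "ADD"))

  expect_warning(cc4 <- cumulative_contrasts(setdiff(full, "SMC")), "SMC")
  expect_length(cc4, 4)

  suppressWarnings(expect_warning(cc0 <- cumulative_contrasts("CN"), "ADD"))
  expect_length(cc0, 0)
})

test_that("staging results are deterministic under a fixed seed", {
  fx <- toy_cohort()
  feats <- fcm_features(fx$stacks$WG, fx$stacks$WW)
  lab <- fx$stacks$table$group == "ADD"
  r1 <- stage_classification(feats, lab, n_trees = 80, folds = 5,
                             nested = FALSE, seed = 9)
  r2 <- stage_classification(feats, lab, n_trees = 80, folds = 5,
                             nested = FALSE, seed = 9)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$decision_values, r2$decision_values)
  expect_identical(r1$selection$optimal, r2$selection$optimal)
})

test_that("nested staging separates a strongly planted contrast", {
  fx <- toy_cohort()
  feats <- fcm_features(fx$stacks$WG, fx$stacks$WW)
  lab <- fx$stacks$table$group == "ADD"
  res <- stage_classification(feats, lab, n_trees = 100, folds = 5,
                              nested = TRUE, seed = 4)
  expect_gte(res$auc, 0.8)
  expect_true(res$nested)
  # decision values exist for every subject exactly once
  expect_false(anyNA(res$decision_values))
})
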