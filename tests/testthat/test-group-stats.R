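test_that("group means average element-wise and skip missing entries", {
  stack <- rbind(s1 = c(0.2, 0.5), s2 = c(0.4, NA), s3 = c(0.1, 0.3))
  labels <- c("CN", "CN", "ADD")
  m <- mean_fcm(stack, labels)
  expect_equal(m["CN", ], c(0.3, 0.5))
  expect_equal(m["ADD", ], c(0.1, 0.3))
  expect_equal(attr(m, "n_missing")["CN", ], c(0, 1))

  # identical subjects: mean equals any subject
  stack2 <- rbind(a = c(1, 2), b = c(1, 2))
  expect_equal(unname(mean_fcm(stack2, c("g", "g"))["g", ]), c(1, 2))

  expect_error(mean_fcm(stack, factor(labels, levels = c("CN", "ADD", "X"))),
               "empty group")
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration on a 4-vs-4 toy", {
  x <- c(0.1, 0.3, 0.2, 0.4, 0.6, 0.5, 0.8, 0.7)
  labels <- rep(c("CN", "ADD"), each = 4)
  stack <- matrix(x, 8, 1)

  # independent oracle: enumerate all choose(8,4) = 70 group-1 assignments
  obs <- mean(x[1:4]) - mean(x[5:8])
  splits <- combn(8, 4)
  stats <- apply(splits, 2, function(idx) mean(x[idx]) - mean(x[-idx]))
  p_exact <- mean(abs(stats) >= abs(obs) - 1e-12)

  pt <- permutation_test(stack, labels, c("CN", "ADD"), n_perm = 5000, seed = 4)
  expect_equal(pt$statistic[1], obs)
  expect_lt(abs(pt$p[1] - p_exact), 0.02)
})

test_that("permutation p is exactly 1 when the groups are identical element-wise", {
  stack <- rbind(a = c(1, 2), b = c(3, 1), c = c(1, 2), d = c(3, 1))
  pt <- permutation_test(stack, c("CN", "CN", "ADD", "ADD"), c("CN", "ADD"),
                         n_perm = 300, seed = 1)
  expect_equal(pt$p, rep(1, 2))
  expect_warning(permutation_test(stack, c("CN", "CN", "ADD", "ADD"),
                                  c("CN", "ADD"), n_perm = 50, seed = 1),
                 "coarse")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(42)
  n <- 30
  stack <- matrix(rnorm(n * 400), n, 400)
  labels <- rep(c("CN", "ADD"), each = n / 2)
  pt <- permutation_test(stack, labels, c("CN", "ADD"), n_perm = 400, seed = 9)
  for (alpha in c(0.05, 0.1)) {
    rate <- mean(pt$p <= alpha)
    se <- sqrt(alpha * (1 - alpha) / 400)
    expect_lt(rate, alpha + 3 * se)
    expect_gt(rate, alpha - 3 * se)
  }
})

test_that("BH adjustment reproduces the manual step-up and its invariants", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))

  set.seed(11)
  p <- matrix(runif(60), 6, 10)
  adj <- fdr_adjust(p)
  expect_equal(dim(adj), dim(p))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in sorted order
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("effect sizes are pooled-SD Cohen's d with the contrast's sign", {
  stack <- matrix(c(1, 2, 3, 3, 4, 5), 6, 1)
  labels <- rep(c("CN", "ADD"), each = 3)
  d <- effect_size(stack, labels, c("CN", "ADD"))
  expect_equal(unname(d), -2)   # pooled SD 1, mean difference -2

  stack2 <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1)
  expect_equal(unname(effect_size(stack2, labels, c("CN", "ADD"))), 0)

  # zero pooled SD -> NA
  stack3 <- matrix(rep(2, 6), 6, 1)
  expect_true(is.na(effect_size(stack3, labels, c("CN", "ADD"))))
})

test_that("comparison bundle thresholds exactly at the FDR level", {
  fx <- toy_cohort()
  wg <- fx$stacks$WG
  cmp <- group_comparison(wg, fx$stacks$table$group, c("CN", "ADD"),
                          n_perm = 800, seed = 3)
  expect_true(all(cmp$p_fdr >= cmp$p_perm))
  nz <- cmp$thresholded_difference != 0
  expect_true(all(cmp$p_fdr[nz] <= cmp$alpha))
  expect_true(all(cmp$thresholded_difference[cmp$p_fdr > cmp$alpha] == 0))
  expect_equal(cmp$difference,
               cmp$mean_by_group["CN", ] - cmp$mean_by_group["ADD", ])
})

test_that("tract-wise FC averages rows as specified for WG and WW", {
  # constant matrix: every tract's value is the constant
  cst <- matrix(0.4, 3, 5, dimnames = list(paste0("W", 1:3), paste0("G", 1:5)))
  expect_equal(unname(tractwise_fc(cst, kind = "WG")), rep(0.4, 3))

  # single-row signal
  one <- matrix(0, 3, 5, dimnames = dimnames(cst))
  one[2, ] <- 0.5
  expect_equal(unname(tractwise_fc(one, kind = "WG")), c(0, 0.5, 0))

  # hand-written 3 x 4 toy
  m <- matrix(c(0.1, 0.2, 0.3, 0.4,
                0.0, 0.5, 0.1, 0.2,
                0.3, 0.3, 0.3, 0.3), 3, 4, byrow = TRUE)
  rownames(m) <- paste0("W", 1:3)
  expect_equal(unname(tractwise_fc(m, kind = "WG")),
               c(0.25, 0.2, 0.3))

  # WW excludes the unit diagonal by default, includes it on request
  ww <- matrix(c(1, 0.2, 0.4,
                 0.2, 1, 0.6,
                 0.4, 0.6, 1), 3, 3)
  dimnames(ww) <- list(paste0("W", 1:3), paste0("W", 1:3))
  expect_equal(unname(tractwise_fc(ww, kind = "WW")), c(0.3, 0.4, 0.5))
  expect_equal(unname(tractwise_fc(ww, kind = "WW", include_diagonal = TRUE)),
               unname(rowMeans(ww)))
})

test_that("tract t-tests match the closed-form pooled-variance statistic", {
  a <- c(1, 2, 3, 4); b <- c(3, 5, 7, 9)
  tv <- matrix(c(a, b), 8, 1, dimnames = list(NULL, "W01"))
  labels <- rep(c("CN", "ADD"), each = 4)
  out <- tract_ttest(tv, labels, c("CN", "ADD"))
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$t, t_hand, tolerance = 1e-6)
  expect_equal(out$p, 2 * pt(abs(t_hand), df = 6, lower.tail = FALSE),
               tolerance = 1e-6)

  # identical groups: t = 0, p = 1, no stars
  tv2 <- matrix(rep(c(1, 2, 3, 4), 2), 8, 1, dimnames = list(NULL, "W01"))
  out2 <- tract_ttest(tv2, labels, c("CN", "ADD"))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  expect_equal(out2$stars, "")
})

test_that("overall-FC normalization hits its anchors exactly and preserves order", {
  set.seed(12)
  overall <- c(rnorm(20, 0.5, 0.02), rnorm(20, 0.4, 0.02),
               rnorm(20, 0.3, 0.02))
  labels <- factor(rep(c("CN", "MCI", "ADD"), each = 20),
                   levels = c("CN", "MCI", "ADD"))
  tr <- overall_fc_trend(overall, labels)
  expect_equal(tr$mean_normalized[tr$group == "CN"], 1)
  expect_equal(tr$mean_normalized[tr$group == "ADD"], 0)
  expect_true(all(diff(tr$mean_normalized) < 0))   # affine map preserves order
  # midpoint maps to 0.5
  m <- tapply(overall, labels, mean)
  mid <- (m[["CN"]] + m[["ADD"]]) / 2
  expect_equal((mid - m[["ADD"]]) / (m[["CN"]] - m[["ADD"]]), 0.5)
  # SDs are scaled by the same factor
  expect_equal(tr$sd_normalized, tr$sd / (m[["CN"]] - m[["ADD"]]))

  expect_error(overall_fc_trend(rep(0.5, 10),
                                factor(rep(c("CN", "ADD"), 5))), "equal")
})
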