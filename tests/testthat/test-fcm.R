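test_that("censored correlation equals Pearson on the truncated series", {
  set.seed(7)
  vals <- matrix(rnorm(60 * 5), 60, 5)
  ser <- roi_timeseries(vals, roi_order = paste0("R", 1:5), tr_seconds = 3)
  fd <- runif(60, 0, 1)
  r <- censored_correlation(ser, fd, fd_threshold = 0.5)
  keep <- fd <= 0.5
  expect_lt(max(abs(r - cor(vals[keep, ]))), 1e-12)
  expect_equal(attr(r, "n_retained"), sum(keep))

  # censoring frames that were never spiked leaves a clean pair unchanged
  r_all <- censored_correlation(ser, rep(0, 60))
  expect_lt(max(abs(r_all - cor(vals))), 1e-12)

  # identical columns correlate at exactly 1
  ser2 <- roi_timeseries(cbind(a = vals[, 1], b = vals[, 1]))
  expect_equal(censored_correlation(ser2, rep(0, 60))["a", "b"], 1)
})

test_that("hand-censored 5-frame pair matches arithmetic Pearson", {
  ser <- hand_series()
  fd <- c(0, 0, 0.9, 0, 0)           # censor frame 3
  r <- censored_correlation(ser, fd, min_frames = 3)
  a <- c(1, 3, 5, 4); b <- c(2, 1, 3, 6)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unname(r["a", "b"]), r_hand, tolerance = 1e-12)
})

test_that("FCM assembly selects and orders blocks by the registry", {
  reg <- make_toy_registry(3, 4)
  set.seed(8)
  vals <- matrix(rnorm(50 * 7), 50, 7)
  colnames(vals) <- reg$abbreviation
  r <- censored_correlation(roi_timeseries(vals), rep(0, 50))

  wg <- assemble_fcm(r, reg, "WG")
  ww <- assemble_fcm(r, reg, "WW")
  gg <- assemble_fcm(r, reg, "GG")
  expect_equal(dim(wg$values), c(3L, 4L))
  expect_equal(dim(ww$values), c(3L, 3L))
  expect_equal(dim(gg$values), c(4L, 4L))
  expect_equal(ww$values, t(ww$values))
  expect_equal(unname(diag(ww$values)), rep(1, 3))
  expect_true(all(abs(wg$values) <= 1))

  # permuted ROI input order gives the identical matrix after ordering
  perm <- sample(7)
  r_perm <- censored_correlation(
    roi_timeseries(vals[, perm], roi_order = colnames(vals)[perm]), rep(0, 50))
  wg2 <- assemble_fcm(r_perm, reg, "WG")
  expect_equal(wg2$values, wg$values, tolerance = 1e-14)

  expect_error(assemble_fcm(r[1:5, 1:5], reg, "WG"), "lacks")
})

test_that("packaged-registry FCMs have the canonical dimensionalities", {
  reg <- load_roi_registry()
  set.seed(9)
  vals <- matrix(rnorm(40 * 130), 40, 130)
  colnames(vals) <- reg$abbreviation
  r <- censored_correlation(roi_timeseries(vals), rep(0, 40))
  wg <- assemble_fcm(r, reg, "WG")
  ww <- assemble_fcm(r, reg, "WW")
  expect_equal(dim(wg$values), c(48L, 82L))
  expect_length(fcm_vector(wg), 3936)
  expect_length(fcm_vector(ww), 48 * 47 / 2)
  feats <- fcm_features(stack_fcms(list(s1 = wg)), stack_fcms(list(s1 = ww)))
  expect_equal(ncol(feats), 5064)
})

test_that("stack and unstack are mutually inverse", {
  fx <- toy_cohort()
  wg <- fx$stacks$WG
  ww <- fx$stacks$WW
  v <- wg[3, ]
  m <- unstack_fcm(v, wg)
  expect_equal(as.vector(m), unname(v))
  mw <- unstack_fcm(ww[1, ], ww)
  expect_equal(mw, t(mw))
  expect_true(all(is.na(diag(mw))))
  expect_equal(mw[upper.tri(mw)], unname(ww[1, ]))
})

test_that("covariate partialling matches closed-form least squares", {
  # 6-subject toy, solved through the normal equations
  age <- c(61, 72, 68, 80, 75, 66)
  sex <- c(0, 1, 1, 0, 1, 0)
  edu <- c(12, 16, 18, 14, 20, 15)
  y <- c(0.30, 0.12, 0.25, 0.08, 0.15, 0.28)
  stack <- matrix(y, 6, 1, dimnames = list(paste0("S", 1:6), "W01|G01"))
  attr(stack, "kind") <- "WG"
  covs <- data.frame(age = age, sex = sex, education = edu)

  X <- cbind(1, age, sex, edu)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid_hand <- y - X %*% beta

  out <- partial_out_covariates(stack, covs)
  expect_equal(unname(out[, 1]), as.numeric(resid_hand + mean(y)),
               tolerance = 1e-10)

  # plain residuals when centering is off
  out0 <- partial_out_covariates(stack, covs, center_back = FALSE)
  expect_equal(unname(out0[, 1]), as.numeric(resid_hand), tolerance = 1e-10)
})

test_that("partialling is a projection: orthogonal covariates change nothing", {
  set.seed(10)
  n <- 24
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                     education = rnorm(n),
                     site = sample(c("a", "b"), n, replace = TRUE))
  d <- wmfc:::covariate_design(covs)
  dc <- scale(d, scale = FALSE)
  # build elements orthogonal to the centered design (plus arbitrary mean)
  q <- qr.Q(qr(cbind(1, dc)), complete = TRUE)[, (ncol(dc) + 2):n]
  stack <- q %*% matrix(rnorm(ncol(q) * 5), ncol(q), 5) + 0.3
  rownames(stack) <- paste0("S", seq_len(n))
  out <- partial_out_covariates(stack, covs)
  expect_lt(max(abs(out - stack)), 1e-10)

  # an element exactly linear in age collapses to its mean
  stack2 <- cbind(e1 = 0.1 + 0.01 * covs$age)
  out2 <- partial_out_covariates(stack2, covs)
  expect_lt(var(out2[, 1]), 1e-20)
  expect_equal(mean(out2[, 1]), mean(stack2[, 1]), tolerance = 1e-12)
})

test_that("partialling handles missing entries pairwise and keeps attributes", {
  fx <- toy_cohort()
  wg <- fx$stacks$WG
  wg[2, 5] <- NA
  covs <- fx$stacks$table[c("age", "sex", "education", "site")]
  out <- partial_out_covariates(wg, covs)
  expect_equal(attr(out, "kind"), "WG")
  expect_true(is.na(out[2, 5]))
  expect_false(anyNA(out[-2, ]))
})

test_that("the opt-in Fisher z-transform maps stacks through atanh", {
  expect_equal(fisher_z(c(-0.5, 0, 0.5)), atanh(c(-0.5, 0, 0.5)))
  expect_true(is.finite(fisher_z(1)))
  fx <- toy_cohort()
  stz <- cohort_fcm_stacks(fx$cohort, fisher_z = TRUE)
  expect_equal(unname(stz$WG[1, 1]), atanh(unname(fx$stacks$WG[1, 1])),
               tolerance = 1e-12)
})

test_that("subjects below the retained-frame floor are excluded with a reason", {
  fx <- toy_cohort()
  coh <- fx$cohort
  # starve one subject of frames
  id <- names(coh$subjects)[1]
  inj <- inject_motion(coh$subjects[[id]]$series, coh$subjects[[id]]$motion,
                       spike_frames = 2:coh$config$n_frames)
  coh$subjects[[id]] <- list(series = inj$series, motion = inj$motion)
  st <- cohort_fcm_stacks(coh)
  expect_true(id %in% names(st$excluded))
  expect_match(st$excluded[[id]], "too few retained frames")
  expect_equal(nrow(st$WG), length(coh$subjects) - 1)
  expect_false(id %in% st$table$subject)
})
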