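test_that("framewise displacement follows the backward-difference convention", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))

  m[5:10, 1] <- 0.6                       # sustained x-translation step
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 0.6)
  expect_equal(fd[-5], rep(0, 9))

  m2 <- matrix(0, 10, 6)
  m2[3:10, 5] <- 0.01                     # 0.01 rad rotation step -> 50 * 0.01
  expect_equal(framewise_displacement(m2)[3], 0.5)

  expect_error(framewise_displacement(matrix(0, 10, 5)), "6 columns")
})

test_that("the 24-parameter expansion lags and squares correctly", {
  m <- matrix(seq_len(18), 3, 6)
  e <- motion24(m)
  expect_equal(dim(e), c(3L, 24L))
  expect_equal(e[, 7:12], rbind(0, m[-3, ]), ignore_attr = TRUE)  # lag-1, zero-padded
  expect_equal(e[, 13:18], m^2, ignore_attr = TRUE)
  expect_equal(e[1, 19:24], rep(0, 6), ignore_attr = TRUE)
})

test_that("nuisance projection removes spanned signals and is idempotent", {
  set.seed(1)
  n <- 80
  design <- matrix(rnorm(n * 4), n, 4)
  # a signal that is exactly a linear combination of the regressors
  y <- cbind(design %*% c(2, -1, 0.5, 3) + 7)
  res <- wmfc:::project_out(y, design)
  expect_lt(max(abs(res)), 1e-10)

  y2 <- matrix(rnorm(n * 3), n, 3)
  r1 <- wmfc:::project_out(y2, design)
  r2 <- wmfc:::project_out(r1, design)
  expect_lt(sqrt(mean((r2 - r1)^2)), 1e-8)

  # collinear design columns are dropped, not fatal
  bad <- cbind(design, design[, 1] * 2)
  r3 <- wmfc:::project_out(y2, bad)
  expect_equal(r3, r1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_length(attr(r3, "dropped"), 1)
})

test_that("band-pass removes slow drift and cleaning normalizes to unit variance", {
  tr <- 2                                  # Nyquist 0.25 Hz
  n <- 600
  t_sec <- (seq_len(n) - 1) * tr
  drift <- sin(2 * pi * 0.005 * t_sec)     # well below the 0.01 Hz edge
  filtered <- bandpass_filter(cbind(drift), tr, c(0.01, 0.1))
  expect_lt(sqrt(mean(filtered^2)) / sqrt(mean(drift^2)), 0.05)

  # in-band signal passes essentially intact
  inband <- sin(2 * pi * 0.05 * t_sec)
  kept <- bandpass_filter(cbind(inband), tr, c(0.01, 0.1))
  expect_gt(sqrt(mean(kept^2)) / sqrt(mean(inband^2)), 0.9)

  set.seed(2)
  x <- matrix(rnorm(n * 5), n, 5)
  motion <- matrix(rnorm(n * 6, sd = 0.01), n, 6)
  cleaned <- clean_timeseries(x, motion = motion, csf = rnorm(n),
                              tr_seconds = tr)
  expect_lt(max(abs(colMeans(cleaned))), 1e-6)
  expect_lt(max(abs(apply(cleaned, 2, var) - 1)), 1e-6)

  expect_error(bandpass_filter(x, tr_seconds = 6, band = c(0.01, 0.1)),
               "Nyquist")
})

test_that("masks honour labels, the probability threshold, and monotonicity", {
  reg <- make_toy_registry(1, 2)
  labels <- array(0L, c(4, 4, 4))
  labels[1, 1, 1] <- 1; labels[2, 1, 1] <- 1; labels[3, 1, 1] <- 1
  labels[1, 2, 1] <- 2
  labels[1, 3, 1] <- 3
  prob <- array(1, c(4, 4, 4))
  prob[3, 1, 1] <- 0.5                     # below threshold

  masks <- build_masks(labels, prob, reg, threshold = 0.8)
  expect_length(masks[["W01"]], 2)         # 3 labelled, 1 under threshold
  expect_length(masks[["G01"]], 1)

  # threshold 0 with all-positive probability reproduces raw label extents
  masks0 <- build_masks(labels, array(1, c(4, 4, 4)), reg, threshold = 0)
  expect_length(masks0[["W01"]], 3)

  # raising the threshold never adds voxels
  set.seed(3)
  prob_r <- array(runif(64), c(4, 4, 4))
  labels_r <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
  prev <- NULL
  for (thr in c(0.1, 0.4, 0.7, 0.9)) {
    mk <- suppressWarnings(build_masks(labels_r, prob_r, reg, threshold = thr))
    if (!is.null(prev)) {
      for (ab in names(mk)) expect_true(all(mk[[ab]] %in% prev[[ab]]))
    }
    prev <- mk
  }

  expect_error(build_masks(labels, array(1, c(4, 4, 2)), reg), "grid")
  expect_warning(build_masks(array(0L, c(4, 4, 4)), prob, reg), "empty mask")
})

test_that("ROI means average voxels and keep empty-ROI slots as NA", {
  reg <- make_toy_registry(2, 1)
  # 5 frames x 4 voxels with hand-written signals
  vox <- cbind(c(1, 2, 3, 4, 5), c(3, 2, 5, 4, 1), c(2, 2, 4, 4, 3),
               c(0, 1, 0, 1, 0))
  masks <- list(W01 = c(1L), W02 = c(2L, 3L), G01 = integer(0))
  ts <- extract_roi_means(vox, masks, reg, renormalize = FALSE)
  expect_equal(unname(ts$values[, "W01"]), vox[, 1])
  expect_equal(unname(ts$values[, "W02"]), rowMeans(vox[, 2:3]))
  expect_true(all(is.na(ts$values[, "G01"])))

  # two identical voxels: mean equals either, idempotent under averaging
  masks2 <- list(W01 = c(4L, 4L), W02 = c(1L), G01 = c(2L))
  ts2 <- extract_roi_means(vox, masks2, reg, renormalize = FALSE)
  expect_equal(unname(ts2$values[, "W01"]), vox[, 4])

  # renormalized columns are unit-variance z-scores
  ts3 <- extract_roi_means(vox, masks, reg, renormalize = TRUE)
  expect_equal(unname(colMeans(ts3$values[, 1:2])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ts3$values[, 1:2], 2, var)), c(1, 1),
               tolerance = 1e-12)
})

test_that("roi time series survive a TSV round trip with their retention mask", {
  ts <- roi_timeseries(matrix(rnorm(40), 10, 4),
                       roi_order = c("W01", "W02", "G01", "G02"),
                       retained = c(rep(TRUE, 8), FALSE, TRUE))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_roi_timeseries(ts, tmp)
  back <- read_roi_timeseries(tmp, tr_seconds = ts$tr_seconds)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  expect_equal(back$retained, ts$retained)
})
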