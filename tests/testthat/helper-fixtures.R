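# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# 2-group toy cohort on a 4 WM + 8 GM registry with a planted CN-vs-ADD
# deficit; reused by fcm / group-stats / behavior tests.
toy_cohort <- function() {
  if (is.null(.fixture_env$toy)) {
    reg <- make_toy_registry(4, 8)
    cfg <- simulation_config(
      n_per_group = c(CN = 15, ADD = 12), n_frames = 150,
      base_correlation = 0.35,
      deficit_edges = data.frame(roi1 = c("W01", "W01", "W01", "W02"),
                                 roi2 = c("G01", "G03", "G05", "G02")),
      deficit_delta_by_group = c(CN = 0, ADD = 0.25),
      motion_spike_rate = 0.03, seed = 101)
    coh <- simulate_cohort(cfg, reg)
    stacks <- cohort_fcm_stacks(coh)
    .fixture_env$toy <- list(registry = reg, config = cfg, cohort = coh,
                             stacks = stacks)
  }
  .fixture_env$toy
}

# deterministic hand-sized series matrix
hand_series <- function() {
  m <- cbind(a = c(1, 3, 2, 5, 4), b = c(2, 1, 4, 3, 6))
  roi_timeseries(m, tr_seconds = 1)
}
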