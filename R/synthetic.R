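#' Configuration for the synthetic multi-group BOLD cohort
#'
#' Defines the study conditions the simulator emulates: a multi-group elderly
#' cohort whose ROI time series are stationary multivariate Gaussian signals
#' with an equicorrelated base structure, group-specific planted connectivity
#' deficits on selected white-matter edges, motion traces with censorable
#' spikes, and neuropsychological scores generated as noisy affine functions
#' of each group's true overall FC.
#'
#' Default group sizes follow a 6-stage clinical cohort (CN, SMC, eMCI, MCI,
#' lMCI, ADD) with pronounced deficits only at the two late stages, which is
#' the qualitative structure the downstream statistics are designed to
#' detect.
#'
#' @param n_per_group named integer vector, subjects per clinical group (the
#'   names define the group labels and their ordering by disease severity)
#' @param n_frames frames (time points) per subject
#' @param tr_seconds repetition time in seconds
#' @param base_correlation baseline inter-ROI correlation in [0,1)
#' @param deficit_edges data frame with columns `roi1` (a WM abbreviation)
#'   and `roi2` (any other ROI abbreviation); `NULL` selects the default
#'   planted set for the given registry (see [default_deficit_edges()])
#' @param deficit_delta_by_group named numeric vector, correlation reduction
#'   applied on deficit edges per group (0 for unaffected groups); values
#'   must not exceed `base_correlation`
#' @param deficit_mode `"attenuate"` (default) scales the signal share of
#'   the white-matter tracts named in the edge set so their correlation with
#'   unaffected partners drops by exactly the group delta — positive
#'   semi-definite by construction and tract-concentrated, like the deficits
#'   the downstream statistics target. `"subtract"` lowers exactly the
#'   listed edges, which only admits a valid correlation matrix for sparse
#'   edge sets (eigenvalue-clip repair with refusal beyond 0.05 entry
#'   distortion)
#' @param motion_spike_rate per-frame probability of a motion spike whose FD
#'   exceeds the usual 0.5 mm censoring threshold
#' @param spike_translation_mm size of the translation step at a spike frame
#' @param score_noise_scale multiplier on the per-score residual noise SD
#' @param ar_coefficient optional lag-1 autoregressive coefficient for
#'   temporal autocorrelation (default 0, white innovations)
#' @param seed RNG seed; the whole cohort is reproducible from it
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(n_per_group = c(CN = 60, SMC = 18, eMCI = 33,
                                              MCI = 15, lMCI = 18, ADD = 35),
                              n_frames = 200, tr_seconds = 3,
                              base_correlation = 0.35,
                              deficit_edges = NULL,
                              deficit_delta_by_group = c(CN = 0, SMC = 0.03,
                                                         eMCI = 0.04, MCI = 0.06,
                                                         lMCI = 0.15, ADD = 0.30),
                              deficit_mode = c("attenuate", "subtract"),
                              motion_spike_rate = 0.03,
                              spike_translation_mm = 0.6,
                              score_noise_scale = 1,
                              ar_coefficient = 0,
                              seed = 1L) {
  deficit_mode <- match.arg(deficit_mode)
  n_per_group <- unlist(n_per_group)            # tolerate YAML-style lists
  deficit_delta_by_group <- unlist(deficit_delta_by_group)
  stopifnot(all(n_per_group > 0), n_frames > 0, tr_seconds > 0)
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stopf("n_per_group must be a named vector of group sizes")
  }
  if (base_correlation < 0 || base_correlation >= 1) {
    stopf("base_correlation must be in [0, 1)")
  }
  deficit_delta_by_group <- deficit_delta_by_group[names(n_per_group)]
  deficit_delta_by_group[is.na(deficit_delta_by_group)] <- 0
  names(deficit_delta_by_group) <- names(n_per_group)
  if (any(deficit_delta_by_group < 0) ||
      any(deficit_delta_by_group > base_correlation)) {
    stopf("deficit deltas must lie in [0, base_correlation]")
  }
  structure(list(n_per_group = n_per_group, n_frames = n_frames,
                 tr_seconds = tr_seconds, base_correlation = base_correlation,
                 deficit_edges = deficit_edges, deficit_mode = deficit_mode,
                 deficit_delta_by_group = deficit_delta_by_group,
                 motion_spike_rate = motion_spike_rate,
                 spike_translation_mm = spike_translation_mm,
                 score_noise_scale = score_noise_scale,
                 ar_coefficient = ar_coefficient,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default planted-deficit edge set for a registry
#'
#' Concentrates the planted deficit on a few white-matter tracts (so that
#' tract-wise statistics have a well-defined ground truth): each selected
#' tract loses correlation with a spread of gray-matter partner regions, and
#' the selected tracts also lose correlation among themselves (WM-WM edges).
#' For the packaged registry the tracts are commissural and association
#' fibres typically implicated in late-stage cognitive decline (splenium of
#' corpus callosum, bilateral superior longitudinal fasciculus, bilateral
#' cingulum).
#'
#' @param registry an ROI registry
#' @param n_tracts number of affected WM tracts
#' @param n_partners number of GM partner regions per affected tract
#' @return data frame with columns `roi1`, `roi2`
#' @export
default_deficit_edges <- function(registry, n_tracts = 5, n_partners = 20) {
  wm <- registry$abbreviation[registry$tissue == "WM"]
  gm <- registry$abbreviation[registry$tissue == "GM"]
  preferred <- c("SCC", "SLFl", "SLFr", "CGCl", "CGCr", "SSl", "SSr", "FXCl")
  tracts <- intersect(preferred, wm)
  if (length(tracts) < n_tracts) tracts <- unique(c(tracts, wm))
  tracts <- tracts[seq_len(min(n_tracts, length(tracts)))]
  n_partners <- min(n_partners, length(gm))
  partners <- gm[unique(round(seq(1, length(gm), length.out = n_partners)))]
  wg <- expand.grid(roi1 = tracts, roi2 = partners, stringsAsFactors = FALSE)
  ww <- if (length(tracts) >= 2) {
    cmb <- utils::combn(tracts, 2)
    data.frame(roi1 = cmb[1, ], roi2 = cmb[2, ], stringsAsFactors = FALSE)
  } else NULL
  rbind(wg, ww)
}

# Target correlation matrix for one group: equicorrelated base plus a
# planted deficit.
#
# "attenuate" (default): the white-matter tracts named in the edge set have
# their signal share scaled so that each tract's correlation with an
# unaffected partner drops from `base` to `base - delta` (lambda =
# (base-delta)/base, rows/columns scaled by lambda, diagonal restored).
# This is positive semi-definite by construction and lowers *every* edge of
# an affected tract, reproducing the tract-wise deficit stripes the
# statistics are designed to find; pairs of affected tracts drop further,
# to lambda^2 * base.
#
# "subtract": delta is subtracted on exactly the listed edges. Only sparse,
# low-coherence edge sets admit a valid correlation matrix this way; if the
# result is indefinite, negative eigenvalues are clipped to 1e-8 and the
# matrix re-normalized to unit diagonal, refusing when the repair moves any
# entry by more than 0.05.
#' @noRd
build_target_matrix <- function(registry, base, edges, delta, group = "?",
                                mode = c("attenuate", "subtract")) {
  mode <- match.arg(mode)
  p <- nrow(registry)
  R <- matrix(base, p, p)
  diag(R) <- 1
  dimnames(R) <- list(registry$abbreviation, registry$abbreviation)
  if (delta <= 0 || is.null(edges) || nrow(edges) == 0) return(R)
  i <- match(edges$roi1, registry$abbreviation)
  j <- match(edges$roi2, registry$abbreviation)
  if (anyNA(i) || anyNA(j)) stopf("deficit edge names not found in registry")

  if (mode == "attenuate") {
    if (base <= 0) stopf("attenuation deficits need base_correlation > 0")
    wm <- registry$abbreviation[registry$tissue == "WM"]
    affected <- intersect(unique(c(edges$roi1, edges$roi2)), wm)
    lam <- rep(1, p)
    lam[match(affected, registry$abbreviation)] <- (base - delta) / base
    R <- R * tcrossprod(lam)
    diag(R) <- 1
    return(R)
  }

  R[cbind(i, j)] <- base - delta
  R[cbind(j, i)] <- base - delta
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 1e-8)
    R2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    if (max(abs(R2 - R)) > 0.05) {
      stopf("target correlation matrix for group %s is not positive semi-definite and repair would move an entry by %.3f (> 0.05)",
            group, max(abs(R2 - R)))
    }
    dimnames(R2) <- dimnames(R)
    R <- R2
  }
  R
}

# Score generation model: each score interpolates between its ADD-group and
# CN-group means along the normalized true overall-FC, with residual noise on
# its natural scale and clipping to a plausible range. Scores with equal CN
# and ADD anchors (Hachinski, GDS) are deliberately FC-independent, matching
# the null associations expected for them.
#' @noRd
default_score_model <- function() {
  data.frame(
    score = c("MMSE", "CDR_global", "CDR_SOB", "GDS", "FAQ",
              "WMS_LMII", "ADAS_Cog", "Hachinski"),
    cn_mean = c(29.1, 0.0, 0.3, 1.3, 1.0, 15.4, 9.6, 0.6),
    add_mean = c(22.4, 0.8, 4.7, 1.3, 14.6, 4.5, 22.7, 0.6),
    noise_sd = c(1.7, 0.2, 1.0, 1.5, 3.7, 3.3, 4.4, 0.8),
    lo = c(0, 0, 0, 0, 0, 0, 0, 0),
    hi = c(30, 3, 18, 15, 30, 25, 70, 12),
    stringsAsFactors = FALSE
  )
}

#' Inject motion spikes into a subject's series and motion table
#'
#' Each spike frame receives a sustained translation step on the first motion
#' axis (so the backward-difference FD at exactly that frame exceeds the
#' censoring threshold) and an additive signal artifact across all ROIs.
#'
#' @param series a [roi_timeseries()] (or plain frames x ROIs matrix)
#' @param motion frames x 6 motion table
#' @param spike_frames integer frame indices (>= 2) to spike
#' @param translation_step translation jump in mm at each spike frame
#' @param artifact_scale SD of the additive artifact placed on spiked frames
#' @return list with elements `series` and `motion`
#' @export
inject_motion <- function(series, motion, spike_frames,
                          translation_step = 0.6, artifact_scale = 2) {
  is_rts <- inherits(series, "roi_timeseries")
  vals <- if (is_rts) series$values else as.matrix(series)
  motion <- as.matrix(motion)
  n <- nrow(vals)
  if (length(spike_frames) == 0) {
    return(list(series = series, motion = motion))
  }
  spike_frames <- as.integer(spike_frames)
  if (any(spike_frames < 2L) || any(spike_frames > n)) {
    stopf("spike frames must lie in 2..%d", n)
  }
  for (t in spike_frames) {
    motion[t:n, 1] <- motion[t:n, 1] + translation_step
    vals[t, ] <- vals[t, ] + artifact_scale * rnorm(ncol(vals))
  }
  if (is_rts) series$values <- vals else series <- vals
  list(series = series, motion = motion)
}

#' Simulate a synthetic multi-group cohort with planted FC deficits
#'
#' Generates, fully reproducibly from the config seed: per-subject ROI time
#' series drawn from a zero-mean stationary multivariate Gaussian model whose
#' population correlation equals the subject group's target matrix (base
#' equicorrelation minus the group's planted deficit, PSD-repaired if
#' needed); 6-column motion tables with drift and censorable spikes;
#' demographic covariates; and neuropsychological scores that are affine in
#' the group's true overall FC plus Gaussian noise.
#'
#' @param config a [simulation_config()]
#' @param registry an ROI registry; `NULL` uses the packaged 48 WM + 82 GM
#'   registry
#' @return list of class `wm_cohort` with elements `subjects` (named list of
#'   `series` / `motion` pairs), `table` (cohort data frame with group,
#'   covariates and scores), `truth` (ground truth: target matrices, deficit
#'   edges, score model, per-group true overall FC) and `registry`
#' @export
simulate_cohort <- function(config, registry = NULL) {
  if (is.null(registry)) registry <- load_roi_registry()
  groups <- names(config$n_per_group)
  edges <- config$deficit_edges %||% default_deficit_edges(registry)
  set.seed(config$seed)

  targets <- lapply(groups, function(g) {
    build_target_matrix(registry, config$base_correlation, edges,
                        config$deficit_delta_by_group[[g]], group = g,
                        mode = config$deficit_mode %||% "attenuate")
  })
  names(targets) <- groups

  # true overall FC per group: mean over the WM-GM block of the target
  wm_idx <- which(registry$tissue == "WM")
  gm_idx <- which(registry$tissue == "GM")
  f_g <- vapply(targets, function(R) mean(R[wm_idx, gm_idx]), 0)
  f_cn <- if ("CN" %in% groups) f_g[["CN"]] else max(f_g)
  f_add <- if ("ADD" %in% groups) f_g[["ADD"]] else min(f_g)
  u_g <- if (abs(f_cn - f_add) < 1e-12) setNames(rep(1, length(groups)), groups)
         else (f_g - f_add) / (f_cn - f_add)

  score_model <- default_score_model()
  chols <- lapply(targets, function(R) chol(R))
  p <- nrow(registry)
  subjects <- list()
  rows <- list()
  sid <- 0L
  for (g in groups) {
    U <- chols[[g]]
    for (k in seq_len(config$n_per_group[[g]])) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      Z <- matrix(rnorm(config$n_frames * p), config$n_frames, p)
      if (config$ar_coefficient > 0) {
        phi <- config$ar_coefficient
        Z <- apply(Z, 2, function(z) {
          as.numeric(stats::filter(z * sqrt(1 - phi^2), phi,
                                   method = "recursive"))
        })
      }
      vals <- Z %*% U
      colnames(vals) <- registry$abbreviation
      motion <- cbind(
        apply(matrix(rnorm(config$n_frames * 3, 0, 0.01), ncol = 3), 2, cumsum),
        apply(matrix(rnorm(config$n_frames * 3, 0, 2e-4), ncol = 3), 2, cumsum))
      colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
      spike_frames <- which(runif(config$n_frames) < config$motion_spike_rate)
      spike_frames <- spike_frames[spike_frames >= 2L]
      ser <- roi_timeseries(vals, tr_seconds = config$tr_seconds)
      inj <- inject_motion(ser, motion, spike_frames,
                           translation_step = config$spike_translation_mm)
      scores <- vapply(seq_len(nrow(score_model)), function(i) {
        m <- score_model[i, ]
        raw <- m$add_mean + u_g[[g]] * (m$cn_mean - m$add_mean) +
          rnorm(1, 0, m$noise_sd * config$score_noise_scale)
        min(max(raw, m$lo), m$hi)
      }, 0)
      names(scores) <- score_model$score
      subjects[[id]] <- list(series = inj$series, motion = inj$motion)
      rows[[id]] <- data.frame(
        subject = id, group = g,
        age = min(max(rnorm(1, 74.5, 7), 60), 90),
        sex = rbinom(1, 1, 0.5),
        education = max(rnorm(1, 16.4, 2.6), 8),
        site = sample(c("siteA", "siteB", "siteC"), 1),
        as.list(scores),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$group <- factor(tab$group, levels = groups)
  truth <- list(target_fc_by_group = targets, deficit_edges = edges,
                deficit_delta_by_group = config$deficit_delta_by_group,
                score_model = score_model,
                score_slope_sign = setNames(sign(score_model$cn_mean -
                                                   score_model$add_mean),
                                            score_model$score),
                overall_fc_by_group = f_g, normalized_fc_by_group = u_g)
  structure(list(subjects = subjects, table = tab, truth = truth,
                 registry = registry, config = config),
            class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf("wm_cohort: %d subjects in %d groups, %d frames x %d ROIs\n",
              length(x$subjects), nlevels(x$table$group),
              x$config$n_frames, nrow(x$registry)))
  print(table(x$table$group))
  invisible(x)
}

#' Write a cohort to disk as plain-text tables
#'
#' Writes one time-series TSV and one motion TSV per subject, the cohort
#' table, and a JSON ground-truth summary (deficit edges, per-group deltas
#' and true overall FC; the full target matrices stay in memory).
#'
#' @param cohort a [simulate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    write_roi_timeseries(s$series, file.path(dir, paste0(id, "_roi.tsv")))
    write.table(s$motion, file.path(dir, paste0(id, "_motion.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(cohort$table, file.path(dir, "cohort.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- list(deficit_edges = cohort$truth$deficit_edges,
             deficit_delta_by_group = as.list(cohort$truth$deficit_delta_by_group),
             overall_fc_by_group = as.list(cohort$truth$overall_fc_by_group),
             score_slope_sign = as.list(cohort$truth$score_slope_sign))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
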