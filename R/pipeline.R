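#' Build (or read) a pipeline run configuration
#'
#' A run configuration drives the end-to-end analysis. It can be given as a
#' YAML file or as a named list; unspecified keys take the protocol defaults
#' (tissue-probability threshold 0.8, FD threshold 0.5 mm, passband
#' 0.01-0.1 Hz, 10,000 permutations, FDR level 0.05, 200 trees, 10 folds,
#' selection step 5).
#'
#' @param config path to a YAML file, or a named list
#' @return validated list of class `run_config`
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    mode = "synthetic",              # synthetic | roi_timeseries | nifti
    seed = 1L,
    output_dir = "wmfc_out",
    input_dir = NULL,                # roi_timeseries / nifti modes
    simulation = list(),             # overrides for simulation_config()
    cleaning = list(),               # overrides for cleaning_config()
    stats = list(n_perm = 10000, alpha = 0.05),
    behavior = list(n_trees = 200, chunk = 5, folds = 10, max_size = Inf),
    classify = list(n_trees = 200, chunk = 5, folds = 10, nested = TRUE,
                    max_size = Inf),
    contrast_groups = NULL,          # non-CN groups to compare; NULL = all
    stages = c("cohort", "fcm", "groupstats", "behavior", "classify"),
    min_frames = 10,
    registry = NULL                  # path or roi_registry; NULL = packaged
  )
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  if (!defaults$mode %in% c("synthetic", "roi_timeseries", "nifti")) {
    stopf("mode must be synthetic, roi_timeseries or nifti")
  }
  if (defaults$mode != "synthetic" && is.null(defaults$input_dir)) {
    stopf("mode %s requires input_dir", defaults$mode)
  }
  structure(defaults, class = "run_config")
}

#' @noRd
load_roi_timeseries_cohort <- function(input_dir, registry, tr_seconds = 3) {
  tab_path <- file.path(input_dir, "cohort.tsv")
  if (!file.exists(tab_path)) stopf("missing cohort table: %s", tab_path)
  tab <- read.table(tab_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  subjects <- list()
  for (id in tab$subject) {
    ts_path <- file.path(input_dir, paste0(id, "_roi.tsv"))
    mo_path <- file.path(input_dir, paste0(id, "_motion.tsv"))
    if (!file.exists(ts_path)) stopf("missing time-series file for %s", id)
    ser <- read_roi_timeseries(ts_path, tr_seconds = tr_seconds)
    motion <- if (file.exists(mo_path)) {
      as.matrix(read.table(mo_path, sep = "\t", header = TRUE))
    } else matrix(0, nrow(ser$values), 6)
    subjects[[id]] <- list(series = ser, motion = motion)
  }
  tab$group <- factor(tab$group, levels = unique(tab$group))
  structure(list(subjects = subjects, table = tab, truth = NULL,
                 registry = registry,
                 config = list(n_frames = nrow(subjects[[1]]$series$values),
                               tr_seconds = tr_seconds)),
            class = "wm_cohort")
}

#' @noRd
load_nifti_cohort <- function(input_dir, registry, cleaning) {
  tab_path <- file.path(input_dir, "cohort.tsv")
  if (!file.exists(tab_path)) stopf("missing cohort table: %s", tab_path)
  tab <- read.table(tab_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  labels <- RNifti::readNifti(file.path(input_dir, "atlas_labels.nii.gz"))
  prob <- RNifti::readNifti(file.path(input_dir, "tissue_probability.nii.gz"))
  masks <- build_masks(labels, prob, registry,
                       threshold = cleaning$probability_threshold)
  subjects <- list()
  for (id in tab$subject) {
    bold <- read_bold_nifti(file.path(input_dir, paste0(id, "_bold.nii.gz")))
    mo_path <- file.path(input_dir, paste0(id, "_motion.tsv"))
    motion <- if (file.exists(mo_path)) {
      as.matrix(read.table(mo_path, sep = "\t", header = TRUE))
    } else matrix(0, nrow(bold$values), 6)
    csf_path <- file.path(input_dir, paste0(id, "_csf.tsv"))
    csf <- if (file.exists(csf_path)) {
      read.table(csf_path, header = TRUE)[[1]]
    } else NULL
    tr <- if (is.na(bold$tr_seconds)) 3 else bold$tr_seconds
    cleaned <- clean_timeseries(bold$values, motion = motion, csf = csf,
                                tr_seconds = tr, config = cleaning)
    ser <- extract_roi_means(cleaned, masks, registry, tr_seconds = tr)
    subjects[[id]] <- list(series = ser, motion = motion)
  }
  tab$group <- factor(tab$group, levels = unique(tab$group))
  structure(list(subjects = subjects, table = tab, truth = NULL,
                 registry = registry, config = list(tr_seconds = 3)),
            class = "wm_cohort")
}

#' @noRd
write_stack_tsv <- function(stack, path) {
  df <- data.frame(subject = rownames(stack), stack, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full white-matter FC analysis pipeline
#'
#' Orchestrates: cohort acquisition (simulation, pre-extracted ROI series, or
#' NIfTI extraction) -> per-subject FC matrices with motion censoring ->
#' covariate partialling -> CN-vs-group comparisons (permutation + FDR,
#' effect sizes, tract-wise t-tests, overall-FC trend) -> FC-score
#' correlations and RF score regression -> staged SVM classification. All
#' stage outputs are written under `output_dir` together with a JSON
#' manifest; re-running the same config reproduces identical outputs.
#'
#' @param config a [run_config()], a list, or a YAML path
#' @return the manifest list, invisibly; principal in-memory results are in
#'   its `results` element
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cleaning <- do.call(cleaning_config, cfg$cleaning)
  registry <- if (is.null(cfg$registry)) {
    load_roi_registry()
  } else if (is.character(cfg$registry)) {
    load_roi_registry(cfg$registry)
  } else cfg$registry
  manifest <- list(mode = cfg$mode, seed = cfg$seed, stages = list(),
                   exclusions = list())
  results <- list()

  # --- cohort ---
  cohort <- switch(cfg$mode,
    synthetic = {
      sim_cfg <- do.call(simulation_config,
                         c(cfg$simulation,
                           if (is.null(cfg$simulation$seed))
                             list(seed = derive_seed(cfg$seed, "sim"))))
      simulate_cohort(sim_cfg, registry = registry)
    },
    roi_timeseries = load_roi_timeseries_cohort(cfg$input_dir, registry),
    nifti = load_nifti_cohort(cfg$input_dir, registry, cleaning))
  registry <- cohort$registry
  write.table(cohort$table, file.path(cfg$output_dir, "cohort.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$stages$cohort <- list(n_subjects = length(cohort$subjects),
                                 groups = as.list(table(cohort$table$group)),
                                 file = "cohort.tsv")
  if (!"fcm" %in% cfg$stages) {
    manifest$results <- results
    jsonlite::write_json(manifest[names(manifest) != "results"],
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }

  # --- fcm ---
  stacks <- cohort_fcm_stacks(cohort, kinds = c("WG", "WW"),
                              fd_threshold = cleaning$fd_threshold,
                              min_frames = cfg$min_frames)
  manifest$exclusions <- as.list(stacks$excluded)
  tab <- stacks$table
  covars <- c("age", "sex", "education", "site")
  if (all(covars %in% names(tab))) {
    wg <- partial_out_covariates(stacks$WG, tab[covars])
    ww <- partial_out_covariates(stacks$WW, tab[covars])
  } else {
    wg <- stacks$WG; ww <- stacks$WW
  }
  write_stack_tsv(wg, file.path(cfg$output_dir, "fcm_wg_stack.tsv"))
  write_stack_tsv(ww, file.path(cfg$output_dir, "fcm_ww_stack.tsv"))
  manifest$stages$fcm <- list(n_kept = nrow(wg),
                              n_excluded = length(stacks$excluded),
                              wg_elements = ncol(wg), ww_elements = ncol(ww),
                              files = c("fcm_wg_stack.tsv", "fcm_ww_stack.tsv"))
  results$wg <- wg; results$ww <- ww; results$table <- tab

  groups <- as.character(tab$group)
  glevels <- levels(tab$group)

  # --- groupstats ---
  if ("groupstats" %in% cfg$stages && "CN" %in% groups) {
    others <- cfg$contrast_groups %||% setdiff(glevels, "CN")
    others <- intersect(others, unique(groups))
    comparisons <- list()
    tract_tables <- list()
    tw <- tractwise_fc_stack(wg)
    for (g in others) {
      cmp <- group_comparison(wg, groups, c("CN", g),
                              n_perm = cfg$stats$n_perm,
                              alpha = cfg$stats$alpha,
                              seed = derive_seed(cfg$seed, paste0("perm", g)))
      comparisons[[g]] <- cmp
      write.table(unstack_fcm(cmp$thresholded_difference, wg),
                  file.path(cfg$output_dir, paste0("diff_wg_CN_vs_", g, ".tsv")),
                  sep = "\t", quote = FALSE)
      tract_tables[[g]] <- tract_ttest(tw, groups, c("CN", g))
      tract_tables[[g]]$contrast <- paste0("CN_vs_", g)
    }
    tract_tab <- do.call(rbind, tract_tables)
    if (!is.null(tract_tab)) {
      write.table(tract_tab, file.path(cfg$output_dir, "tractwise_fc_tests.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    trend <- if (all(c("CN", "ADD") %in% groups)) {
      overall_fc_trend(overall_fc(wg), factor(groups, levels = glevels))
    } else NULL
    if (!is.null(trend)) {
      write.table(trend, file.path(cfg$output_dir, "overall_fc_trend.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest$stages$groupstats <- list(
      contrasts = paste0("CN_vs_", others), n_perm = cfg$stats$n_perm,
      alpha = cfg$stats$alpha,
      files = c(paste0("diff_wg_CN_vs_", others, ".tsv"),
                "tractwise_fc_tests.tsv",
                if (!is.null(trend)) "overall_fc_trend.tsv"))
    results$comparisons <- comparisons
    results$tract_tests <- tract_tab
    results$trend <- trend
  }

  # --- behavior ---
  score_cols <- intersect(default_score_model()$score, names(tab))
  if ("behavior" %in% cfg$stages && length(score_cols) > 0) {
    assoc <- elementwise_score_correlation(wg, tab[score_cols],
                                           alpha = cfg$stats$alpha)
    tract_r <- vapply(assoc, function(a) tract_average_correlation(a$r_zeroed, wg),
                      numeric(length(attr(wg, "row_labels"))))
    write.table(data.frame(tract = rownames(tract_r), tract_r),
                file.path(cfg$output_dir, "tract_score_correlation.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    features <- fcm_features(wg, ww)
    scored <- rowSums(!is.na(tab[score_cols])) > 0
    regressions <- list()
    for (sc in score_cols) {
      reg <- tryCatch(
        rf_score_regression(features[scored, , drop = FALSE],
                            tab[[sc]][scored],
                            n_trees = cfg$behavior$n_trees,
                            chunk = cfg$behavior$chunk,
                            folds = cfg$behavior$folds,
                            max_size = cfg$behavior$max_size %||% Inf,
                            seed = derive_seed(cfg$seed, paste0("reg", sc))),
        error = function(e) NULL)
      if (!is.null(reg)) regressions[[sc]] <- reg
    }
    reg_summary <- data.frame(
      score = names(regressions),
      r = vapply(regressions, `[[`, 0, "r"),
      r2 = vapply(regressions, `[[`, 0, "r2"),
      p = vapply(regressions, `[[`, 0, "p"))
    write.table(reg_summary, file.path(cfg$output_dir, "score_regression.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$stages$behavior <- list(
      scores = score_cols, n_scored_subjects = sum(scored),
      files = c("tract_score_correlation.tsv", "score_regression.tsv"))
    results$score_association <- assoc
    results$score_regressions <- regressions
  }

  # --- classify ---
  if ("classify" %in% cfg$stages && "CN" %in% groups) {
    features <- fcm_features(wg, ww)
    ladder <- staging_ladder(features, groups,
                             n_trees = cfg$classify$n_trees,
                             chunk = cfg$classify$chunk,
                             folds = cfg$classify$folds,
                             nested = cfg$classify$nested,
                             max_size = cfg$classify$max_size %||% Inf,
                             seed = derive_seed(cfg$seed, "ladder"))
    summ <- data.frame(
      contrast = names(ladder),
      auc = vapply(ladder, `[[`, 0, "auc"),
      sensitivity = vapply(ladder, `[[`, 0, "sensitivity"),
      specificity = vapply(ladder, `[[`, 0, "specificity"),
      cv_error = vapply(ladder, `[[`, 0, "cv_error"))
    write.table(summ, file.path(cfg$output_dir, "staging_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(ladder)) {
      write.table(ladder[[nm]]$roc,
                  file.path(cfg$output_dir,
                            paste0("roc_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest$stages$classify <- list(
      contrasts = names(ladder), nested = cfg$classify$nested,
      files = c("staging_summary.tsv"))
    results$staging <- ladder
    results$staging_summary <- summ
  }

  manifest$results <- results
  jsonlite::write_json(manifest[names(manifest) != "results"],
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
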