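#' Benchmark configuration
#'
#' Bundles every tunable of the simulation benchmark with its default. The
#' defaults reproduce the study design: 168 features in 8 correlated
#' families per stratum, 32% normal marginals, a 600/300/100 x
#' balanced/unbalanced x high/low factorial, six selection settings crossed
#' with six classifiers, SMOTE on unbalanced training folds, and
#' probability threshold 0.5 for sensitivity/specificity.
#'
#' @param n_features,n_blocks,normal_fraction,within,between,skew_range
#'   reference-structure parameters (see [build_reference_stats()]).
#' @param sizes,balancings,signals scenario factorial levels.
#' @param shifts named list of shift vectors for high and low signal; `NULL`
#'   for the [scenario_spec()] defaults.
#' @param fs selection settings to run (subset of [fs_methods()]).
#' @param classifiers_ classifiers to run (subset of [classifiers()]).
#' @param replicates seeded replicates of the whole grid (default 5).
#' @param master_seed integer master seed; all child seeds derive from it.
#' @param alpha significance level for Wilcoxon filters and the FS-effect
#'   test (default 0.05).
#' @param threshold probability threshold for sensitivity/specificity
#'   (default 0.5).
#' @param cv_folds stratified CV folds for tuning (default 5).
#' @param tuning `"cv"` (grid search) or `"fast"` (fixed single-point
#'   grids, for large sweeps).
#' @param smote apply SMOTE to unbalanced training folds (default TRUE;
#'   balanced folds are never resampled).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param fs_control hyperparameter overrides for [select_features()].
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(n_features = 168, n_blocks = 8,
                             normal_fraction = 0.32, within = 0.7,
                             between = 0.1, skew_range = c(0.5, 3),
                             sizes = c(600, 300, 100),
                             balancings = c("balanced", "unbalanced"),
                             signals = c("high", "low"), shifts = NULL,
                             fs = fs_methods(),
                             classifiers_ = classifiers(),
                             replicates = 5, master_seed = 1, alpha = 0.05,
                             threshold = 0.5, cv_folds = 5,
                             tuning = c("cv", "fast"), smote = TRUE,
                             smote_k = 5, fs_control = list()) {
  tuning <- match.arg(tuning)
  stopifnot(replicates >= 1, alpha > 0, alpha < 1,
            all(fs %in% fs_methods()),
            all(classifiers_ %in% classifiers()))
  structure(as.list(environment()), class = "benchmark_config")
}

#' Run the full benchmark grid
#'
#' Sweeps scenario x feature-selection x classifier x replicate. Each
#' replicate rebuilds the twelve cohorts from a derived seed; within a
#' scenario the training fold is (for unbalanced scenarios) SMOTE-resampled,
#' each selection method is fitted once on the training fold, every
#' classifier is tuned and fitted on the selected features, and AUC,
#' sensitivity, specificity and planted-feature recovery are measured on the
#' untouched validation fold. LSR is skipped without a selection step
#' (stepwise regression on the full feature set is refused). Cell failures
#' are recorded as failed rows, never silently dropped.
#'
#' @param config a [benchmark_config()].
#' @param out_dir optional directory; if given, the tidy record table, the
#'   classifier/FS aggregate tables, an FS x classifier mean-AUC matrix, a
#'   sensitivity/specificity table and a run manifest are written there, and
#'   records are flushed incrementally after every scenario.
#' @param progress print per-cell progress to stderr (default FALSE).
#' @return data frame of performance records, one row per cell.
#' @export
run_benchmark <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  ref <- build_reference_stats(
    n_features = config$n_features, n_blocks = config$n_blocks,
    normal_fraction = config$normal_fraction,
    seed = derive_seed(config$master_seed, "reference"),
    within = config$within, between = config$between,
    skew_range = config$skew_range)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  records <- list()
  for (r in seq_len(config$replicates)) {
    rep_seed <- derive_seed(config$master_seed, paste0("rep/", r))
    suite <- build_scenario_suite(ref, rep_seed, sizes = config$sizes,
                                  balancings = config$balancings,
                                  signals = config$signals,
                                  shifts = config$shifts)
    for (nm in names(suite)) {
      records[[paste(r, nm)]] <- run_scenario_cells(
        suite[[nm]], config, replicate = r,
        seed = derive_seed(rep_seed, paste0("cells/", nm)),
        progress = progress)
      if (!is.null(out_dir)) {
        utils::write.csv(do.call(rbind, records),
                         file.path(out_dir, "records.csv"),
                         row.names = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  if (!is.null(out_dir)) {
    write_benchmark_reports(records, config, out_dir)
  }
  records
}

# All FS x classifier cells for one cohort
run_scenario_cells <- function(cohort, config, replicate, seed,
                               progress = FALSE) {
  tr <- cohort$split$train
  va <- cohort$split$validation
  x_tr <- cohort$features[tr, , drop = FALSE]
  y_tr <- cohort$outcome[tr]
  x_va <- cohort$features[va, , drop = FALSE]
  y_va <- cohort$outcome[va]
  resampled <- FALSE
  if (config$smote && cohort$spec$balancing == "unbalanced") {
    sm <- smote_oversample(x_tr, y_tr, k_neighbors = config$smote_k,
                           seed = derive_seed(seed, "smote"))
    x_tr <- sm$features
    y_tr <- sm$outcome
    resampled <- TRUE
  }
  ctl <- utils::modifyList(list(alpha = config$alpha), config$fs_control)
  rows <- list()
  for (fsm in config$fs) {
    sel <- tryCatch(select_features(fsm, x_tr, y_tr, control = ctl),
                    error = function(e) e)
    for (cl in config$classifiers_) {
      if (fsm == "none" && cl == "LSR") next # stepwise refused without FS
      row <- data.frame(
        size = cohort$spec$size, balancing = cohort$spec$balancing,
        signal = cohort$spec$signal, fs = fsm, classifier = cl,
        replicate = replicate, smote = resampled,
        n_selected = NA_integer_, auc = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_,
        controls_in_top20 = NA_integer_, status = "ok",
        stringsAsFactors = FALSE)
      if (inherits(sel, "error")) {
        row$status <- paste0("failed: ", conditionMessage(sel))
        rows[[paste(fsm, cl)]] <- row
        next
      }
      cell_seed <- derive_seed(seed, paste(fsm, cl, sep = "/"))
      out <- tryCatch({
        m <- tune_and_fit(cl, x_tr[, sel$selected, drop = FALSE], y_tr,
                          cv_folds = config$cv_folds,
                          grid = if (config$tuning == "fast") "fast",
                          seed = cell_seed)
        sc <- predict_scores(m, x_va)
        ss <- sens_spec(sc, y_va, threshold = config$threshold)
        row$n_selected <- length(sel$selected)
        row$auc <- roc_auc(sc, y_va)
        row$sensitivity <- ss[["sensitivity"]]
        row$specificity <- ss[["specificity"]]
        if (cl %in% c("PR", "RF", "XGBoost", "LSR")) {
          row$controls_in_top20 <- top20_recovery(extract_importance(m),
                                                  cohort$controls)
        }
        row
      }, error = function(e) {
        row$status <- paste0("failed: ", conditionMessage(e))
        row
      })
      if (progress) {
        message(sprintf("[rep %d] %s_%s_%s | %-20s | %-7s | AUC %s",
                        replicate, cohort$spec$size,
                        cohort$spec$balancing, cohort$spec$signal, fsm, cl,
                        ifelse(is.na(out$auc), out$status,
                               sprintf("%.3f", out$auc))))
      }
      rows[[paste(fsm, cl)]] <- out
    }
  }
  do.call(rbind, rows)
}

# Aggregate tables, AUC heatmap matrix, SE/SP table and manifest
write_benchmark_reports <- function(records, config, out_dir) {
  ok <- records[records$status == "ok", , drop = FALSE]
  utils::write.csv(records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(aggregate_records(ok, by = "classifier"),
                   file.path(out_dir, "aggregate_by_classifier.csv"),
                   row.names = FALSE)
  utils::write.csv(aggregate_records(ok, by = "fs"),
                   file.path(out_dir, "aggregate_by_fs.csv"),
                   row.names = FALSE)
  auc_mat <- stats::aggregate(auc ~ fs + classifier, data = ok, FUN = mean)
  wide <- stats::reshape(auc_mat, idvar = "fs", timevar = "classifier",
                         direction = "wide")
  names(wide) <- sub("^auc\\.", "", names(wide))
  utils::write.csv(wide, file.path(out_dir, "auc_matrix.csv"),
                   row.names = FALSE)
  ss <- stats::aggregate(cbind(sensitivity, specificity) ~
                           size + balancing + signal + fs + classifier,
                         data = ok, FUN = mean)
  utils::write.csv(ss, file.path(out_dir, "sens_spec.csv"),
                   row.names = FALSE)
  manifest <- c(
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("r_version: %s", R.version.string),
    sprintf("master_seed: %d", config$master_seed),
    sprintf("replicates: %d", config$replicates),
    sprintf("tuning: %s", config$tuning),
    sprintf("cells_total: %d", nrow(records)),
    sprintf("cells_failed: %d", sum(records$status != "ok")),
    sprintf("config: %s", paste(deparse(config[setdiff(
      names(config), c("fs_control", "shifts"))]), collapse = " ")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(records)
}
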