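#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with half-credit for
#' ties, which equals the trapezoidal area under the empirical ROC curve and
#' is invariant to monotone transforms of the scores.
#'
#' @param scores numeric score/probability vector.
#' @param labels 0/1 vector, both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires both classes in the labels", call. = FALSE)
  }
  r <- rank(scores) # midranks give ties half credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a probability threshold
#'
#' Predicted positive iff `score >= threshold`.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5) {
  pos <- labels == 1
  if (!any(pos) || all(pos)) {
    stop("sensitivity/specificity require both classes", call. = FALSE)
  }
  pred <- scores >= threshold
  c(sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos))
}

#' Count planted control features recovered in the top 20
#'
#' @param importance character vector of feature ids ranked best first (or a
#'   data frame with a `feature` column, as returned by
#'   [extract_importance()]).
#' @param controls character vector of control feature ids.
#' @param top number of leading ranks inspected (default 20, inclusive).
#' @return integer count in 0..length(controls).
#' @export
top20_recovery <- function(importance, controls, top = 20) {
  if (is.data.frame(importance)) importance <- importance$feature
  stopifnot(length(importance) >= 1)
  sum(controls %in% utils::head(importance, top))
}

#' Aggregate performance records
#'
#' Mean and sample standard deviation of AUC, sensitivity and specificity per
#' group (classifier or feature-selection method), optionally split by signal
#' strength. A single-record group reports SD 0.
#'
#' @param records data frame of performance records (one row per scenario x
#'   FS x classifier x replicate) with columns `auc`, `sensitivity`,
#'   `specificity` and the grouping columns.
#' @param by `"classifier"` or `"fs"`.
#' @param by_signal also condition on the `signal` column (default FALSE).
#' @return data frame of group means and SDs.
#' @export
aggregate_records <- function(records, by = c("classifier", "fs"),
                              by_signal = FALSE) {
  by <- match.arg(by)
  stopifnot(nrow(records) > 0)
  keys <- if (by_signal) records[c(by, "signal")] else records[by]
  groups <- split(seq_len(nrow(records)), keys, drop = TRUE)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    r <- records[idx, , drop = FALSE]
    cbind(unique(keys[idx, , drop = FALSE]),
          data.frame(n = length(idx),
                     auc_mean = mean(r$auc), auc_sd = sd0(r$auc),
                     sensitivity_mean = mean(r$sensitivity),
                     sensitivity_sd = sd0(r$sensitivity),
                     specificity_mean = mean(r$specificity),
                     specificity_sd = sd0(r$specificity)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out[[by]]), , drop = FALSE]
}

#' Wilcoxon test for the effect of the feature-selection step
#'
#' Two-sided rank-sum test comparing validation AUC with (`fs != "none"`)
#' and without (`fs == "none"`) a selection step, optionally restricted to a
#' subset of classifiers or excluding some selection methods.
#'
#' @param records performance-record data frame with `auc`, `fs`,
#'   `classifier` columns.
#' @param classifiers optional subset of classifiers to compare within.
#' @param exclude_fs selection methods dropped from the "with FS" group.
#' @param alpha significance level for the reported decision (default 0.05).
#' @return list with the group means, W statistic, p-value, and the
#'   significance decision at `alpha`.
#' @export
fs_effect_test <- function(records, classifiers = NULL,
                           exclude_fs = character(0), alpha = 0.05) {
  r <- records
  if (!is.null(classifiers)) r <- r[r$classifier %in% classifiers, ]
  none <- r$auc[r$fs == "none"]
  with_fs <- r$auc[r$fs != "none" & !(r$fs %in% exclude_fs)]
  if (length(none) == 0 || length(with_fs) == 0) {
    stop("both the no-FS and with-FS groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(none, with_fs, exact = NULL))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(mean_auc_no_fs = mean(none), mean_auc_fs = mean(with_fs),
       statistic = unname(wt$statistic), p_value = p,
       significant = p < alpha, alpha = alpha,
       n_no_fs = length(none), n_fs = length(with_fs))
}
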