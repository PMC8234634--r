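#' Define one benchmark scenario
#'
#' A scenario is one cell of the size x balancing x signal factorial. The
#' default shift vectors place the planted class separation on the three
#' control features, in units of the feature's pooled within-class standard
#' deviation: under high signal all three controls are strongly separated
#' (2 SD each); under low signal only the larger shifts remain reliably
#' detectable at small sample sizes.
#'
#' @param size total cohort size; one of 600 ("large"), 300 ("medium"),
#'   100 ("small") by default (any positive size is accepted).
#' @param balancing `"balanced"` (50% positives) or `"unbalanced"` (30%).
#' @param signal `"high"` or `"low"`; selects the default `shifts`.
#' @param control_features character vector of 3 feature ids carrying signal.
#' @param shifts numeric vector of 3 non-negative shifts (pooled-SD units);
#'   defaults to (2, 2, 2) for high and (1.2, 0.8, 0.5) for low signal.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(size = 600,
                          balancing = c("balanced", "unbalanced"),
                          signal = c("high", "low"),
                          control_features = character(0),
                          shifts = NULL) {
  balancing <- match.arg(balancing)
  signal <- match.arg(signal)
  if (is.null(shifts)) {
    shifts <- if (signal == "high") c(2, 2, 2) else c(1.2, 0.8, 0.5)
  }
  stopifnot(size >= 2, all(shifts >= 0),
            length(control_features) == 0 ||
              length(control_features) == length(shifts),
            !anyDuplicated(control_features))
  structure(list(size = size, balancing = balancing, signal = signal,
                 control_features = control_features, shifts = shifts),
            class = "scenario_spec")
}

#' @exportS3Method base::print
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario: n=%d, %s, %s signal; controls %s; shifts %s\n",
              x$size, x$balancing, x$signal,
              paste(x$control_features, collapse = "/"),
              paste(x$shifts, collapse = "/")))
  invisible(x)
}

#' Design counts per stratum and class
#'
#' The per-stratum (FBP:IR = 2:1) and per-class (50:50 or 70:30) counts for a
#' given total size, filled by largest-remainder apportionment so that both
#' margins are met exactly: stratum totals and class totals are apportioned
#' first, the FBP row is apportioned within its total (ties to the negative
#' class), and the IR row is the remainder. Reproduces e.g. 34/33/16/17 at
#' n = 100 balanced and 47/20/23/10 at n = 100 unbalanced.
#'
#' @param size total number of samples.
#' @param balancing `"balanced"` or `"unbalanced"`.
#' @param stratum_props named proportions of the strata (default 2:1).
#' @return integer matrix, rows = strata, columns = c("neg", "pos").
#' @export
design_counts <- function(size, balancing,
                          stratum_props = c(FBP = 2 / 3, IR = 1 / 3)) {
  class_props <- if (balancing == "balanced") c(0.5, 0.5) else c(0.7, 0.3)
  stratum_tot <- apportion(size, stratum_props)
  class_tot <- apportion(size, class_props)
  S <- length(stratum_tot)
  counts <- matrix(0L, S, 2,
                   dimnames = list(names(stratum_props), c("neg", "pos")))
  for (s in seq_len(S - 1)) {
    counts[s, ] <- apportion(stratum_tot[s], class_props)
  }
  counts[S, ] <- class_tot - colSums(counts[-S, , drop = FALSE])
  if (any(counts < 0)) {
    stop("size too small to realize the design proportions", call. = FALSE)
  }
  counts
}

#' Randomly assign a binary outcome with exact class counts
#'
#' @param n number of samples (>= 2).
#' @param balancing `"balanced"` (exactly `round(0.5 n)` positives) or
#'   `"unbalanced"` (exactly `round(0.3 n)`).
#' @param seed integer seed.
#' @return integer vector of 0/1 labels.
#' @export
assign_outcome <- function(n, balancing = c("balanced", "unbalanced"), seed) {
  balancing <- match.arg(balancing)
  stopifnot(n >= 2)
  n_pos <- round(ifelse(balancing == "balanced", 0.5, 0.3) * n)
  if (n_pos < 1 || n_pos > n - 1) {
    stop("n too small to realize both outcome classes", call. = FALSE)
  }
  set.seed(seed)
  outcome <- integer(n)
  outcome[sample.int(n, n_pos)] <- 1L
  outcome
}

new_cohort <- function(features, outcome, stratum, controls, spec,
                       sample_id = NULL, split = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sprintf("S%04d", seq_len(nrow(features)))
  }
  structure(list(features = features, outcome = unname(as.integer(outcome)),
                 stratum = unname(stratum), controls = controls, spec = spec,
                 sample_id = unname(sample_id), split = split),
            class = "radbench_cohort")
}

#' @exportS3Method base::print
print.radbench_cohort <- function(x, ...) {
  cat(sprintf(
    "cohort: %d samples x %d features (%d positives; FBP %d / IR %d)%s\n",
    nrow(x$features), ncol(x$features), sum(x$outcome),
    sum(x$stratum == "FBP"), sum(x$stratum == "IR"),
    if (!is.null(x$split)) sprintf("; split %d/%d", length(x$split$train),
                                   length(x$split$validation)) else ""))
  invisible(x)
}

#' Plant outcome signal on the control features
#'
#' Each control feature is shifted additively in the positive class by
#' `shift_k` times that feature's whole-cohort (pre-shift) standard
#' deviation. Non-control features and the entire negative class are left
#' bitwise untouched. Applied after range rescaling.
#'
#' @param cohort a `radbench_cohort`.
#' @param spec a `scenario_spec` providing `control_features` and `shifts`.
#' @return the cohort with shifted control features.
#' @export
inject_signal <- function(cohort, spec) {
  stopifnot(inherits(cohort, "radbench_cohort"),
            inherits(spec, "scenario_spec"))
  controls <- spec$control_features
  if (!all(controls %in% colnames(cohort$features))) {
    stop("unknown control feature id(s): ",
         paste(setdiff(controls, colnames(cohort$features)), collapse = ", "),
         call. = FALSE)
  }
  pos <- cohort$outcome == 1L
  for (k in seq_along(controls)) {
    sd_k <- stats::sd(cohort$features[, controls[k]])
    cohort$features[pos, controls[k]] <-
      cohort$features[pos, controls[k]] + spec$shifts[k] * sd_k
  }
  cohort$controls <- controls
  cohort$spec <- spec
  cohort
}

#' Build one full 600-sample scenario cohort
#'
#' Simulates features separately for the FBP and IR strata (400 and 200
#' samples), rescales each feature to its reference range, assigns the
#' outcome within each stratum so that the per-stratum per-class design
#' counts hold exactly, and plants the signal on the control features.
#'
#' @param ref a `reference_stats` object (both strata).
#' @param spec a `scenario_spec`; empty `control_features` are filled from
#'   `ref$controls`.
#' @param seed integer master seed for this cohort (child seeds are derived
#'   per stage).
#' @param n_total total cohort size before subsampling (default 600).
#' @param preps optional named list of prepared `vm_simulator`s per stratum,
#'   to amortize the Fleishman/Vale-Maurelli setup across cohorts.
#' @return a `radbench_cohort` of `n_total` samples.
#' @export
build_full_scenario <- function(ref, spec, seed, n_total = 600,
                                preps = NULL) {
  stopifnot(inherits(ref, "reference_stats"), inherits(spec, "scenario_spec"))
  if (length(spec$control_features) == 0) {
    spec$control_features <- ref$controls
    stopifnot(length(spec$control_features) == length(spec$shifts))
  }
  counts <- design_counts(n_total, spec$balancing)
  feats <- list()
  outcome <- list()
  stratum <- list()
  for (s in rownames(counts)) {
    n_s <- sum(counts[s, ])
    prep <- if (!is.null(preps)) preps[[s]]
            else vm_prepare(ref$strata[[s]]$moments,
                            ref$strata[[s]]$correlation)
    x <- simulate_features(prep, n = n_s,
                           seed = derive_seed(seed, paste0("sim/", s)))
    m <- ref$strata[[s]]$moments
    for (j in seq_len(ncol(x))) {
      x[, j] <- rescale_to_range(x[, j], m$range_min[j], m$range_max[j])
    }
    y <- integer(n_s)
    set.seed(derive_seed(seed, paste0("outcome/", s)))
    y[sample.int(n_s, counts[s, "pos"])] <- 1L
    feats[[s]] <- x
    outcome[[s]] <- y
    stratum[[s]] <- rep(s, n_s)
  }
  cohort <- new_cohort(do.call(rbind, feats), unlist(outcome),
                       unlist(stratum), spec$control_features, spec)
  inject_signal(cohort, spec)
}

#' Stratified train/validation split
#'
#' Splits a cohort into training (`round(2n/3)` samples) and validation sets,
#' stratified by outcome class crossed with reconstruction stratum; per-cell
#' training counts are filled by largest-remainder apportionment so the total
#' is conserved exactly.
#'
#' @param cohort a `radbench_cohort` (every class x stratum cell non-empty).
#' @param seed integer seed.
#' @return the cohort with a `split` element: list of integer index vectors
#'   `train` and `validation`.
#' @export
split_train_validation <- function(cohort, seed) {
  n <- nrow(cohort$features)
  stopifnot(n >= 3)
  cells <- cohort_cells(cohort)
  if (any(lengths(cells) == 0)) {
    stop("every class x stratum cell must be non-empty for a stratified split",
         call. = FALSE)
  }
  train_total <- round(2 * n / 3)
  per_cell <- apportion(train_total, lengths(cells))
  set.seed(seed)
  train <- integer(0)
  for (k in seq_along(cells)) {
    idx <- cells[[k]]
    train <- c(train, sort(idx[sample.int(length(idx), per_cell[k])]))
  }
  train <- sort(train)
  cohort$split <- list(train = train,
                       validation = setdiff(seq_len(n), train))
  cohort
}

# Cells in deterministic order: stratum (FBP first) x class (neg first)
cohort_cells <- function(cohort) {
  strata <- unique(cohort$stratum)
  cells <- list()
  for (s in strata) {
    for (cl in c(0L, 1L)) {
      cells[[paste(s, cl, sep = "/")]] <-
        which(cohort$stratum == s & cohort$outcome == cl)
    }
  }
  cells
}

#' Subsample a cohort to a smaller design size
#'
#' Draws, without replacement, the exact per-stratum per-class design counts
#' for the target size. When the cohort carries a train/validation split the
#' subsampling happens within the training and validation sets separately
#' (each cell's target is itself split by largest remainder), so that nested
#' chains 100 within 300 within 600 preserve set membership.
#'
#' @param cohort a `radbench_cohort`.
#' @param size target size (<= current size).
#' @param seed integer seed.
#' @return a `radbench_cohort` of `size` samples (split preserved if
#'   present). Sample ids carry over, so nesting can be verified.
#' @export
subsample <- function(cohort, size, seed) {
  n <- nrow(cohort$features)
  if (size > n) {
    stop("subsample size exceeds cohort size", call. = FALSE)
  }
  counts <- design_counts(size, cohort$spec$balancing)
  cells <- cohort_cells(cohort)
  target <- as.integer(t(counts)) # order matches cohort_cells
  train_total <- if (!is.null(cohort$split)) round(2 * size / 3) else NULL
  per_cell_train <- if (!is.null(train_total)) {
    apportion(train_total, target)
  }
  set.seed(seed)
  keep <- integer(0)
  for (k in seq_along(cells)) {
    idx <- cells[[k]]
    if (length(idx) < target[k]) {
      stop("cohort cell too small for requested subsample", call. = FALSE)
    }
    if (is.null(cohort$split)) {
      keep <- c(keep, idx[sample.int(length(idx), target[k])])
    } else {
      tr <- intersect(idx, cohort$split$train)
      va <- intersect(idx, cohort$split$validation)
      n_tr <- per_cell_train[k]
      n_va <- target[k] - n_tr
      if (length(tr) < n_tr || length(va) < n_va) {
        stop("cohort split cell too small for requested subsample",
             call. = FALSE)
      }
      keep <- c(keep, tr[sample.int(length(tr), n_tr)],
                va[sample.int(length(va), n_va)])
    }
  }
  keep <- sort(keep)
  spec <- cohort$spec
  spec$size <- size
  out <- new_cohort(cohort$features[keep, , drop = FALSE],
                    cohort$outcome[keep], cohort$stratum[keep],
                    cohort$controls, spec,
                    sample_id = cohort$sample_id[keep])
  if (!is.null(cohort$split)) {
    out$split <- list(
      train = which(keep %in% cohort$split$train),
      validation = which(keep %in% cohort$split$validation))
  }
  out
}

#' Build the full factorial of benchmark cohorts
#'
#' Produces the twelve scenario cohorts: for each balancing a base feature
#' set of 600 samples is simulated once and the outcome assigned; each signal
#' level is then planted on a copy, the 600-cohort is split 2/3-1/3, and the
#' medium and small cohorts are drawn nested (small within medium within
#' large, separately in the training and validation sets).
#'
#' @param ref a `reference_stats` object.
#' @param seed master seed.
#' @param sizes design sizes, largest first (default c(600, 300, 100)).
#' @param balancings,signals factor levels to cross.
#' @param shifts named list with `high` and `low` shift vectors; `NULL` for
#'   the `scenario_spec` defaults.
#' @return named list of `radbench_cohort`s, names like
#'   `"600_balanced_high"`.
#' @export
build_scenario_suite <- function(ref, seed, sizes = c(600, 300, 100),
                                 balancings = c("balanced", "unbalanced"),
                                 signals = c("high", "low"),
                                 shifts = NULL) {
  sizes <- sort(sizes, decreasing = TRUE)
  preps <- lapply(ref$strata, function(s) {
    vm_prepare(s$moments, s$correlation)
  })
  suite <- list()
  for (bal in balancings) {
    base_seed <- derive_seed(seed, paste0("cohort/", bal))
    for (sig in signals) {
      spec <- scenario_spec(size = sizes[1], balancing = bal, signal = sig,
                            control_features = ref$controls,
                            shifts = shifts[[sig]])
      full <- build_full_scenario(ref, spec, base_seed, n_total = sizes[1],
                                  preps = preps)
      full <- split_train_validation(
        full, derive_seed(seed, paste0("split/", bal)))
      suite[[paste(sizes[1], bal, sig, sep = "_")]] <- full
      parent <- full
      for (sz in sizes[-1]) {
        parent <- subsample(parent, sz,
                            derive_seed(seed, paste0("sub/", bal, "/", sz)))
        suite[[paste(sz, bal, sig, sep = "_")]] <- parent
      }
    }
  }
  suite
}

#' Write / load a cohort as delimited text
#'
#' Columns: `sample_id`, `stratum`, `outcome`, then one column per feature.
#'
#' @param cohort a `radbench_cohort`.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(sample_id = cohort$sample_id, stratum = cohort$stratum,
                   outcome = cohort$outcome, cohort$features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort
#' @param spec optional `scenario_spec` to attach.
#' @export
load_cohort <- function(path, spec = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample_id", "stratum", "outcome")
  if (!all(meta %in% names(df))) {
    stop("cohort file must have sample_id, stratum and outcome columns",
         call. = FALSE)
  }
  features <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  new_cohort(features, df$outcome, df$stratum,
             controls = if (!is.null(spec)) spec$control_features
                        else character(0),
             spec = spec, sample_id = df$sample_id)
}
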