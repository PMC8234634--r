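#' Build a synthetic reference description of radiomic-like features
#'
#' The benchmark needs a statistical portrait of a radiomic feature table to
#' drive the simulator: per-feature skewness, excess kurtosis and ranges for
#' two reconstruction strata (FBP and IR), plus a feature-feature correlation
#' matrix. This function generates a parametric stand-in with block
#' correlation structure: features fall into `n_blocks` families with high
#' within-family correlation and low between-family correlation, roughly a
#' `normal_fraction` share of features are normal and the rest skewed and
#' heavy-tailed, and three designated control features (one each from three
#' distinct families, emulating a texture, an intensity-histogram and a 3D
#' shape feature) are kept weakly correlated with every other feature so that
#' planted outcome signal is attributable to them alone.
#'
#' @param n_features features per stratum (default 168).
#' @param n_blocks number of feature families (default 8).
#' @param normal_fraction share of features with skewness 0 and excess
#'   kurtosis 0 (default 0.32); the count is rounded, the features sampled.
#' @param seed integer seed; output is deterministic given all arguments.
#' @param within,between within- and between-block correlations
#'   (defaults 0.7 and 0.1).
#' @param skew_range range the non-normal skewnesses are drawn from
#'   (default c(0.5, 3)).
#' @param kurt_spread width of the uniform band above the Fleishman
#'   feasibility boundary that excess kurtosis is drawn from (default 4).
#' @param n_controls number of control features (default 3; 0 when the
#'   structure is too small to host them).
#' @return a `reference_stats` object: list with `strata` (per-stratum lists
#'   of `moments` data frame and `correlation` matrix) and `controls`
#'   (character vector of control feature ids).
#' @export
build_reference_stats <- function(n_features = 168, n_blocks = 8,
                                  normal_fraction = 0.32, seed = 1,
                                  within = 0.7, between = 0.1,
                                  skew_range = c(0.5, 3), kurt_spread = 4,
                                  n_controls = 3) {
  stopifnot(n_features >= 1, n_blocks >= 1, n_features >= n_blocks,
            normal_fraction >= 0, normal_fraction <= 1,
            within >= 0, within < 1, between >= 0, between <= within)
  feature_id <- sprintf("F%03d", seq_len(n_features))
  block_sizes <- apportion(n_features, rep(1, n_blocks))
  block_id <- rep(seq_len(n_blocks), times = block_sizes)

  if (n_controls > 0 && n_blocks >= n_controls && n_features >= n_controls) {
    ctrl_blocks <- unique(round(seq(1, n_blocks, length.out = n_controls)))
    controls <- feature_id[match(ctrl_blocks, block_id)]
  } else {
    controls <- character(0)
  }

  corr <- block_correlation_template(block_id, within, between,
                                     detached = match(controls, feature_id))
  dimnames(corr) <- list(feature_id, feature_id)

  # feature ranges: per-family magnitude factor, echoing the very different
  # numeric scales of shape, intensity and texture features
  range_max <- 100 * 10^((block_id - 1) %% 3)
  range_min <- rep(0, n_features)

  set.seed(seed)
  strata <- list()
  for (stratum in c("FBP", "IR")) {
    n_normal <- round(normal_fraction * n_features)
    normal_idx <- sample.int(n_features, n_normal)
    g1 <- numeric(n_features)
    g2 <- numeric(n_features)
    for (i in setdiff(seq_len(n_features), normal_idx)) {
      drawn <- draw_feasible_moments(skew_range, kurt_spread)
      g1[i] <- drawn[1]
      g2[i] <- drawn[2]
    }
    moments <- data.frame(
      feature_id = feature_id, stratum = stratum,
      skewness = g1, excess_kurtosis = g2,
      range_min = range_min, range_max = range_max,
      block_id = block_id, stringsAsFactors = FALSE)
    strata[[stratum]] <- list(moments = moments, correlation = corr)
  }
  structure(list(strata = strata, controls = controls),
            class = "reference_stats")
}

# Block-structured correlation template. `detached` features (the controls)
# get the between-block correlation with everyone, including own-block mates.
block_correlation_template <- function(block_id, within, between,
                                       detached = integer(0)) {
  p <- length(block_id)
  corr <- matrix(between, p, p)
  same <- outer(block_id, block_id, "==")
  corr[same] <- within
  if (length(detached) > 0) {
    corr[detached, ] <- between
    corr[, detached] <- between
  }
  diag(corr) <- 1
  corr
}

# Approximate lower boundary of the Fleishman-feasible region in the
# (skewness, excess kurtosis) plane, used as a sampling floor; every draw is
# re-checked with the solver and resampled on failure.
fleishman_kurtosis_floor <- function(skewness) {
  -1.2264489 + 1.6410373 * skewness^2
}

draw_feasible_moments <- function(skew_range, kurt_spread, max_attempts = 50) {
  for (attempt in seq_len(max_attempts)) {
    g1 <- stats::runif(1, skew_range[1], skew_range[2])
    lb <- fleishman_kurtosis_floor(g1) + 0.1
    g2 <- stats::runif(1, lb, lb + kurt_spread)
    if (fleishman_feasible(g1, g2)) {
      return(c(g1, g2))
    }
  }
  stop("could not draw a Fleishman-feasible (skewness, kurtosis) pair; ",
       "check skew_range / kurt_spread configuration", call. = FALSE)
}

#' Write / load reference statistics as delimited text
#'
#' The moments file is comma-delimited with header
#' `feature_id,stratum,skewness,excess_kurtosis,range_min,range_max,block_id`
#' (both strata stacked). The correlation file carries feature ids as the
#' first row and column and the matrix as the body; the same matrix is
#' applied to both strata.
#'
#' @param ref a `reference_stats` object.
#' @param moments_path,correlation_path file paths.
#' @export
write_reference_stats <- function(ref, moments_path, correlation_path) {
  stopifnot(inherits(ref, "reference_stats"))
  moments <- do.call(rbind, lapply(ref$strata, `[[`, "moments"))
  rownames(moments) <- NULL
  utils::write.csv(moments, moments_path, row.names = FALSE, quote = FALSE)
  corr <- ref$strata[[1]]$correlation
  out <- data.frame(feature_id = rownames(corr), corr, check.names = FALSE)
  utils::write.csv(out, correlation_path, row.names = FALSE, quote = FALSE)
  invisible(ref)
}

#' @rdname write_reference_stats
#' @param controls optional character vector naming the control features
#'   (control designation is not part of the file format).
#' @return `load_reference_stats`: a validated `reference_stats` object.
#' @export
load_reference_stats <- function(moments_path, correlation_path,
                                 controls = character(0)) {
  moments <- utils::read.csv(moments_path, stringsAsFactors = FALSE)
  needed <- c("feature_id", "stratum", "skewness", "excess_kurtosis",
              "range_min", "range_max", "block_id")
  if (!all(needed %in% names(moments))) {
    stop("moments file must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  raw <- utils::read.csv(correlation_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- raw[[1]]
  corr <- as.matrix(raw[, -1, drop = FALSE])
  rownames(corr) <- ids
  if (nrow(corr) != ncol(corr)) {
    stop("correlation matrix is not square", call. = FALSE)
  }
  if (!identical(ids, colnames(corr))) {
    stop("correlation row and column feature ids disagree", call. = FALSE)
  }
  storage.mode(corr) <- "double"
  if (any(abs(corr) > 1 + 1e-12)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(corr) - 1) > 1e-12)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  strata <- list()
  for (stratum in unique(moments$stratum)) {
    m <- moments[moments$stratum == stratum, , drop = FALSE]
    rownames(m) <- NULL
    if (anyDuplicated(m$feature_id)) {
      stop("duplicated feature_id in moments file for stratum ", stratum,
           call. = FALSE)
    }
    if (!setequal(m$feature_id, ids) || !identical(m$feature_id, ids)) {
      stop("feature ids in moments and correlation files do not match",
           call. = FALSE)
    }
    if (any(m$range_min >= m$range_max)) {
      stop("range_min must be below range_max for every feature",
           call. = FALSE)
    }
    bad <- !vapply(seq_len(nrow(m)), function(i) {
      fleishman_feasible(m$skewness[i], m$excess_kurtosis[i])
    }, logical(1))
    if (any(bad)) {
      stop("Fleishman-infeasible moments for feature(s): ",
           paste(m$feature_id[bad], collapse = ", "), call. = FALSE)
    }
    strata[[stratum]] <- list(moments = m, correlation = corr)
  }
  if (length(controls) > 0 && !all(controls %in% ids)) {
    stop("unknown control feature id(s)", call. = FALSE)
  }
  structure(list(strata = strata, controls = controls),
            class = "reference_stats")
}

#' @exportS3Method base::print
print.reference_stats <- function(x, ...) {
  p <- nrow(x$strata[[1]]$moments)
  cat(sprintf("reference_stats: %d features x %d strata (%s); controls: %s\n",
              p, length(x$strata), paste(names(x$strata), collapse = ", "),
              if (length(x$controls)) paste(x$controls, collapse = ", ")
              else "none"))
  invisible(x)
}
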