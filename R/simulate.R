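#' Prepare a simulator for one stratum
#'
#' Solves the Fleishman system once per distinct (skewness, kurtosis) pair,
#' inverts the Vale-Maurelli cubic for every feature pair to obtain the
#' normal-scale (intermediate) correlation matrix, repairs it to the nearest
#' correlation matrix if indefinite, and pre-factorizes it. The returned
#' object makes repeated cohort draws cheap.
#'
#' @param moments per-feature moments data frame (one stratum), as produced
#'   by [build_reference_stats()].
#' @param corr target correlation matrix on the transformed (outcome) scale.
#' @return a `vm_simulator` object.
#' @export
vm_prepare <- function(moments, corr) {
  ids <- moments$feature_id
  stopifnot(identical(ids, rownames(corr)), identical(ids, colnames(corr)))
  cache <- new.env(parent = emptyenv())
  coefs <- lapply(seq_along(ids), function(i) {
    key <- sprintf("%.12g_%.12g", moments$skewness[i],
                   moments$excess_kurtosis[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- tryCatch(
        solve_fleishman(moments$skewness[i], moments$excess_kurtosis[i]),
        error = function(e) stop("feature ", ids[i], ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    cache[[key]]
  })
  inter <- tryCatch(
    vm_intermediate_matrix(unname(corr), coefs),
    error = function(e) stop("intermediate correlation failed: ",
                             conditionMessage(e), call. = FALSE))
  inter <- nearest_correlation(inter)
  structure(list(feature_id = ids, moments = moments, coefs = coefs,
                 chol = chol(inter)),
            class = "vm_simulator")
}

#' Simulate multivariate non-normal features
#'
#' Draws `n` multivariate-normal vectors with the (repaired) intermediate
#' correlation and pushes each coordinate through its feature's Fleishman
#' polynomial, so that sample correlations, skewness and kurtosis converge to
#' the targets as `n` grows. Deterministic given `seed`.
#'
#' @param moments per-feature moments data frame for one stratum, or a
#'   prepared `vm_simulator` (then `corr` is ignored).
#' @param corr target correlation matrix (outcome scale).
#' @param n number of samples.
#' @param seed integer seed.
#' @return numeric matrix n x features with feature ids as column names.
#'   Values are on the standardized (mean 0, variance 1) scale; see
#'   [rescale_to_range()] for mapping onto feature ranges.
#' @export
simulate_features <- function(moments, corr = NULL, n, seed) {
  prep <- if (inherits(moments, "vm_simulator")) moments
          else vm_prepare(moments, corr)
  stopifnot(n >= 1)
  p <- length(prep$feature_id)
  set.seed(seed)
  z <- matrix(stats::rnorm(n * p), n, p) %*% prep$chol
  y <- matrix(0, n, p, dimnames = list(NULL, prep$feature_id))
  for (j in seq_len(p)) {
    y[, j] <- fleishman_transform(prep$coefs[[j]], z[, j])
  }
  y
}

#' Affine min-max rescaling to a target range
#'
#' Maps the observed minimum to `range_min` and the observed maximum to
#' `range_max`; rank order is preserved exactly.
#'
#' @param values numeric vector.
#' @param range_min,range_max target range, `range_min < range_max`.
#' @return rescaled vector.
#' @export
rescale_to_range <- function(values, range_min, range_max) {
  stopifnot(range_min < range_max)
  lo <- min(values)
  hi <- max(values)
  if (hi - lo <= 0) {
    stop("cannot rescale a constant vector: scale is undefined",
         call. = FALSE)
  }
  range_min + (values - lo) * (range_max - range_min) / (hi - lo)
}
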