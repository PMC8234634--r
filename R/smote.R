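#' SMOTE oversampling of the minority class
#'
#' Synthetic Minority Over-sampling Technique: each synthetic sample is a
#' random convex combination of a minority-class instance and one of its
#' `k_neighbors` minority-class nearest neighbours (Euclidean distance),
#' generated until the two classes have equal counts. Applied to training
#' folds only, never to validation data.
#'
#' @param train_features numeric matrix.
#' @param train_outcome 0/1 vector; the rarer class is oversampled.
#' @param k_neighbors candidate neighbours per instance (default 5); must be
#'   below the minority class size.
#' @param seed integer seed.
#' @return list with `features`, `outcome` and logical `synthetic` flags
#'   (original rows first, in their input order).
#' @export
smote_oversample <- function(train_features, train_outcome, k_neighbors = 5,
                             seed = 1) {
  y <- as.integer(train_outcome)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) {
    stop("SMOTE needs both classes present", call. = FALSE)
  }
  minority <- as.integer(names(counts)[which.min(counts)])
  n_needed <- abs(counts[[1]] - counts[[2]])
  if (n_needed == 0) {
    return(list(features = train_features, outcome = y,
                synthetic = rep(FALSE, length(y))))
  }
  min_idx <- which(y == minority)
  if (length(min_idx) <= k_neighbors) {
    stop("minority class (", length(min_idx), ") must exceed k_neighbors (",
         k_neighbors, "); use a smaller k_neighbors", call. = FALSE)
  }
  xm <- train_features[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) {
    order(row, seq_along(row))[seq_len(k_neighbors)]
  }))
  set.seed(seed)
  base <- sample(seq_along(min_idx), n_needed, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_needed, replace = TRUE))]
  w <- stats::runif(n_needed)
  synth <- xm[base, , drop = FALSE] * (1 - w) + xm[pick, , drop = FALSE] * w
  list(features = rbind(train_features, synth),
       outcome = c(y, rep(minority, n_needed)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_needed)),
       parents = cbind(first = min_idx[base], second = min_idx[pick]))
}
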