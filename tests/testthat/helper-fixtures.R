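# Shared fixtures, built in code at test time.

# Small reference structure for fast simulator/scenario tests
small_reference <- function(n_features = 12, n_blocks = 3, seed = 101,
                            normal_fraction = 0.5) {
  build_reference_stats(n_features = n_features, n_blocks = n_blocks,
                        normal_fraction = normal_fraction, seed = seed)
}

# Separable two-feature toy classification problem
toy_separable <- function(n = 100, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(f1 = rnorm(n, mean = 4 * y), f2 = rnorm(n))
  list(x = x, y = y)
}

# Monte-Carlo skewness/kurtosis of a Fleishman transform. `batches` averages
# independent estimates to cut the estimator's own noise (needed for heavy
# tails, where the kurtosis estimator's variance involves the 8th moment)
# without allocating one huge vector.
mc_moments <- function(coef, n = 1e6, seed = 99, batches = 1) {
  set.seed(seed)
  est <- vapply(seq_len(batches), function(b) {
    y <- fleishman_transform(coef, rnorm(n))
    m <- mean(y)
    s2 <- mean((y - m)^2)
    c(mean((y - m)^3) / s2^1.5, mean((y - m)^4) / s2^2 - 3)
  }, numeric(2))
  c(skew = mean(est[1, ]), kurt = mean(est[2, ]))
}

# Brute-force AUC: mean over all (positive, negative) pairs with half
# credit for ties; the independent oracle for roc_auc
auc_pair_counting <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n1+n0, n1) group assignments; the oracle for Wilcoxon p-values
wilcoxon_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-9)
}
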