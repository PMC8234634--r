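#' Feature-selection methods
#'
#' Six selection settings are benchmarked: no selection, hierarchical
#' clustering followed by a Wilcoxon filter, two PCA-based variable
#' clusterings followed by the same filter, minimum-redundancy
#' maximum-relevance, and ReliefF. All methods are pure functions of the
#' training fold; each returns a `selection_result` with the chosen features
#' ordered best-first by the method's own score.
#'
#' @name feature_selection
NULL

new_selection <- function(method, selected, diagnostics) {
  if (length(selected) == 0) {
    stop("feature selection method '", method,
         "' returned no features", call. = FALSE)
  }
  structure(list(method = method, selected = selected,
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d features (top: %s)\n", x$method,
              length(x$selected),
              paste(utils::head(x$selected, 5), collapse = ", ")))
  invisible(x)
}

# Two-sided Wilcoxon rank-sum p-value per feature. Uses the exact
# distribution when sample sizes permit and there are no ties, otherwise the
# tie-corrected normal approximation; a feature identical in both classes
# (all ties, zero rank variance) gets p = 1.
wilcoxon_pvalues <- function(features, outcome) {
  pos <- outcome == 1
  if (all(pos) || !any(pos)) {
    stop("Wilcoxon filter needs both outcome classes", call. = FALSE)
  }
  apply(features, 2, function(x) {
    p <- suppressWarnings(
      stats::wilcox.test(x[pos], x[!pos], exact = NULL)$p.value)
    if (!is.finite(p)) 1 else p
  })
}

#' Wilcoxon rank-sum filter
#'
#' Keeps features whose two-sided rank-sum p-value is below `alpha`; if none
#' pass, the `k_min` smallest p-values are kept so downstream classifiers
#' always receive a non-empty feature set.
#'
#' @param train_features numeric matrix (training fold).
#' @param train_outcome 0/1 vector.
#' @param alpha significance level (default 0.05).
#' @param k_min fallback number of features when nothing passes (default 5).
#' @return a `selection_result` (method `"WLCX"`), p-values as diagnostics.
#' @export
wilcoxon_filter <- function(train_features, train_outcome, alpha = 0.05,
                            k_min = 5) {
  p <- wilcoxon_pvalues(train_features, train_outcome)
  keep <- which(p < alpha)
  if (length(keep) == 0) {
    keep <- order(p, seq_along(p))[seq_len(min(k_min, length(p)))]
  }
  ord <- keep[order(p[keep], keep)]
  new_selection("WLCX", colnames(train_features)[ord], p)
}

#' Hierarchical-clustering feature selection with Wilcoxon filter
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' 1 - |Spearman correlation|, cut at height `1 - cut`, so features whose
#' absolute rank correlation exceeds `cut` fall in one cluster. Each cluster
#' is represented by its medoid (the member with the largest mean absolute
#' correlation to the other members); representatives then pass through
#' [wilcoxon_filter()].
#'
#' @inheritParams wilcoxon_filter
#' @param cut correlation threshold for the dendrogram cut (default 0.75).
#' @return a `selection_result` (method `"HC+WLCX"`).
#' @export
hc_cluster_select <- function(train_features, train_outcome, cut = 0.75,
                              alpha = 0.05, k_min = 5) {
  p <- ncol(train_features)
  stopifnot(p >= 2)
  rho <- abs(stats::cor(train_features, method = "spearman"))
  rho[!is.finite(rho)] <- 0 # constant features correlate with nothing
  diag(rho) <- 1
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  cluster <- stats::cutree(hc, h = 1 - cut)
  reps <- vapply(split(seq_len(p), cluster), function(members) {
    if (length(members) == 1) return(members)
    strength <- rowMeans(rho[members, members, drop = FALSE])
    members[order(-strength, members)[1]] # medoid, ties by feature order
  }, integer(1))
  res <- wilcoxon_filter(train_features[, sort(reps), drop = FALSE],
                         train_outcome, alpha = alpha, k_min = k_min)
  res$method <- "HC+WLCX"
  res
}

# Number of principal components to retain.
# proportion: smallest K with cumulative explained variance >= threshold.
# delta: the scree ("delta plot") criterion - K is the largest rank whose
# eigenvalue drop to the next component still exceeds the mean drop
# (lambda_1 - lambda_p)/(p - 1), i.e. the point where the scree flattens.
pca_n_components <- function(eigenvalues, criterion, proportion = 0.80) {
  p <- length(eigenvalues)
  if (p == 1) return(1L)
  if (criterion == "proportion") {
    cum <- cumsum(eigenvalues) / sum(eigenvalues)
    return(max(1L, which(cum >= proportion - 1e-12)[1]))
  }
  deltas <- eigenvalues[-p] - eigenvalues[-1]
  mean_delta <- (eigenvalues[1] - eigenvalues[p]) / (p - 1)
  if (mean_delta <= 1e-12) return(1L) # flat spectrum
  above <- which(deltas > mean_delta)
  if (length(above) == 0) 1L else max(above)
}

#' PCA variable-clustering feature selection with Wilcoxon filter
#'
#' PCA on the standardized training features; the number of retained
#' components K is set either by the cumulative explained-variance
#' `proportion` criterion (threshold 0.80) or by the `delta` (scree-drop)
#' criterion. The retained loadings (rotation scaled by component standard
#' deviation) are varimax-rotated so that components align with feature
#' families even when eigenvalues are nearly degenerate; features are then
#' grouped by the component on which they load most strongly, and each
#' group's representative is its highest-loading feature,
#' and representatives pass through [wilcoxon_filter()]. Selection stays in
#' the original feature space so downstream importance and planted-feature
#' recovery remain interpretable.
#'
#' @inheritParams wilcoxon_filter
#' @param criterion `"delta"` or `"proportion"`.
#' @param proportion explained-variance threshold for the proportion
#'   criterion (default 0.80).
#' @return a `selection_result` (method `"PCA(Delta)+WLCX"` or
#'   `"PCA(Proportion)+WLCX"`).
#' @export
pca_cluster_select <- function(train_features, train_outcome,
                               criterion = c("delta", "proportion"),
                               alpha = 0.05, proportion = 0.80, k_min = 5) {
  criterion <- match.arg(criterion)
  stopifnot(ncol(train_features) >= 2, nrow(train_features) > 2)
  keep_cols <- which(apply(train_features, 2, stats::sd) > 0)
  pc <- stats::prcomp(train_features[, keep_cols, drop = FALSE],
                      center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  K <- pca_n_components(eig, criterion, proportion)
  K <- min(K, ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(K), drop = FALSE] *
    rep(pc$sdev[seq_len(K)], each = length(keep_cols))
  if (K >= 2) {
    # varimax resolves the rotational ambiguity of (near-)degenerate
    # eigenvalues so each component aligns with one feature family; a fixed
    # small pre-rotation moves the start off the symmetric saddle point at
    # which the varimax iteration would otherwise stall
    pre <- diag(K)
    for (j in seq_len(K - 1)) {
      g <- diag(K)
      g[j, j] <- g[j + 1, j + 1] <- cos(0.15)
      g[j, j + 1] <- sin(0.15)
      g[j + 1, j] <- -sin(0.15)
      pre <- pre %*% g
    }
    loadings <- stats::varimax(loadings %*% pre)$loadings
  }
  loadings <- abs(loadings)
  assigned <- max.col(loadings, ties.method = "first")
  reps <- integer(0)
  for (comp in sort(unique(assigned))) {
    members <- which(assigned == comp)
    best <- members[order(-loadings[members, comp], members)[1]]
    reps <- c(reps, keep_cols[best])
  }
  res <- wilcoxon_filter(train_features[, sort(reps), drop = FALSE],
                         train_outcome, alpha = alpha, k_min = k_min)
  res$method <- if (criterion == "delta") "PCA(Delta)+WLCX"
                else "PCA(Proportion)+WLCX"
  res
}

# Mutual information (nats) between two discrete codes
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  pj <- tab / sum(tab)
  px <- rowSums(pj)
  py <- colSums(pj)
  ind <- outer(px, py)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / ind[nz]))
}

# Equal-frequency discretization into n_bins codes
ef_discretize <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  if (length(br) < 2) return(rep(1L, length(x))) # constant feature
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy forward selection under the mutual-information difference (MID)
#' scheme: at each step pick the feature maximizing
#' I(f; y) - mean over selected s of I(f; s). Features are discretized into
#' `n_bins` equal-frequency bins for mutual-information estimation; ties are
#' broken by feature order.
#'
#' @inheritParams wilcoxon_filter
#' @param m number of features to select (default 20; capped at p with a
#'   warning).
#' @param n_bins equal-frequency bins for discretization (default 3).
#' @return a `selection_result` (method `"MRMR"`), MID scores (in pick
#'   order) as diagnostics.
#' @export
mrmr_select <- function(train_features, train_outcome, m = 20, n_bins = 3) {
  stopifnot(m >= 1)
  p <- ncol(train_features)
  if (m > p) {
    warning("m exceeds the number of features; returning all ", p)
    m <- p
  }
  disc <- apply(train_features, 2, ef_discretize, n_bins = n_bins)
  relevance <- apply(disc, 2, discrete_mi, y = train_outcome)
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p) # running sum of I(f; s) over selected s
  for (step in seq_len(m)) {
    crit <- if (length(selected) == 0) relevance
            else relevance - red_sum / length(selected)
    crit[selected] <- -Inf
    pick <- order(-crit, seq_len(p))[1]
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    if (step < m) {
      rest <- setdiff(seq_len(p), selected)
      red_sum[rest] <- red_sum[rest] + vapply(rest, function(j) {
        discrete_mi(disc[, j], disc[, pick])
      }, numeric(1))
    }
  }
  new_selection("MRMR", colnames(train_features)[selected],
                stats::setNames(scores, colnames(train_features)[selected]))
}

#' ReliefF feature weighting
#'
#' Instance-based weighting: features are scaled to [0, 1] on the training
#' fold, and for every training instance the `k_neighbors` nearest same-class
#' (hits) and other-class (misses) neighbours (Manhattan distance) pull each
#' feature's weight down and up by the mean absolute feature difference,
#' respectively. All training instances are used. A constant feature has
#' weight exactly 0.
#'
#' @inheritParams wilcoxon_filter
#' @param k_neighbors nearest hits/misses per instance (default 10).
#' @param m number of top-weight features returned (default 20).
#' @return a `selection_result` (method `"RELF"`), weights as diagnostics.
#' @export
relieff_select <- function(train_features, train_outcome, k_neighbors = 10,
                           m = 20) {
  n <- nrow(train_features)
  p <- ncol(train_features)
  if (min(table(factor(train_outcome, levels = c(0, 1)))) <= k_neighbors) {
    stop("both classes must have more than k_neighbors members; ",
         "use a smaller k_neighbors", call. = FALSE)
  }
  rng <- apply(train_features, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1 # constant features contribute zero diffs anyway
  x <- sweep(sweep(train_features, 2, rng[1, ], "-"), 2, span, "/")
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  diag(d) <- Inf
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(train_outcome == train_outcome[i])
    same <- same[same != i]
    other <- which(train_outcome != train_outcome[i])
    hits <- same[order(d[i, same], same)][seq_len(k_neighbors)]
    misses <- other[order(d[i, other], other)][seq_len(k_neighbors)]
    diff_hit <- colMeans(abs(x[hits, , drop = FALSE] -
                               rep(x[i, ], each = k_neighbors)))
    diff_miss <- colMeans(abs(x[misses, , drop = FALSE] -
                                rep(x[i, ], each = k_neighbors)))
    w <- w + (diff_miss - diff_hit) / n
  }
  names(w) <- colnames(train_features)
  m <- min(m, p)
  ord <- order(-w, seq_len(p))[seq_len(m)]
  new_selection("RELF", colnames(train_features)[ord], w)
}

#' Apply one of the benchmark's selection settings
#'
#' Dispatcher over the six settings of the benchmark; `"none"` returns all
#' features in their original order.
#'
#' @inheritParams wilcoxon_filter
#' @param method one of `"none"`, `"HC+WLCX"`, `"PCA(Delta)+WLCX"`,
#'   `"PCA(Proportion)+WLCX"`, `"MRMR"`, `"RELF"`.
#' @param control list of hyperparameters overriding the per-method defaults
#'   (`alpha`, `k_min`, `cut`, `proportion`, `mrmr_m`, `n_bins`,
#'   `relieff_k`, `relieff_m`).
#' @return a `selection_result`.
#' @export
select_features <- function(method, train_features, train_outcome,
                            control = list()) {
  ctl <- utils::modifyList(list(alpha = 0.05, k_min = 5, cut = 0.75,
                                proportion = 0.80, mrmr_m = 20, n_bins = 3,
                                relieff_k = 10, relieff_m = 20), control)
  switch(method,
    "none" = new_selection("none", colnames(train_features),
                           diagnostics = NULL),
    "HC+WLCX" = hc_cluster_select(train_features, train_outcome,
                                  cut = ctl$cut, alpha = ctl$alpha,
                                  k_min = ctl$k_min),
    "PCA(Delta)+WLCX" = pca_cluster_select(train_features, train_outcome,
                                           criterion = "delta",
                                           alpha = ctl$alpha,
                                           proportion = ctl$proportion,
                                           k_min = ctl$k_min),
    "PCA(Proportion)+WLCX" = pca_cluster_select(train_features,
                                                train_outcome,
                                                criterion = "proportion",
                                                alpha = ctl$alpha,
                                                proportion = ctl$proportion,
                                                k_min = ctl$k_min),
    "MRMR" = mrmr_select(train_features, train_outcome, m = ctl$mrmr_m,
                         n_bins = ctl$n_bins),
    "RELF" = relieff_select(train_features, train_outcome,
                            k_neighbors = ctl$relieff_k, m = ctl$relieff_m),
    stop("unknown feature selection method: ", method, call. = FALSE))
}

#' All feature-selection method names
#' @return character vector of the six settings.
#' @export
fs_methods <- function() {
  c("none", "HC+WLCX", "PCA(Delta)+WLCX", "PCA(Proportion)+WLCX",
    "MRMR", "RELF")
}
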