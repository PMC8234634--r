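make_xy <- function(n = 60, p = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("F%03d", 1:p)))
  list(x = x, y = rep(c(0L, 1L), length.out = n))
}

test_that("Wilcoxon p-values match exact enumeration and handle ties", {
  # 3-vs-3 complete separation: exact two-sided p = 0.1
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(1, 1, 1, 0, 0, 0)
  p <- radbench:::wilcoxon_pvalues(x, y)
  expect_equal(unname(p), 0.1, tolerance = 1e-12)
  expect_equal(unname(p), wilcoxon_exact_enum(x[y == 1, 1], x[y == 0, 1]),
               tolerance = 1e-12)
  # random small instances against the enumeration oracle
  set.seed(8)
  for (i in 1:10) {
    v <- matrix(rnorm(8), ncol = 1, dimnames = list(NULL, "f"))
    yy <- sample(rep(0:1, 4))
    expect_equal(unname(radbench:::wilcoxon_pvalues(v, yy)),
                 wilcoxon_exact_enum(v[yy == 1, 1], v[yy == 0, 1]),
                 tolerance = 1e-12)
  }
  # all-ties feature: p = 1, never selected at any alpha
  d <- make_xy(seed = 3)
  d$x[, 2] <- 5
  p <- radbench:::wilcoxon_pvalues(d$x, d$y)
  expect_equal(unname(p[2]), 1)
})

test_that("Wilcoxon filter is monotone in alpha and has a non-empty fallback", {
  d <- make_xy(n = 80, p = 10, seed = 4)
  s01 <- wilcoxon_filter(d$x, d$y, alpha = 0.01)
  s10 <- wilcoxon_filter(d$x, d$y, alpha = 0.10)
  passed01 <- names(which(s01$diagnostics < 0.01))
  passed10 <- names(which(s10$diagnostics < 0.10))
  expect_true(all(passed01 %in% passed10))
  # pure-noise features: fallback keeps exactly k_min smallest p-values
  expect_length(wilcoxon_filter(d$x, d$y, alpha = 1e-12)$selected, 5)
  expect_error(wilcoxon_filter(d$x, rep(1, 80)), "both")
})

test_that("null features are selected at about the nominal alpha rate", {
  set.seed(10)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 1000), n, 1000,
              dimnames = list(NULL, sprintf("N%04d", 1:1000)))
  p <- radbench:::wilcoxon_pvalues(x, y)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("hierarchical clustering merges duplicates and keeps the medoid", {
  set.seed(12)
  n <- 400
  y <- rep(0:1, each = n / 2)
  z <- rnorm(n)
  x <- cbind(hub = z + rnorm(n, sd = 0.15),  # correlates best with both
             twin = z + rnorm(n, sd = 0.3),
             far = z + rnorm(n, sd = 0.45),
             indep1 = rnorm(n), indep2 = rnorm(n))
  # duplicated feature pair collapses to one representative
  dup <- cbind(a = z, b = z, other = rnorm(n))
  sel <- hc_cluster_select(dup, y, alpha = 1) # alpha 1: keep all reps
  expect_length(intersect(c("a", "b"), sel$selected), 1)
  # medoid of the correlated triple is the hub feature
  sel2 <- hc_cluster_select(x, y, cut = 0.5, alpha = 1)
  expect_true("hub" %in% sel2$selected)
  expect_false(any(c("twin", "far") %in% sel2$selected))
  # independent features survive as singletons
  expect_true(all(c("indep1", "indep2") %in% sel2$selected))
})

test_that("PCA component counts follow the stated stop criteria", {
  # isotropic noise, p = 10: cumulative proportion is k/10, so K = 8
  expect_equal(radbench:::pca_n_components(rep(1, 10), "proportion", 0.80),
               8L)
  # two duplicated blocks: eigenvalues (2, 2, 0, 0) -> K = 2 either way
  expect_equal(radbench:::pca_n_components(c(2, 2, 0, 0), "delta"), 2L)
  expect_equal(radbench:::pca_n_components(c(2, 2, 0, 0), "proportion",
                                           0.80), 2L)
  expect_equal(radbench:::pca_n_components(5, "delta"), 1L)
})

test_that("PCA clustering separates independent blocks of duplicates", {
  set.seed(14)
  n <- 300
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  # outcome depends on both latent factors so each representative passes
  # the downstream Wilcoxon filter
  y <- as.integer(z1 + z2 + rnorm(n, sd = 0.5) > 0)
  x <- cbind(a1 = z1, a2 = z1 + rnorm(n, sd = 0.01),
             b1 = z2, b2 = z2 + rnorm(n, sd = 0.01))
  for (crit in c("delta", "proportion")) {
    sel <- pca_cluster_select(x, y, criterion = crit)
    expect_length(sel$selected, 2)
    expect_length(intersect(c("a1", "a2"), sel$selected), 1)
    expect_length(intersect(c("b1", "b2"), sel$selected), 1)
  }
})

test_that("MRMR picks by relevance first and penalizes redundancy", {
  set.seed(15)
  n <- 600
  y <- rep(0:1, each = n / 2)
  strong <- y + rnorm(n, sd = 0.4)
  weak <- y + rnorm(n, sd = 2)
  x <- cbind(strong = strong, copy = strong, weak = weak, noise = rnorm(n))
  sel <- mrmr_select(x, y, m = 3)
  expect_equal(sel$selected[1], "strong") # max relevance first
  expect_false(sel$selected[2] == "copy") # duplicate never second
  expect_warning(out <- mrmr_select(x, y, m = 10), "exceeds")
  expect_length(out$selected, 4)
  # outcome independent of features: ties broken by feature order
  set.seed(16)
  xn <- matrix(rep(rnorm(n), 3), n, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(mrmr_select(xn, y, m = 1)$selected, "A")
})

test_that("ReliefF weights rank a perfect indicator above noise", {
  set.seed(17)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- cbind(ind = y + rnorm(n, sd = 0.05),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
             const = rep(1, n))
  sel <- relieff_select(x, y, k_neighbors = 10, m = 5)
  w <- sel$diagnostics
  expect_equal(sel$selected[1], "ind")
  expect_gt(w[["ind"]], max(w[c("n1", "n2", "n3")]))
  expect_equal(w[["const"]], 0)
  # two identical features receive identical weights
  x2 <- cbind(a = x[, "ind"], b = x[, "ind"], c = x[, "n1"])
  w2 <- relieff_select(x2, y, k_neighbors = 5, m = 3)$diagnostics
  expect_equal(w2[["a"]], w2[["b"]])
  expect_error(relieff_select(x, y, k_neighbors = 150), "k_neighbors")
})

test_that("selection is a deterministic pure function of the training fold", {
  d <- make_xy(n = 120, p = 12, seed = 18)
  ctl <- list(mrmr_m = 6, relieff_m = 6)
  for (m in fs_methods()[-1]) {
    s1 <- select_features(m, d$x, d$y, control = ctl)
    s2 <- select_features(m, d$x, d$y, control = ctl)
    expect_identical(s1$selected, s2$selected)
  }
})

test_that("clustering selections retain a planted control at high signal", {
  ref <- build_reference_stats(seed = derive_seed(1, "reference"))
  preps <- lapply(ref$strata, function(s) {
    vm_prepare(s$moments, s$correlation)
  })
  methods <- c("HC+WLCX", "PCA(Delta)+WLCX", "PCA(Proportion)+WLCX")
  hits <- matrix(0, nrow = 20, ncol = length(methods),
                 dimnames = list(NULL, methods))
  for (r in 1:20) {
    seed_r <- derive_seed(900, paste0("retention/", r))
    spec <- scenario_spec(600, "balanced", "high", ref$controls)
    ch <- build_full_scenario(ref, spec, seed_r, preps = preps)
    ch <- split_train_validation(ch, derive_seed(seed_r, "split"))
    x <- ch$features[ch$split$train, ]
    y <- ch$outcome[ch$split$train]
    for (m in methods) {
      sel <- select_features(m, x, y)
      hits[r, m] <- any(ref$controls %in% sel$selected)
    }
  }
  for (m in methods) {
    expect_gte(mean(hits[, m]), 0.95)
  }
})
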