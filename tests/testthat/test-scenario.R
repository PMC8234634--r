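test_that("design counts reproduce every cell of the published table", {
  expect_equal(unname(design_counts(600, "balanced")),
               matrix(c(200L, 100L, 200L, 100L), 2))
  expect_equal(unname(design_counts(300, "balanced")),
               matrix(c(100L, 50L, 100L, 50L), 2))
  expect_equal(unname(design_counts(100, "balanced")),
               matrix(c(34L, 16L, 33L, 17L), 2))
  expect_equal(unname(design_counts(600, "unbalanced")),
               matrix(c(280L, 140L, 120L, 60L), 2))
  expect_equal(unname(design_counts(300, "unbalanced")),
               matrix(c(140L, 70L, 60L, 30L), 2))
  expect_equal(unname(design_counts(100, "unbalanced")),
               matrix(c(47L, 23L, 20L, 10L), 2))
})

test_that("outcome assignment hits exact class counts", {
  y <- assign_outcome(600, "balanced", seed = 1)
  expect_equal(sum(y), 300)
  y <- assign_outcome(100, "unbalanced", seed = 1)
  expect_equal(sum(y), 30)
  expect_equal(sort(assign_outcome(2, "balanced", seed = 1)), c(0L, 1L))
  expect_identical(assign_outcome(50, "balanced", 9),
                   assign_outcome(50, "balanced", 9))
})

test_that("signal injection shifts only the positive class of the controls", {
  ref <- small_reference(seed = 21)
  spec0 <- scenario_spec(600, "balanced", "high", ref$controls,
                         shifts = c(0, 0, 0))
  ch0 <- build_full_scenario(ref, spec0, seed = 31)
  spec2 <- scenario_spec(600, "balanced", "high", ref$controls)
  ch2 <- build_full_scenario(ref, spec2, seed = 31)
  neg <- ch0$outcome == 0
  # zero shift leaves everything bitwise identical
  expect_identical(inject_signal(ch0, spec0)$features, ch0$features)
  # negative class and non-control features identical across shift settings
  expect_identical(ch2$features[neg, ], ch0$features[neg, ])
  non_ctrl <- setdiff(colnames(ch0$features), ref$controls)
  expect_identical(ch2$features[, non_ctrl], ch0$features[, non_ctrl])
  expect_error(inject_signal(ch0, scenario_spec(600, "balanced", "high",
                                                c("nope", "F002", "F003"))),
               "unknown control")
})

test_that("injected standardized mean differences match the shift sizes", {
  ref <- small_reference(seed = 22)
  spec <- scenario_spec(10000, "balanced", "high", ref$controls)
  ch <- build_full_scenario(ref, spec, seed = 8, n_total = 10000)
  pos <- ch$outcome == 1
  for (k in ref$controls) {
    x <- ch$features[, k]
    d <- (mean(x[pos]) - mean(x[!pos])) /
      sqrt((var(x[pos]) + var(x[!pos])) / 2)
    expect_lt(abs(d - 2), 0.1)
  }
  # non-control features carry no injected signal
  other <- setdiff(colnames(ch$features), ref$controls)[1]
  x <- ch$features[, other]
  d <- (mean(x[pos]) - mean(x[!pos])) /
    sqrt((var(x[pos]) + var(x[!pos])) / 2)
  expect_lt(abs(d), 0.05)
})

test_that("full scenarios satisfy the per-stratum class counts exactly", {
  ref <- small_reference(seed = 23)
  for (bal in c("balanced", "unbalanced")) {
    spec <- scenario_spec(600, bal, "high", ref$controls)
    ch <- build_full_scenario(ref, spec, seed = 41)
    tab <- table(factor(ch$stratum, c("FBP", "IR")),
                 factor(ch$outcome, 0:1))
    expect_equal(unname(unclass(tab)), unname(design_counts(600, bal)),
                 ignore_attr = TRUE)
    ch2 <- build_full_scenario(ref, spec, seed = 41)
    expect_identical(ch$features, ch2$features)
    expect_identical(ch$outcome, ch2$outcome)
  }
})

test_that("train/validation split is stratified and conserves totals", {
  ref <- small_reference(seed = 24)
  spec <- scenario_spec(600, "balanced", "low", ref$controls)
  ch <- build_full_scenario(ref, spec, seed = 51)
  ch <- split_train_validation(ch, seed = 52)
  expect_length(ch$split$train, 400)
  expect_length(ch$split$validation, 200)
  expect_setequal(c(ch$split$train, ch$split$validation), 1:600)
  # per-cell proportions preserved within rounding
  for (s in c("FBP", "IR")) {
    for (cl in 0:1) {
      cell <- which(ch$stratum == s & ch$outcome == cl)
      n_tr <- length(intersect(cell, ch$split$train))
      expect_lt(abs(n_tr - 2 / 3 * length(cell)), 1)
    }
  }
  sub3 <- subsample(ch, 300, seed = 53)
  expect_length(sub3$split$train, 200)
  sub1 <- subsample(sub3, 100, seed = 54)
  expect_length(sub1$split$train, 67)
  expect_length(sub1$split$validation, 33)
})

test_that("subsampling hits the design counts, nests, and checks its bounds", {
  ref <- small_reference(seed = 25)
  suite <- build_scenario_suite(ref, seed = 61)
  expect_length(suite, 12)
  for (nm in names(suite)) {
    parts <- strsplit(nm, "_")[[1]]
    ch <- suite[[nm]]
    tab <- table(factor(ch$stratum, c("FBP", "IR")),
                 factor(ch$outcome, 0:1))
    expect_equal(unname(unclass(tab)),
                 unname(design_counts(as.integer(parts[1]), parts[2])),
                 ignore_attr = TRUE)
  }
  # nested membership, separately in train and validation
  big <- suite[["300_unbalanced_low"]]
  small <- suite[["100_unbalanced_low"]]
  expect_true(all(small$sample_id %in% big$sample_id))
  expect_true(all(small$sample_id[small$split$train] %in%
                    big$sample_id[big$split$train]))
  expect_true(all(small$sample_id[small$split$validation] %in%
                    big$sample_id[big$split$validation]))
  expect_error(subsample(small, 200, seed = 1), "exceeds")
  # size = n keeps every member
  same <- subsample(big, 300, seed = 2)
  expect_setequal(same$sample_id, big$sample_id)
})

test_that("cohorts round-trip through their file format", {
  ref <- small_reference(seed = 26)
  spec <- scenario_spec(100, "unbalanced", "low", ref$controls)
  ch <- build_full_scenario(ref, spec, seed = 71, n_total = 100)
  path <- tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- load_cohort(path, spec = spec)
  expect_equal(back$features, ch$features, tolerance = 1e-12)
  expect_identical(back$outcome, ch$outcome)
  expect_identical(back$stratum, ch$stratum)
  unlink(path)
})
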