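test_that("correlation template is exact, symmetric with unit diagonal", {
  # 4 features, 2 blocks, no detached controls
  ref <- build_reference_stats(n_features = 4, n_blocks = 2, seed = 1,
                               n_controls = 0)
  corr <- ref$strata$FBP$correlation
  tmpl <- matrix(0.1, 4, 4)
  tmpl[1:2, 1:2] <- 0.7
  tmpl[3:4, 3:4] <- 0.7
  diag(tmpl) <- 1
  expect_equal(unname(corr), tmpl)
  for (nf in c(5, 9)) {
    r <- build_reference_stats(n_features = nf, n_blocks = 3, seed = 2)
    co <- r$strata$IR$correlation
    expect_identical(unname(co), unname(t(co)))
    expect_identical(unname(diag(co)), rep(1, nf))
  }
})

test_that("about a third of the 168 features per stratum are normal", {
  ref <- build_reference_stats(seed = 5)
  for (s in c("FBP", "IR")) {
    m <- ref$strata[[s]]$moments
    expect_equal(nrow(m), 168)
    frac <- mean(m$skewness == 0 & m$excess_kurtosis == 0)
    expect_equal(frac, round(0.32 * 168) / 168, tolerance = 1e-12)
    expect_lt(abs(frac - 0.32), 0.1)
  }
})

test_that("every emitted moment pair is Fleishman-feasible", {
  ref <- small_reference(n_features = 20, n_blocks = 4, seed = 9,
                         normal_fraction = 0.2)
  m <- ref$strata$FBP$moments
  ok <- vapply(seq_len(nrow(m)), function(i) {
    fleishman_feasible(m$skewness[i], m$excess_kurtosis[i])
  }, logical(1))
  expect_true(all(ok))
  nn <- m$skewness != 0
  expect_true(all(m$skewness[nn] >= 0.5 & m$skewness[nn] <= 3))
})

test_that("degenerate single-feature structure is handled", {
  ref <- build_reference_stats(n_features = 1, n_blocks = 1,
                               normal_fraction = 1, seed = 1)
  m <- ref$strata$FBP$moments
  expect_equal(m$skewness, 0)
  expect_equal(m$excess_kurtosis, 0)
  expect_equal(unname(ref$strata$FBP$correlation), matrix(1, 1, 1))
  expect_length(ref$controls, 0)
})

test_that("controls sit in three distinct blocks, weakly coupled", {
  ref <- build_reference_stats(seed = 3)
  expect_length(ref$controls, 3)
  m <- ref$strata$FBP$moments
  blocks <- m$block_id[match(ref$controls, m$feature_id)]
  expect_length(unique(blocks), 3)
  corr <- ref$strata$FBP$correlation
  off <- corr[ref$controls, setdiff(m$feature_id, ref$controls)]
  expect_true(all(abs(off) <= 0.1 + 1e-12))
})

test_that("reference stats round-trip through their file format", {
  ref <- small_reference(seed = 13)
  mp <- tempfile(fileext = ".csv")
  cp <- tempfile(fileext = ".csv")
  write_reference_stats(ref, mp, cp)
  back <- load_reference_stats(mp, cp, controls = ref$controls)
  for (s in c("FBP", "IR")) {
    expect_equal(back$strata[[s]]$moments, ref$strata[[s]]$moments,
                 tolerance = 1e-12)
    expect_equal(back$strata[[s]]$correlation, ref$strata[[s]]$correlation,
                 tolerance = 1e-12)
  }
  expect_identical(back$controls, ref$controls)
  unlink(c(mp, cp))
})

test_that("malformed reference files are rejected with clear errors", {
  ref <- small_reference(seed = 13)
  mp <- tempfile(fileext = ".csv")
  cp <- tempfile(fileext = ".csv")
  write_reference_stats(ref, mp, cp)
  # correlation out of range
  raw <- read.csv(cp, check.names = FALSE)
  raw[2, 3] <- 1.2
  raw[3, 2] <- 1.2
  bad_cp <- tempfile(fileext = ".csv")
  write.csv(raw, bad_cp, row.names = FALSE, quote = FALSE)
  expect_error(load_reference_stats(mp, bad_cp), "\\[-1, 1\\]")
  # duplicated feature id in the moments table
  mom <- read.csv(mp)
  mom$feature_id[2] <- mom$feature_id[1]
  bad_mp <- tempfile(fileext = ".csv")
  write.csv(mom, bad_mp, row.names = FALSE, quote = FALSE)
  expect_error(load_reference_stats(bad_mp, cp), "duplicated|match")
  unlink(c(mp, cp, bad_cp, bad_mp))
})
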