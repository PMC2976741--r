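test_that("pulse pressure and relative cardiac output derive with missing propagation", {
  six <- derive_series(list(hr = c(60, 70, NA), sbp = c(120, 130, 118),
                            dbp = c(80, NA, 75), map = c(93, 90, 89)))
  expect_equal(six$pp, c(40, NA, 43))
  expect_equal(six$co, c(2400, NA, NA))
  expect_length(six, 6)
})

test_that("statistical features use the documented conventions", {
  f <- statistical_features(rep(3.5, 30))
  expect_equal(unname(f), c(3.5, 3.5, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(statistical_features(0:29)["slope"]), 1)
  f2 <- statistical_features(c(1, 2, 3, 4))
  expect_equal(unname(f2["mean"]), 2.5)
  expect_equal(unname(f2["var"]), 1.25)   # population convention
  expect_equal(unname(f2["iqr"]), 1.5)    # type-7 interpolated quantiles
  expect_error(statistical_features(c(1, rep(NA, 29))), "2 non-missing")
})

test_that("statistical features agree with a direct-formula oracle", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(30, 80, 10)
    if (i %% 3 == 0) x[sample(30, 2)] <- NA
    expect_equal(statistical_features(x), naive_stats(x), tolerance = 1e-10)
  }
})

test_that("zero-lag cross-correlation is the raw uncentered mean product", {
  mk <- function(x, y) {
    s <- list(hr = x, sbp = y, dbp = y, map = x)
    derive_series(s)
  }
  ones <- mk(rep(1, 10), rep(1, 10))
  expect_equal(unname(cross_correlation_features(ones)["xcorr_hr_map"]), 1)
  two <- mk(c(1, 2), c(2, 1))
  expect_equal(unname(cross_correlation_features(two)["xcorr_hr_sbp"]), 2)
  # symmetry and scaling over random series
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(30); b <- rnorm(30)
    s1 <- mk(a, b); s2 <- mk(b, a)
    expect_equal(cross_correlation_features(s1)[["xcorr_hr_sbp"]],
                 cross_correlation_features(s2)[["xcorr_hr_sbp"]])
    s3 <- mk(3 * a, b)
    expect_equal(cross_correlation_features(s3)[["xcorr_hr_sbp"]],
                 3 * cross_correlation_features(s1)[["xcorr_hr_sbp"]])
  }
})

test_that("wavelet relative energies match the reference decomposition", {
  # frozen from an independent reference DWT (dmey, symmetric extension)
  x <- sin(2 * pi * (0:29) / 7) + 0.1 * (0:29)
  ref <- c(a5 = 0.811230679000855, d5 = 0.167275191561872,
           d4 = 0.000878634921094515, d3 = 0.00487448980893943,
           d2 = 0.0157178271365539, d1 = 2.31775706857499e-05)
  got <- wavelet_features(x)
  expect_equal(got[c("a5", "d5", "d4", "d3", "d2", "d1")], ref,
               tolerance = 1e-12)
  # approximation coefficients, first level, same reference
  w1 <- dwt_dmey(x, 1)
  expect_equal(w1$a[1:4],
               c(5.17982918848123, 2.70049783157355, 2.93369848208326,
                 4.62743136663124), tolerance = 1e-12)
})

test_that("wavelet energy distributes as expected for degenerate signals", {
  const <- wavelet_features(rep(5, 30))
  expect_gt(const["a5"], 0.999)
  alt <- wavelet_features(rep(c(1, -1), 15))
  expect_equal(names(which.max(alt)), "d1")
  set.seed(12)
  for (i in 1:10) {
    e <- wavelet_features(rnorm(30, 80, 5))
    expect_true(all(e >= 0))
    expect_equal(sum(e), 1, tolerance = 1e-9)
  }
  expect_error(wavelet_features(rep(0, 30)), "zero total")
})

test_that("clinical features sum doses inside the half-open observation window", {
  meds <- data.frame(minute = c(100, 110, 130, 131),
                     drug = c("dopamine", "lasix", "dobutamine", "lasix"),
                     dose_mcg_per_kg = c(5, 3, 2, 9))
  rec <- hemodynamic_record("m", hr = rep(80, 300), sbp = rep(120, 300),
                            dbp = rep(70, 300), map = rep(87, 300),
                            age = 71, medications = meds)
  ex <- list(obs_start = 100L, spec = window_spec(30, 60))
  cf <- clinical_features(rec, ex)
  # window [100, 130): dopamine 5 raising, lasix 3 lowering; minute 130/131 out
  expect_equal(unname(cf), c(71, 5, 3))
  rec0 <- flat_record(300)
  expect_equal(unname(clinical_features(rec0, ex)), c(60, 0, 0))
})

test_that("feature vectors have 102 stably named entries and the bulk path agrees", {
  expect_length(feature_names(), 102)
  expect_equal(48 + 15 + 36 + 3, 102)
  recs <- cached_cohort("strong", n_records = 4, seed = 55)
  comp <- compile_cohort(recs, window_spec(30, 60), "multiple")
  idx <- seq(1, min(25, length(comp$examples)))
  fm <- feature_matrix(comp$examples[idx], recs)
  expect_equal(colnames(fm), feature_names())
  for (i in idx) {
    ex <- comp$examples[[i]]
    fv <- extract_features(ex, recs[[ex$record_id]])
    expect_length(fv, 102)
    expect_equal(unname(fm[i, ]), unname(fv), tolerance = 1e-10)
    # determinism
    expect_identical(fv, extract_features(ex, recs[[ex$record_id]]))
  }
})
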