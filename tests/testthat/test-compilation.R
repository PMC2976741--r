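test_that("target-window labeling follows the printed definition with its boundary strictness", {
  expect_equal(label_target_window(rep(55, 30)), "hypotensive")
  # 26/30 = 0.867 < 0.90 fails the episode rule; all 30 in (10,200) -> control
  expect_equal(label_target_window(c(rep(55, 26), rep(70, 4))), "control")
  # 27/30 = 0.90 meets "at least 90%"
  expect_equal(label_target_window(c(rep(55, 27), rep(70, 3))), "hypotensive")
  # 25/30 = 0.833 not > 0.90 -> excluded
  expect_equal(label_target_window(c(rep(80, 25), rep(250, 5))), "excluded")
  # missing minutes count against both fractions
  expect_equal(label_target_window(c(rep(55, 27), rep(NA, 3))), "hypotensive")
  expect_equal(label_target_window(c(rep(80, 27), rep(NA, 3))), "excluded")
  expect_error(label_target_window(rep(55, 29)), "30 minutes")
})

test_that("observation validity needs every series in bounds for more than 95%", {
  mk <- function(map) list(hr = rep(80, length(map)), sbp = rep(120, length(map)),
                           dbp = rep(70, length(map)), map = map)
  expect_true(check_observation_validity(mk(rep(85, 30))))
  # 28/30 = 0.933 <= 0.95
  expect_false(check_observation_validity(mk(c(rep(85, 28), NA, NA))))
  # 58/60 = 0.967 > 0.95
  expect_true(check_observation_validity(mk(c(rep(85, 58), 250, NA))))
  expect_error(check_observation_validity(
    list(hr = rep(80, 30), sbp = rep(120, 30), dbp = rep(70, 29),
         map = rep(85, 30))), "length")
})

test_that("multiple compilation tiles non-overlapping targets from minute 0", {
  rec <- flat_record(600)
  ex <- compile_multiple(rec, window_spec(30, 60))
  expect_length(ex, 17)
  starts <- vapply(ex, function(e) e$target_start, integer(1))
  expect_equal(starts, seq(90L, 570L, by = 30L))
  # no two examples share a target minute
  mins <- unlist(lapply(starts, function(s) s:(s + 29)))
  expect_false(anyDuplicated(mins) > 0)
  # short records yield nothing
  expect_length(compile_multiple(flat_record(119), window_spec(30, 60)), 0)
})

test_that("stored labels and medians are consistent with relabeling the target slice", {
  recs <- cached_cohort("strong", n_records = 6, seed = 21)
  for (rec in recs) {
    for (ex in compile_multiple(rec, window_spec(30, 60))) {
      seg <- rec$map[(ex$target_start + 1):(ex$target_start + 30)]
      expect_equal(ex$label, label_target_window(seg))
      expect_equal(ex$target_median_map, median(seg[!is.na(seg)]))
    }
  }
})

test_that("an exhaustive scan oracle reproduces compile_multiple on short records", {
  cfg <- sim_config(n_records = 4, duration_minutes = 290,
                    duration_spread = 0.03, episode_rate = 2,
                    missing_rate = 0.05, artifact_rate = 0.02, seed = 77)
  spec <- window_spec(30, 60)
  for (i in 1:4) {
    rec <- simulate_record(cfg, i)
    n <- record_length(rec)
    oracle <- list()
    for (s in seq(0, n - 30, by = 30)) {
      if (s < spec$gap + spec$obs) next
      oi <- (s - spec$gap - spec$obs + 1):(s - spec$gap)
      frac_ok <- function(x) {
        sum(!is.na(x) & x > 10 & x < 200) / spec$obs
      }
      if (!(frac_ok(rec$hr[oi]) > 0.95 && frac_ok(rec$sbp[oi]) > 0.95 &&
              frac_ok(rec$dbp[oi]) > 0.95 && frac_ok(rec$map[oi]) > 0.95)) next
      lab <- brute_label(rec$map[(s + 1):(s + 30)])
      if (lab == "excluded") next
      oracle[[length(oracle) + 1]] <- list(start = s, label = lab)
    }
    got <- compile_multiple(rec, spec)
    expect_equal(vapply(got, function(e) e$target_start, integer(1)),
                 vapply(oracle, function(e) as.integer(e$start), integer(1)))
    expect_equal(vapply(got, function(e) e$label, character(1)),
                 vapply(oracle, function(e) e$label, character(1)))
  }
})

test_that("records containing a generated episode yield a hypotensive example", {
  # dropouts disabled: a missing block in the only candidate observation
  # window could legitimately invalidate an episode's examples
  cfg <- fixture_cohort_config("strong", n_records = 15, seed = 99)
  cfg$missing_rate <- 0
  cfg$artifact_rate <- 0
  recs <- simulate_cohort(cfg)
  log <- attr(recs, "episode_log")
  with_ep <- unique(log$record_id[log$onset >= 90])
  expect_gt(length(with_ep), 0)
  for (id in with_ep) {
    labs <- vapply(compile_multiple(recs[[id]], window_spec(30, 60)),
                   function(e) e$label, character(1))
    expect_true(any(labs == "hypotensive"), label = id)
  }
})

test_that("single compilation is hypotensive-first, seeded, and a subset of multiple", {
  recs <- cached_cohort("strong", n_records = 20, seed = 88)
  spec <- window_spec(30, 60)
  for (rec in recs) {
    all_ex <- compile_multiple(rec, spec)
    one <- compile_single(rec, spec, seed = 13)
    if (length(all_ex) == 0) {
      expect_null(one)
      next
    }
    labs <- vapply(all_ex, function(e) e$label, character(1))
    if (any(labs == "hypotensive")) {
      expect_equal(one$label, "hypotensive")
    } else {
      expect_equal(one$label, "control")
    }
    expect_true(one$target_start %in%
                  vapply(all_ex, function(e) e$target_start, integer(1)))
    expect_identical(one, compile_single(rec, spec, seed = 13))
  }
})
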