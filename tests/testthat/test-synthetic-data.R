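test_that("the generator is deterministic under seed and index", {
  cfg <- sim_config(n_records = 2, duration_minutes = 500,
                    duration_spread = 0.1, seed = 7)
  expect_identical(simulate_record(cfg, 1), simulate_record(cfg, 1))
  expect_false(identical(simulate_record(cfg, 1)$map,
                         simulate_record(cfg, 2)$map))
})

test_that("cohorts have distinct ids and an episode log", {
  cfg <- sim_config(n_records = 10, duration_minutes = 400,
                    duration_spread = 0.05, seed = 3)
  recs <- simulate_cohort(cfg)
  expect_length(recs, 10)
  expect_length(unique(names(recs)), 10)
  log <- attr(recs, "episode_log")
  expect_true(all(c("record_id", "onset", "end") %in% names(log)))
})

test_that("a quiet configuration produces no hypotensive window at any phase", {
  cfg <- sim_config(n_records = 3, duration_minutes = 600,
                    duration_spread = 0, episode_rate = 0,
                    missing_rate = 0, artifact_rate = 0, seed = 11)
  for (i in 1:3) {
    rec <- simulate_record(cfg, i)
    n <- record_length(rec)
    labels <- vapply(0:(n - 30), function(s) {
      brute_label(rec$map[(s + 1):(s + 30)])
    }, character(1))
    expect_false(any(labels == "hypotensive"))
  }
})

test_that("generated pressures are mutually consistent and artifacts out of bound", {
  cfg <- sim_config(n_records = 1, duration_minutes = 2000,
                    duration_spread = 0, artifact_rate = 0.01, seed = 5)
  rec <- simulate_record(cfg, 1)
  ok <- !is.na(rec$sbp) & !is.na(rec$dbp)
  expect_true(all(rec$sbp[ok] >= rec$dbp[ok]))
  vals <- c(rec$hr, rec$sbp, rec$dbp, rec$map)
  vals <- vals[!is.na(vals)]
  expect_true(any(vals < 10 | vals > 200))  # artifacts present
  expect_gt(mean(is.na(rec$map)), 0)        # missing blocks present
})

test_that("every generated episode contains a qualifying hypotensive target window", {
  recs <- cached_cohort("strong", n_records = 20, seed = 88)
  log <- attr(recs, "episode_log")
  expect_gt(nrow(log), 0)
  for (i in seq_len(nrow(log))) {
    rec <- recs[[log$record_id[i]]]
    n <- record_length(rec)
    starts <- seq(0, n - 30, by = 30)
    starts <- starts[starts >= log$onset[i] - 30 & starts <= log$end[i] + 30]
    labs <- vapply(starts, function(s) {
      label_target_window(rec$map[(s + 1):(s + 30)])
    }, character(1))
    expect_true(any(labs == "hypotensive"),
                label = sprintf("episode %d of %s", i, log$record_id[i]))
  }
})

test_that("with no dropouts or artifacts every interior window passes validity", {
  cfg <- sim_config(n_records = 2, duration_minutes = 700,
                    duration_spread = 0, missing_rate = 0,
                    artifact_rate = 0, seed = 19)
  for (i in 1:2) {
    rec <- simulate_record(cfg, i)
    n <- record_length(rec)
    for (s in seq(0, n - 30, by = 90)) {
      oi <- (s + 1):(s + 30)
      expect_true(check_observation_validity(
        list(hr = rec$hr[oi], sbp = rec$sbp[oi], dbp = rec$dbp[oi],
             map = rec$map[oi])))
    }
  }
})

test_that("the configured precursor MAP slope is recovered over the pre-onset hour", {
  # Monte-Carlo check of the generator against its own parameter: the mean
  # least-squares slope over the hour before onset, across >= 50 episodes,
  # must sit within 3 standard errors of the configured -0.2 mmHg/min.
  slopes <- numeric(0)
  batch <- 0
  while (length(slopes) < 50 && batch < 6) {
    batch <- batch + 1
    cfg <- sim_config(n_records = 30, duration_minutes = 1200,
                      duration_spread = 0.05, episode_rate = 1.5,
                      precursor_map_slope = -0.2, missing_rate = 0,
                      artifact_rate = 0, seed = 300 + batch)
    recs <- simulate_cohort(cfg)
    log <- attr(recs, "episode_log")
    for (i in seq_len(nrow(log))) {
      rec <- recs[[log$record_id[i]]]
      o <- log$onset[i]
      if (o >= 60) {
        seg <- rec$map[(o - 60 + 1):o]
        tt <- 0:59
        slopes <- c(slopes, unname(coef(lm(seg ~ tt))[2]))
      }
    }
  }
  expect_gte(length(slopes), 50)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(mean(slopes), 0)
  expect_lt(abs(mean(slopes) - (-0.2)), 3 * se)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(duration_minutes = 100), "210")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(episode_depth = 65), "episode_depth")
})
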