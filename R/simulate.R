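#' Configuration for the synthetic cohort generator
#'
#' The generator emulates minute-by-minute bedside-monitor trend data: each
#' series is an AR(1) process around a slowly drifting per-record baseline,
#' with SBP and DBP derived from the simulated MAP and pulse-pressure paths
#' (`SBP = MAP + 2 PP / 3`, `DBP = SBP - PP`) so the four pressures are
#' mutually consistent. Hypotensive episodes arrive as a Poisson count per
#' record; each ramps the MAP baseline below 60 mmHg and holds it there long
#' enough that at least one grid-aligned 30-minute window qualifies as a
#' hypotensive episode regardless of tiling phase. Optional precursor
#' signatures — a linear MAP drift, pulse-pressure narrowing and inflated
#' variability — are imposed on the window preceding each onset, which is
#' what makes the prediction task solvable in principle; setting all three
#' to zero yields a null cohort with no learnable signal before onsets.
#'
#' @param n_records Number of records in the cohort.
#' @param duration_minutes Median record duration in minutes. Durations are
#'   drawn lognormally (skewed, like real ICU stays), truncated to
#'   `[240, 6 * duration_minutes]`.
#' @param duration_spread Log-scale SD of the duration distribution.
#' @param baseline_map,baseline_hr,baseline_pp Cohort-level normotensive
#'   baselines (mmHg, beats/min, mmHg). Each record jitters these.
#' @param ar_coef AR(1) coefficient shared by the noise processes.
#' @param noise_sd_map,noise_sd_hr,noise_sd_pp Innovation SDs.
#' @param drift_sd Per-minute SD of the random-walk baseline drift.
#' @param episode_rate Expected hypotensive episodes per record (Poisson).
#' @param episode_depth Plateau MAP during an episode (mmHg, below 60).
#' @param episode_plateau Minutes the plateau is held. The default 55 makes
#'   a qualifying aligned 30-minute window certain for any tiling phase.
#' @param episode_ramp Ramp length (minutes) into and out of the plateau.
#' @param precursor_minutes Length of the pre-onset window carrying the
#'   precursor signature. The default 120 covers the observation window for
#'   the 30-minute-observation, 1-hour-gap geometry.
#' @param precursor_map_slope MAP drift during the precursor window,
#'   mmHg/min (negative = decline). 0 disables.
#' @param precursor_pp_narrow Fractional pulse-pressure narrowing reached at
#'   onset (e.g. 0.3 = PP down 30%), ramped linearly over the precursor
#'   window. 0 disables.
#' @param precursor_var_mult Multiplier on innovation SDs reached at onset,
#'   ramped over the precursor window. 1 disables.
#' @param missing_rate Fraction of minutes dropped (monitor disconnections,
#'   drawn as contiguous blocks affecting all four series).
#' @param artifact_rate Fraction of minutes replaced, per series, by
#'   out-of-physiologic-bound spikes (outside 10--200).
#' @param med_response If `TRUE`, pressor doses are injected shortly after
#'   each episode onset, and occasional background diuretic doses occur.
#' @param seed Integer master seed; records are independently seeded from it
#'   and their index.
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_records = 3, duration_minutes = 600)
#' rec <- simulate_record(cfg, 1)
#' rec
#' @export
sim_config <- function(n_records = 120,
                       duration_minutes = 4788,
                       duration_spread = 0.9,
                       baseline_map = 80, baseline_hr = 85, baseline_pp = 45,
                       ar_coef = 0.9,
                       noise_sd_map = 1.2, noise_sd_hr = 1.6,
                       noise_sd_pp = 1.2,
                       drift_sd = 0.03,
                       episode_rate = 1.1,
                       episode_depth = 52,
                       episode_plateau = 55,
                       episode_ramp = 10,
                       precursor_minutes = 120,
                       precursor_map_slope = -0.15,
                       precursor_pp_narrow = 0.3,
                       precursor_var_mult = 2,
                       missing_rate = 0.02,
                       artifact_rate = 0.005,
                       med_response = TRUE,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (cfg$n_records < 1) stop("n_records must be >= 1", call. = FALSE)
  if (cfg$duration_minutes <= 210) {
    stop("duration_minutes must exceed the maximal observation + gap + ",
         "target span (210 minutes)", call. = FALSE)
  }
  for (r in c("missing_rate", "artifact_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(r, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$episode_rate < 0) stop("episode_rate must be >= 0", call. = FALSE)
  if (cfg$episode_depth >= 60 || cfg$episode_depth <= 10) {
    stop("episode_depth must lie in (10, 60) mmHg", call. = FALSE)
  }
  if (cfg$ar_coef < 0 || cfg$ar_coef >= 1) {
    stop("ar_coef must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$precursor_var_mult <= 0) {
    stop("precursor_var_mult must be > 0", call. = FALSE)
  }
  cfg
}

# Fixture cohorts used throughout the tests and the acceptance analysis:
# 120 records of ~30 h each, either carrying the strong precursor signature
# or its matched null (identical in every other respect).

#' @rdname sim_config
#' @param kind `"strong"` for the learnable-precursor fixture cohort,
#'   `"null"` for its matched no-signal twin.
#' @export
fixture_cohort_config <- function(kind = c("strong", "null"),
                                  n_records = 120, seed = 20100L) {
  kind <- match.arg(kind)
  null <- kind == "null"
  sim_config(n_records = n_records,
             duration_minutes = 1800, duration_spread = 0.12,
             episode_rate = 1.1,
             precursor_map_slope = if (null) 0 else -0.15,
             precursor_pp_narrow = if (null) 0 else 0.3,
             precursor_var_mult = if (null) 1 else 2,
             missing_rate = 0.02, artifact_rate = 0.005,
             seed = seed)
}

# AR(1) noise with a time-varying innovation scale profile.
ar1_noise <- function(n, phi, sd, scale_profile) {
  e <- stats::rnorm(n, 0, sd) * scale_profile
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Simulate one hemodynamic record
#'
#' @param config A [sim_config()].
#' @param record_index 1-based index of the record within the cohort; with
#'   the config seed it fully determines the record.
#' @return A `hemodynamic_record` with attribute `"episodes"`: a data frame
#'   of the generated episode onsets and ends (minute indices of the
#'   below-60 span), for cross-module contract checks.
#' @export
simulate_record <- function(config, record_index) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, record_index), {
    n <- round(stats::rlnorm(1, log(config$duration_minutes),
                             config$duration_spread))
    n <- as.integer(min(max(n, 240), 6 * config$duration_minutes))
    age <- round(min(max(stats::rnorm(1, 65, 12), 18), 95))

    # per-record baselines with slow random-walk drift
    map0 <- config$baseline_map + stats::rnorm(1, 0, 4)
    hr0 <- config$baseline_hr + stats::rnorm(1, 0, 6)
    pp0 <- max(config$baseline_pp + stats::rnorm(1, 0, 4), 20)
    t_idx <- seq_len(n)
    map_base <- map0 + cumsum(stats::rnorm(n, 0, config$drift_sd))
    hr_base <- hr0 + cumsum(stats::rnorm(n, 0, config$drift_sd))
    pp_base <- pp0 + cumsum(stats::rnorm(n, 0, config$drift_sd))

    # episode onsets: Poisson count, uniform placement without overlap
    ep_total <- config$episode_plateau + 2 * config$episode_ramp
    margin_lo <- config$precursor_minutes + 60
    margin_hi <- n - ep_total - 60
    k <- stats::rpois(1, config$episode_rate)
    onsets <- integer(0)
    if (k > 0 && margin_hi > margin_lo) {
      sep <- config$precursor_minutes + ep_total + 90
      for (i in seq_len(k)) {
        for (try in 1:50) {
          cand <- floor(stats::runif(1, margin_lo, margin_hi))
          if (all(abs(cand - onsets) >= sep)) {
            onsets <- c(onsets, cand)
            break
          }
        }
      }
      onsets <- sort(onsets)
    }

    # variability profile (precursor effect on innovation scale)
    var_prof <- rep(1, n)
    pp_factor <- rep(1, n)
    P <- config$precursor_minutes
    onset_offset <- numeric(length(onsets))
    for (j in seq_along(onsets)) {
      o <- onsets[j]
      pre <- (o - P):(o - 1) + 1L          # 1-based indices of [o-P, o)
      w <- seq_along(pre) / length(pre)    # 0 -> 1 toward onset
      var_prof[pre] <- 1 + (config$precursor_var_mult - 1) * w
      pp_factor[pre] <- pp_factor[pre] * (1 - config$precursor_pp_narrow * w)
      map_base[pre] <- map_base[pre] +
        config$precursor_map_slope * (seq_along(pre) - 1)
      onset_offset[j] <- config$precursor_map_slope * (length(pre) - 1)
    }

    # impose the episode trajectory on the MAP baseline: the down-ramp
    # continues from the precursor-depressed level, the recovery ramp
    # returns to the undepressed drifting baseline
    for (j in seq_along(onsets)) {
      o <- onsets[j]
      ramp <- config$episode_ramp
      plat <- config$episode_plateau
      seg <- function(from, len) {
        idx <- from:(from + len - 1)
        idx[idx < n] + 1L
      }
      down <- seg(o, ramp)
      hold <- seg(o + ramp, plat)
      up <- seg(o + ramp + plat, ramp)
      if (length(down) > 0) {
        start_level <- map_base[down] + onset_offset[j]
        map_base[down] <- start_level +
          (config$episode_depth - start_level) *
            seq_along(down) / (length(down) + 1)
      }
      map_base[hold] <- config$episode_depth
      if (length(up) > 0) {
        map_base[up] <- config$episode_depth +
          (map_base[up] - config$episode_depth) *
            seq_along(up) / (length(up) + 1)
      }
    }

    map <- map_base + ar1_noise(n, config$ar_coef, config$noise_sd_map,
                                var_prof)
    hr <- hr_base + ar1_noise(n, config$ar_coef, config$noise_sd_hr,
                              var_prof)
    pp <- pmax(pp_base * pp_factor +
                 ar1_noise(n, config$ar_coef, config$noise_sd_pp, var_prof),
               15)
    sbp <- map + 2 * pp / 3
    dbp <- sbp - pp

    # minutes inside an episode (plus ramps) are protected from missing
    # blocks and artifacts so every episode keeps a qualifying window
    protected <- rep(FALSE, n)
    for (o in onsets) {
      span <- (o - 5):(o + ep_total + 5)
      span <- span[span >= 0 & span < n]
      protected[span + 1L] <- TRUE
    }

    # missing data: contiguous disconnection blocks across all series
    miss <- rep(FALSE, n)
    target_missing <- round(config$missing_rate * n)
    guard <- 0
    while (sum(miss) < target_missing && guard < 10 * n) {
      guard <- guard + 1
      len <- 1 + stats::rgeom(1, 1 / 8)
      start <- sample.int(n, 1)
      span <- start:min(start + len - 1, n)
      span <- span[!protected[span]]
      miss[span] <- TRUE
    }
    hr[miss] <- NA; sbp[miss] <- NA; dbp[miss] <- NA; map[miss] <- NA

    # artifacts: out-of-bound spikes per series, preserving SBP >= DBP
    spike <- function(x, values) {
      n_art <- round(config$artifact_rate * n)
      if (n_art < 1) return(x)
      ok <- which(!miss & !protected)
      if (length(ok) == 0) return(x)
      at <- ok[sample.int(length(ok), min(n_art, length(ok)))]
      x[at] <- values[sample.int(length(values), length(at), replace = TRUE)]
      x
    }
    hr <- spike(hr, c(5, 250))
    sbp <- spike(sbp, 250)
    dbp <- spike(dbp, 5)
    map <- spike(map, c(5, 250))

    meds <- empty_medications()
    if (config$med_response && length(onsets) > 0) {
      for (o in onsets) {
        t1 <- o + 5; t2 <- o + 20
        add <- data.frame(
          minute = c(t1, t2)[c(t1, t2) < n],
          drug = c("dopamine", "norepinephrine")[c(t1, t2) < n],
          dose_mcg_per_kg = round(stats::runif(sum(c(t1, t2) < n), 2, 8), 2))
        meds <- rbind(meds[names(add)], add)
      }
    }
    if (config$med_response && stats::runif(1) < 0.3) {
      meds <- rbind(meds[c("minute", "drug", "dose_mcg_per_kg")],
                    data.frame(minute = sample.int(n, 1) - 1L,
                               drug = "lasix",
                               dose_mcg_per_kg = round(stats::runif(1, 5, 20), 2)))
    }

    rec <- hemodynamic_record(
      record_id = sprintf("sim%05d", record_index),
      hr = hr, sbp = sbp, dbp = dbp, map = map, age = age,
      medications = meds)
    attr(rec, "episodes") <- data.frame(
      onset = as.integer(onsets),
      end = as.integer(onsets + ep_total))
    rec
  })
}

#' Simulate a full cohort
#'
#' @param config A [sim_config()].
#' @return A named list of `hemodynamic_record`s (ids `sim00001`, ...), with
#'   attribute `"episode_log"`: one row per generated episode across the
#'   cohort (`record_id`, `onset`, `end`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  recs <- lapply(seq_len(config$n_records),
                 function(i) simulate_record(config, i))
  names(recs) <- vapply(recs, function(r) r$record_id, character(1))
  logs <- lapply(recs, function(r) {
    ep <- attr(r, "episodes")
    if (nrow(ep) == 0) return(NULL)
    cbind(record_id = r$record_id, ep)
  })
  logs <- logs[!vapply(logs, is.null, logical(1))]
  attr(recs, "episode_log") <- if (length(logs) > 0) {
    do.call(rbind, c(logs, make.row.names = FALSE))
  } else {
    data.frame(record_id = character(0), onset = integer(0),
               end = integer(0))
  }
  recs
}

#' Empirical hypotensive-window prevalence of a cohort
#'
#' Compiles the cohort in multiple mode and reports the fraction of examples
#' labeled hypotensive — the quantity that, on the real ICU data this
#' generator emulates, sits near 2.6%.
#'
#' @param records List of `hemodynamic_record`s.
#' @param spec A [window_spec()].
#' @return Single number in \[0, 1\].
#' @export
he_window_prevalence <- function(records, spec = window_spec()) {
  tab <- compile_cohort(records, spec, mode = "multiple")$table
  if (nrow(tab) == 0) return(NA_real_)
  mean(tab$label == "hypotensive")
}
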