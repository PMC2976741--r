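#' Window geometry for example compilation
#'
#' Each labeled example spans three consecutive intervals: an observation
#' window (30 or 60 min) from which features are computed, a gap (60 or
#' 120 min) giving the prediction horizon, and a fixed 30-min target window
#' whose label (or median MAP) is predicted.
#'
#' @param obs_minutes Observation window length: 30 or 60.
#' @param gap_minutes Gap length: 60 or 120.
#' @return An object of class `"window_spec"` with fields `obs`, `gap` and
#'   `target` (always 30).
#' @examples
#' window_spec(30, 60)
#' @export
window_spec <- function(obs_minutes = 30, gap_minutes = 60) {
  if (!obs_minutes %in% c(30, 60)) {
    stop("obs_minutes must be 30 or 60", call. = FALSE)
  }
  if (!gap_minutes %in% c(60, 120)) {
    stop("gap_minutes must be 60 or 120", call. = FALSE)
  }
  structure(list(obs = as.integer(obs_minutes),
                 gap = as.integer(gap_minutes),
                 target = 30L),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> obs %d min | gap %d min | target %d min\n",
              x$obs, x$gap, x$target))
  invisible(x)
}

# Physiologic plausibility bounds (mmHg / bpm): a crude artifact filter.
BOUND_LO <- 10
BOUND_HI <- 200

#' Label a 30-minute target window
#'
#' A window is a hypotensive episode when MAP lies strictly between 10 and
#' 60 mmHg for at least 90% of its 30 minutes. A window that misses that
#' definition is a control when MAP lies strictly between 10 and 200 mmHg
#' for more than 90% of the window. Anything else — too many missing minutes
#' or out-of-bound artifacts — is excluded. Missing minutes count against
#' both fractions. Note the deliberate asymmetry in strictness: the
#' hypotensive rule is `>= 0.90`, the control rule `> 0.90`.
#'
#' @param map_segment Numeric vector of exactly 30 MAP values (mmHg), `NA`
#'   allowed.
#' @return One of `"hypotensive"`, `"control"`, `"excluded"`.
#' @examples
#' label_target_window(rep(55, 30))                 # hypotensive
#' label_target_window(c(rep(55, 26), rep(70, 4)))  # control: 26/30 < 0.90
#' @export
label_target_window <- function(map_segment) {
  if (length(map_segment) != 30) {
    stop("target window must be exactly 30 minutes, got ",
         length(map_segment), call. = FALSE)
  }
  x <- map_segment
  hypo_frac <- sum(!is.na(x) & x > BOUND_LO & x < 60) / 30
  ctrl_frac <- sum(!is.na(x) & x > BOUND_LO & x < BOUND_HI) / 30
  if (hypo_frac >= 0.90) "hypotensive"
  else if (ctrl_frac > 0.90) "control"
  else "excluded"
}

#' Observation-window validity check
#'
#' All four measured series (HR, SBP, DBP, MAP) must hold in-bound values —
#' strictly between 10 and 200 (bpm for HR, mmHg for the pressures) — for
#' more than 95% of the observation window. Missing minutes count as
#' out-of-bound.
#'
#' @param obs_slices List with numeric elements `hr`, `sbp`, `dbp`, `map`,
#'   all the same length (the observation window length).
#' @return `TRUE` or `FALSE`.
#' @export
check_observation_validity <- function(obs_slices) {
  series <- obs_slices[c("hr", "sbp", "dbp", "map")]
  n <- unique(lengths(series))
  if (length(n) != 1) {
    stop("observation slices must share one length; got ",
         paste(lengths(series), collapse = ", "), call. = FALSE)
  }
  all(vapply(series, function(x) {
    sum(!is.na(x) & x > BOUND_LO & x < BOUND_HI) / n > 0.95
  }, logical(1)))
}

# Assemble the candidate example at `target_start`, or NULL when the
# geometry does not fit, the observation window fails validity, or the
# target is excluded. Shared by both compilation modes and the monitor's
# consistency contract.
make_example <- function(record, target_start, spec) {
  n <- record_length(record)
  obs_start <- target_start - spec$gap - spec$obs
  if (obs_start < 0 || target_start + spec$target > n) return(NULL)
  oi <- (obs_start + 1):(obs_start + spec$obs)
  obs_slices <- list(hr = record$hr[oi], sbp = record$sbp[oi],
                     dbp = record$dbp[oi], map = record$map[oi])
  if (!check_observation_validity(obs_slices)) return(NULL)
  ti <- (target_start + 1):(target_start + spec$target)
  label <- label_target_window(record$map[ti])
  if (label == "excluded") return(NULL)
  tmap <- record$map[ti]
  structure(
    list(record_id = record$record_id,
         target_start = as.integer(target_start),
         label = label,
         target_median_map = stats::median(tmap[!is.na(tmap)]),
         obs_start = as.integer(obs_start),
         obs_slices = obs_slices,
         spec = spec),
    class = "labeled_example")
}

#' Compile all non-overlapping examples from a record
#'
#' Multiple-compilation mode: a 30-minute sliding window with no overlap
#' traverses the record, target windows starting at minutes 0, 30, 60, ....
#' A candidate becomes an example when the full observation-gap-target
#' geometry fits inside the record, the observation window passes the
#' validity check, and the target window is not excluded.
#'
#' @param record A `hemodynamic_record`.
#' @param spec A `window_spec`.
#' @return List of `labeled_example` objects (possibly empty). Each carries
#'   `record_id`, `target_start`, `label`, `target_median_map` (median over
#'   the target window's non-missing MAP) and the raw observation slices.
#' @examples
#' cfg <- sim_config(n_records = 1, duration_minutes = 600,
#'                   duration_spread = 0, missing_rate = 0, artifact_rate = 0,
#'                   episode_rate = 0)
#' rec <- simulate_record(cfg, 1)
#' length(compile_multiple(rec, window_spec(30, 60)))  # 17 tiled targets
#' @export
compile_multiple <- function(record, spec = window_spec()) {
  n <- record_length(record)
  starts <- seq(0L, n - spec$target, by = spec$target)
  starts <- starts[starts >= spec$gap + spec$obs]
  out <- lapply(starts, function(ts) make_example(record, ts, spec))
  out[!vapply(out, is.null, logical(1))]
}

#' Compile at most one example from a record
#'
#' Single-compilation mode: the record's candidate examples are those of
#' [compile_multiple()]; if any is hypotensive, one hypotensive example is
#' drawn uniformly at random, otherwise one control example; records with no
#' candidate yield nothing. Hypotensive-first selection means control
#' examples only ever come from records without a qualifying hypotensive
#' window.
#'
#' @inheritParams compile_multiple
#' @param seed Integer seed making the random draw reproducible.
#' @return A single `labeled_example`, or `NULL` when the record admits no
#'   valid example.
#' @export
compile_single <- function(record, spec = window_spec(), seed = 1L) {
  cand <- compile_multiple(record, spec)
  if (length(cand) == 0) return(NULL)
  labels <- vapply(cand, function(e) e$label, character(1))
  pool <- if (any(labels == "hypotensive")) {
    cand[labels == "hypotensive"]
  } else {
    cand[labels == "control"]
  }
  if (length(pool) == 0) return(NULL)
  pick <- with_seed(seed, sample.int(length(pool), 1))
  pool[[pick]]
}

#' @export
print.labeled_example <- function(x, ...) {
  cat(sprintf(
    "<labeled_example> %s @ target minute %d: %s (median MAP %.1f mmHg; obs %d min, gap %d min)\n",
    x$record_id, x$target_start, x$label, x$target_median_map,
    x$spec$obs, x$spec$gap))
  invisible(x)
}

#' Compile a whole cohort into an example table
#'
#' Applies [compile_multiple()] or [compile_single()] to every record and
#' returns the pooled example list plus a compact summary table.
#'
#' @param records List of `hemodynamic_record`s.
#' @param spec A `window_spec`.
#' @param mode `"multiple"` or `"single"`.
#' @param seed Seed for the single-mode random draws (one derived seed per
#'   record).
#' @return List with `examples` (list of `labeled_example`) and `table`
#'   (data frame: record_id, target_start, label, target_median_map).
#' @export
compile_cohort <- function(records, spec = window_spec(),
                           mode = c("multiple", "single"), seed = 1L) {
  mode <- match.arg(mode)
  examples <- list()
  for (i in seq_along(records)) {
    ex <- if (mode == "multiple") {
      compile_multiple(records[[i]], spec)
    } else {
      one <- compile_single(records[[i]], spec, seed = derive_seed(seed, i))
      if (is.null(one)) list() else list(one)
    }
    examples <- c(examples, ex)
  }
  table <- data.frame(
    record_id = vapply(examples, function(e) e$record_id, character(1)),
    target_start = vapply(examples, function(e) e$target_start, integer(1)),
    label = vapply(examples, function(e) e$label, character(1)),
    target_median_map = vapply(examples, function(e) e$target_median_map,
                               numeric(1)))
  list(examples = examples, table = table)
}
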