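#' Minute-by-minute continuous prediction over a whole record
#'
#' At each minute `t` (the prediction time), the observation window is the
#' `obs` minutes ending at `t`; if it passes the validity check, features
#' are extracted, reduced, and both models are applied. The emitted
#' probability and predicted median MAP refer to the 30-minute target window
#' starting at `t + gap`. Minutes whose observation window does not fit
#' (the first `obs` minutes) or fails the >95% in-bound rule get a
#' no-prediction flag with the reason.
#'
#' @param record A `hemodynamic_record`.
#' @param classifier A `map_classifier` trained with the same window spec.
#' @param regressor A `map_regressor` trained with the same window spec.
#' @param reducer The `fitted_reducer` both models were trained behind.
#' @param spec The [window_spec()] used in training.
#' @return A data frame of class `"monitor_trace"`, one row per minute of
#'   the record: `minute` (0-based), `probability`, `predicted_map`,
#'   `no_prediction_reason` (`NA` when a prediction was made).
#' @export
continuous_predict <- function(record, classifier, regressor, reducer,
                               spec = window_spec()) {
  if (nrow(classifier$weights$W1) != reducer$k ||
      nrow(regressor$weights$W1) != reducer$k) {
    stop("models and reducer disagree on the input dimensionality",
         call. = FALSE)
  }
  n <- record_length(record)
  prob <- rep(NA_real_, n)
  pmap <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  reason[seq_len(min(spec$obs, n))] <- "observation window not yet full"

  ts <- spec$obs:(n - 1)          # prediction times with a full obs window
  valid_t <- integer(0)
  slices <- list()
  for (t in ts) {
    oi <- (t - spec$obs + 1):t    # 1-based indices of minutes [t-obs, t)
    sl <- list(hr = record$hr[oi], sbp = record$sbp[oi],
               dbp = record$dbp[oi], map = record$map[oi])
    if (check_observation_validity(sl)) {
      valid_t <- c(valid_t, t)
      slices[[length(slices) + 1]] <- sl
    } else {
      reason[t + 1] <- "missing or out-of-bound data in observation window"
    }
  }
  if (length(valid_t) > 0) {
    pseudo <- lapply(seq_along(valid_t), function(i) {
      list(record_id = record$record_id,
           obs_start = valid_t[i] - spec$obs,
           obs_slices = slices[[i]],
           spec = spec)
    })
    feats <- feature_matrix(pseudo,
                            stats::setNames(list(record), record$record_id))
    red <- apply_reducer(reducer, feats)
    prob[valid_t + 1] <- predict_probability(classifier, red)
    pmap[valid_t + 1] <- predict_map(regressor, red)
  }
  out <- data.frame(minute = 0:(n - 1), probability = prob,
                    predicted_map = pmap, no_prediction_reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("monitor_trace", "data.frame")
  out
}

#' Shift a trace's MAP predictions for plotting
#'
#' For visual comparison with the true MAP the predicted-MAP series is
#' shifted forward by the gap, so the value predicted at minute `t` is drawn
#' at `t + gap`, the start of the window it describes. The probability
#' series is deliberately left unshifted to preserve its predictive
#' (look-ahead) reading. Applying a shift of `-gap` to a shifted trace
#' restores the original.
#'
#' @param trace A `monitor_trace`.
#' @param spec The matching [window_spec()]; `spec$gap` may be negative to
#'   undo a shift.
#' @return The trace with `predicted_map` displaced by `spec$gap` minutes
#'   (vacated positions `NA`).
#' @export
align_trace_for_plotting <- function(trace, spec = attr(trace, "spec")) {
  g <- spec$gap
  n <- nrow(trace)
  shifted <- rep(NA_real_, n)
  src <- seq_len(n)
  dst <- src + g
  keep <- dst >= 1 & dst <= n
  shifted[dst[keep]] <- trace$predicted_map[src[keep]]
  trace$predicted_map <- shifted
  trace
}
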