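#' Derive the six analysis series from an observation window
#'
#' Adds pulse pressure (`PP = SBP - DBP`) and relative cardiac output
#' (`CO = HR x PP`, a Windkessel proxy proportional to true cardiac output
#' up to arterial compliance) to the four measured series. Minutes where any
#' needed input is missing are missing in the derived series.
#'
#' @param obs_slices List with numeric elements `hr`, `sbp`, `dbp`, `map`.
#' @return List with elements `hr`, `sbp`, `dbp`, `map`, `pp`, `co`, all the
#'   same length.
#' @examples
#' derive_series(list(hr = 60, sbp = 120, dbp = 80, map = 93))
#' @export
derive_series <- function(obs_slices) {
  pp <- obs_slices$sbp - obs_slices$dbp
  co <- obs_slices$hr * pp
  c(obs_slices[c("hr", "sbp", "dbp", "map")], list(pp = pp, co = co))
}

SERIES_NAMES <- c("hr", "sbp", "dbp", "map", "pp", "co")
STAT_NAMES <- c("mean", "median", "sd", "var", "iqr", "skewness",
                "kurtosis", "slope")

#' The eight summary statistics of one series
#'
#' Mean, median, standard deviation, variance, interquartile range,
#' skewness, kurtosis and least-squares linear slope, computed over the
#' non-missing values of an observation-window series. Conventions: variance
#' and SD use the population (divide-by-n) form; skewness and kurtosis are
#' the third and fourth standardized central moments (kurtosis not
#' excess-adjusted), defined as 0 for a constant series; the IQR uses
#' linear-interpolation quantiles; the slope is regressed against the minute
#' index, so its units are (series units) per minute.
#'
#' @param series Numeric vector (one observation-window series), `NA`
#'   allowed; at least two non-missing values required.
#' @return Named numeric vector of length 8.
#' @examples
#' statistical_features(c(1, 2, 3, 4))
#' @export
statistical_features <- function(series) {
  t_min <- seq_along(series) - 1
  ok <- !is.na(series)
  x <- series[ok]
  n <- length(x)
  if (n < 2) {
    stop("statistical features need at least 2 non-missing values",
         call. = FALSE)
  }
  m <- mean(x)
  cx <- x - m
  v <- mean(cx^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean(cx^3) / s^3
    kurt <- mean(cx^4) / s^4
  } else {
    skew <- 0
    kurt <- 0
  }
  tt <- t_min[ok]
  slope <- sum((tt - mean(tt)) * cx) / sum((tt - mean(tt))^2)
  c(mean = m, median = stats::median(x), sd = s, var = v,
    iqr = unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))),
    skewness = skew, kurtosis = kurt, slope = slope)
}

#' Zero-lag cross-correlations of the six series
#'
#' For each unordered pair of the six series, the raw (uncentered,
#' unnormalized) zero-lag cross-correlation `(1/n) * sum(x_i * y_i)` over
#' the minutes where both members are present. Downstream feature
#' normalization absorbs the scale.
#'
#' @param six Output of [derive_series()].
#' @return Named numeric vector of length 15 (`xcorr_hr_sbp`, ...).
#' @export
cross_correlation_features <- function(six) {
  six <- six[SERIES_NAMES]
  pairs <- utils::combn(SERIES_NAMES, 2)
  out <- apply(pairs, 2, function(p) {
    x <- six[[p[1]]]
    y <- six[[p[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) {
      stop("no jointly present minutes for pair ", p[1], "-", p[2],
           call. = FALSE)
    }
    mean(x[ok] * y[ok])
  })
  names(out) <- paste0("xcorr_", pairs[1, ], "_", pairs[2, ])
  out
}

#' Wavelet relative-energy features of one series
#'
#' Five-level discrete Meyer decomposition ([dwt_dmey()]) of the
#' gap-imputed series; the squared Euclidean norm of each coefficient band
#' (approximation `a5` and details `d1`..`d5`) divided by the total across
#' bands. The six relative energies are nonnegative and sum to one, and
#' summarize how the window's variability distributes across spectral bands
#' (from the slowest trends in `a5` to minute-to-minute fluctuation in
#' `d1`).
#'
#' @param series Numeric vector (observation-window series). Missing values
#'   are imputed by linear interpolation (nearest-value extension at the
#'   edges) to restore the uniform grid the transform needs.
#' @return Named numeric vector `(a5, d1, ..., d5)` summing to 1.
#' @examples
#' wavelet_features(rep(5, 30))["a5"]  # constant series: ~ all energy in a5
#' @export
wavelet_features <- function(series) {
  x <- impute_gaps(series)
  w <- dwt_dmey(x, 5L)
  E <- c(a5 = sum(w$a^2),
         d1 = sum(w$d[[1]]^2), d2 = sum(w$d[[2]]^2), d3 = sum(w$d[[3]]^2),
         d4 = sum(w$d[[4]]^2), d5 = sum(w$d[[5]]^2))
  tot <- sum(E)
  if (tot <= 0) {
    stop("zero total wavelet energy: identically zero signal", call. = FALSE)
  }
  E / tot
}

#' Clinical features of an example
#'
#' Patient age plus the summed doses (mcg/kg) of blood-pressure-raising and
#' -lowering medications delivered during the observation window. Window
#' membership is half-open: a dose at the window's first minute counts, one
#' at the end minute does not. Records without medication data contribute
#' zero doses.
#'
#' @param record The `hemodynamic_record` the example came from.
#' @param example A `labeled_example` (or any list with `obs_start` and
#'   `spec`).
#' @return Named numeric vector `(age, dose_raising, dose_lowering)`.
#' @export
clinical_features <- function(record, example) {
  meds <- record$medications
  lo <- example$obs_start
  hi <- example$obs_start + example$spec$obs
  in_win <- !is.na(meds$minute) & meds$minute >= lo & meds$minute < hi
  c(age = record$age,
    dose_raising = sum(meds$dose_mcg_per_kg[in_win &
                                              meds$group == "raising"]),
    dose_lowering = sum(meds$dose_mcg_per_kg[in_win &
                                               meds$group == "lowering"]))
}

#' Names and order of the 102 features
#'
#' 48 statistical (8 per series, series-major), 15 zero-lag
#' cross-correlations, 36 wavelet relative energies (6 per series), 3
#' clinical.
#'
#' @return Character vector of length 102.
#' @export
feature_names <- function() {
  stats <- as.vector(t(outer(SERIES_NAMES, STAT_NAMES, paste, sep = "_")))
  pairs <- utils::combn(SERIES_NAMES, 2)
  xc <- paste0("xcorr_", pairs[1, ], "_", pairs[2, ])
  wav <- as.vector(t(outer(SERIES_NAMES, c("a5", paste0("d", 1:5)),
                           function(a, b) paste0("wav_", a, "_", b))))
  c(stats, xc, wav, c("age", "dose_raising", "dose_lowering"))
}

#' Extract the 102-dimensional feature vector of one example
#'
#' Concatenates, in documented order, the statistical features of the six
#' series, the 15 zero-lag cross-correlations, the 36 wavelet relative
#' energies, and the three clinical features.
#'
#' @param example A `labeled_example` from [compile_multiple()] or
#'   [compile_single()].
#' @param record The `hemodynamic_record` it came from.
#' @return Named numeric vector of length 102, names as [feature_names()].
#' @export
extract_features <- function(example, record) {
  six <- derive_series(example$obs_slices)
  stats <- unlist(lapply(six, statistical_features))
  names(stats) <- as.vector(t(outer(SERIES_NAMES, STAT_NAMES, paste,
                                    sep = "_")))
  xc <- cross_correlation_features(six)
  wav <- unlist(lapply(six, wavelet_features))
  names(wav) <- as.vector(t(outer(SERIES_NAMES, c("a5", paste0("d", 1:5)),
                                  function(a, b) paste0("wav_", a, "_", b))))
  out <- c(stats, xc, wav, clinical_features(record, example))
  stopifnot(length(out) == 102L)
  out
}

#' Feature matrix for a set of examples
#'
#' Vectorized cohort-scale extraction: identical to calling
#' [extract_features()] per example (a tested equivalence), with the wavelet
#' bands computed through a cached linear operator for speed.
#'
#' @param examples List of `labeled_example`s.
#' @param records Named list of `hemodynamic_record`s keyed by record id.
#' @return Numeric matrix, one row per example, 102 named columns.
#' @export
feature_matrix <- function(examples, records) {
  n <- length(examples)
  out <- matrix(NA_real_, nrow = n, ncol = 102,
                dimnames = list(NULL, feature_names()))
  if (n == 0) return(out)
  obs_len <- examples[[1]]$spec$obs
  # statistical + cross-correlation + clinical per example; wavelets in bulk
  imputed <- array(NA_real_, dim = c(obs_len, 6, n))
  for (i in seq_len(n)) {
    ex <- examples[[i]]
    rec <- records[[ex$record_id]]
    six <- derive_series(ex$obs_slices)
    st <- unlist(lapply(six, statistical_features), use.names = FALSE)
    out[i, 1:48] <- st
    out[i, 49:63] <- cross_correlation_features(six)
    out[i, 100:102] <- clinical_features(rec, ex)
    for (s in 1:6) imputed[, s, i] <- impute_gaps(six[[s]])
  }
  X <- matrix(imputed, nrow = obs_len)        # obs_len x (6 n)
  rel <- wavelet_energies_bulk(X)             # 6 bands x (6 n)
  # column block for series s of example i is at (i-1)*6 + s
  for (s in 1:6) {
    cols <- (seq_len(n) - 1) * 6 + s
    out[, 63 + (s - 1) * 6 + 1:6] <- t(rel[, cols, drop = FALSE])
  }
  out
}
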