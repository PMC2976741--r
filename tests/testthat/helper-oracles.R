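# Independent oracles and shared fixtures for the suite. Oracles here are
# deliberately naive re-derivations (direct formulas, exhaustive scans) kept
# separate from the package's implementations.

# Trapezoidal ROC integration: sweep thresholds at the unique scores,
# collect (FPR, TPR) points, integrate. Independent of the rank-statistic
# route used by classification_metrics().
trapezoid_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(ths, function(t) mean(scores[y == 1] >= t), 1), 1)
  fpr <- c(0, vapply(ths, function(t) mean(scores[y == 0] >= t), 1), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Direct-formula summary statistics (population moment conventions).
naive_stats <- function(x) {
  t <- seq_along(x) - 1
  ok <- !is.na(x)
  x <- x[ok]; t <- t[ok]
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  fit <- lm(x ~ t)
  c(mean = m, median = median(x), sd = s, var = v,
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    skewness = if (s > 0) sum((x - m)^3) / n / s^3 else 0,
    kurtosis = if (s > 0) sum((x - m)^4) / n / s^4 else 0,
    slope = unname(coef(fit)[2]))
}

# Brute-force window labeler: literal counting against the printed
# definition, no shared code with label_target_window().
brute_label <- function(seg) {
  stopifnot(length(seg) == 30)
  hypo <- 0; ctrl <- 0
  for (v in seg) {
    if (!is.na(v) && v > 10 && v < 60) hypo <- hypo + 1
    if (!is.na(v) && v > 10 && v < 200) ctrl <- ctrl + 1
  }
  if (hypo / 30 >= 0.9) return("hypotensive")
  if (ctrl / 30 > 0.9) return("control")
  "excluded"
}

# A fully valid flat record for geometry tests: constant vitals, no noise.
flat_record <- function(n = 600, map = 80, id = "flat") {
  hemodynamic_record(id, hr = rep(80, n), sbp = rep(110, n),
                     dbp = rep(65, n), map = rep(map, n), age = 60)
}

# Cohorts are expensive; simulate each fixture once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function(kind, n_records = 120, seed = 20100) {
  key <- paste(kind, n_records, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      simulate_cohort(fixture_cohort_config(kind, n_records, seed))
  }
  .fixture_cache[[key]]
}

# A small trained pipeline (reducer + classifier + regressor) shared by the
# monitor tests; trained on a 10-record strong cohort.
cached_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    recs <- cached_cohort("strong", n_records = 10, seed = 404)
    comp <- compile_cohort(recs, window_spec(30, 60), "multiple")
    fm <- feature_matrix(comp$examples, recs)
    y <- as.numeric(comp$table$label == "hypotensive")
    bal <- balance_by_subsampling(y, seed = 9)
    red <- suppressWarnings(fit_reducer(fm[bal, , drop = FALSE]))
    clf <- train_classifier(apply_reducer(red, fm[bal, , drop = FALSE]),
                            y[bal], seed = 9)
    reg <- train_regressor(apply_reducer(red, fm),
                           comp$table$target_median_map, seed = 9)
    .fixture_cache$pipeline <- list(records = recs, reducer = red,
                                    classifier = clf, regressor = reg)
  }
  .fixture_cache$pipeline
}
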