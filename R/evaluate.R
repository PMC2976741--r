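#' Experiment configuration
#'
#' Defaults follow the study protocol: record-level 5-fold cross-validation;
#' for classification, 10 rounds of majority-class sub-sampling per fold
#' with the test fold left unbalanced; for regression in multiple mode, 10
#' random training subsets of 2,500 examples per fold. Every source of
#' randomness (fold assignment, sub-samples, network initialization,
#' validation splits) derives deterministically from the one experiment
#' seed.
#'
#' @param spec A [window_spec()].
#' @param mode Compilation mode, `"multiple"` or `"single"`.
#' @param task `"classification"` or `"regression"`.
#' @param n_folds Number of record-level folds.
#' @param n_subsamples Sub-sampling (or training-subset) repetitions per
#'   fold.
#' @param regression_train_size Training subset size for regression in
#'   multiple mode.
#' @param variance_target PCA explained-variance target.
#' @param hidden,max_epochs,patience Network training controls.
#' @param seed Master seed.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(spec = window_spec(),
                              mode = c("multiple", "single"),
                              task = c("classification", "regression"),
                              n_folds = 5L, n_subsamples = 10L,
                              regression_train_size = 2500L,
                              variance_target = 0.90,
                              hidden = 20L, max_epochs = 500L,
                              patience = 10L, seed = 1L) {
  mode <- match.arg(mode)
  task <- match.arg(task)
  structure(as.list(environment()), class = "experiment_config")
}

#' Assign records to cross-validation folds
#'
#' The partition is by record, never by example: all examples from a record
#' inherit its fold, so no record can contribute to both training and test
#' data of any run.
#'
#' @param record_ids Character vector of the distinct record ids to split.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector: fold (1..n_folds) per record id.
#' @export
partition_by_record <- function(record_ids, n_folds = 5L, seed = 1L) {
  ids <- unique(as.character(record_ids))
  if (length(ids) < n_folds) {
    stop("need at least ", n_folds, " distinct records, got ", length(ids),
         call. = FALSE)
  }
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(n_folds), length(ids)))
  })
  names(folds) <- ids
  folds
}

#' Balance training examples by majority-class sub-sampling
#'
#' Keeps every minority-class example and an equal-sized without-replacement
#' random sample of the majority class. Test data are never balanced.
#'
#' @param labels Character or 0/1 vector of training labels.
#' @param seed Integer seed.
#' @return Integer vector of the selected row indices.
#' @export
balance_by_subsampling <- function(labels, seed = 1L) {
  y <- as.character(labels)
  classes <- unique(y)
  if (length(classes) != 2) {
    stop("balancing needs exactly two classes present", call. = FALSE)
  }
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(classes, minority)
  min_idx <- which(y == minority)
  maj_idx <- which(y == majority)
  keep_maj <- with_seed(seed, sample(maj_idx, length(min_idx)))
  sort(c(min_idx, keep_maj))
}

#' Classification metric suite
#'
#' AUC via the rank (Mann-Whitney) statistic — tie-aware and identical to
#' trapezoidal integration of the ROC curve — plus accuracy, sensitivity,
#' specificity, PPV and NPV from the confusion matrix at the supplied
#' threshold (positive when `score >= threshold`). PPV and NPV are `NaN`
#' when no case is predicted positive (resp. negative).
#'
#' @param scores Numeric scores (posterior probabilities).
#' @param labels 0/1 vector, both classes present.
#' @param threshold Decision threshold.
#' @return Named numeric vector: auc, accuracy, sensitivity, specificity,
#'   ppv, npv.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- scores >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  c(auc = auc,
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn))
}

#' Regression metric suite
#'
#' Mean absolute error as a percentage of the true value,
#' `MAE = 100/N * sum(|pred - true| / true)`; the slope and intercept of a
#' robust line fit of predicted on true MAP (iteratively reweighted least
#' squares with Tukey bisquare weights, 1 and 0 for perfect regression);
#' and the Pearson correlation between predicted and true values.
#'
#' @param predicted,true Numeric vectors (mmHg), equal length >= 3; true
#'   values must be positive.
#' @return Named numeric vector: mae_pct, pearson_r, slope,
#'   intercept_mmHg. The line and correlation are `NA` when the true (or
#'   predicted) values are constant, where they are undefined.
#' @export
regression_metrics <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) < 3) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (any(true <= 0)) {
    stop("true MAP values must be positive for the percentage error",
         call. = FALSE)
  }
  mae <- mean(abs(predicted - true) / true) * 100
  if (stats::sd(true) > 0) {
    fit <- MASS::rlm(predicted ~ true, psi = MASS::psi.bisquare,
                     maxit = 100)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r <- if (stats::sd(predicted) > 0) stats::cor(predicted, true)
         else NA_real_
  } else {
    # degenerate scatter: the line and correlation are undefined
    slope <- NA_real_
    intercept <- NA_real_
    r <- NA_real_
  }
  c(mae_pct = mae, pearson_r = r, slope = slope, intercept_mmHg = intercept)
}

#' Run the full cross-validated experiment
#'
#' Compiles the cohort under the configured mode and window geometry, then
#' per fold and per sub-sample: fits the reducer on the (balanced or
#' sub-sampled) training rows, trains the network, and evaluates on the
#' fold's untouched test examples. Features are extracted once per cohort;
#' normalization and PCA are refit for every training-set variant. Runs
#' whose test fold contains a single class are flagged and excluded from
#' aggregation with a warning.
#'
#' @param records Named list of `hemodynamic_record`s.
#' @param config An [experiment_config()].
#' @return An object of class `"evaluation_report"`: list with `runs` (one
#'   row per fold x sub-sample with all metrics and the retained
#'   dimensionality `k`), `aggregate` (mean and SD per metric over valid
#'   runs), `n_examples`, `prevalence` and the config.
#' @export
run_experiment <- function(records, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  comp <- compile_cohort(records, config$spec, mode = config$mode,
                         seed = derive_seed(config$seed, 101L))
  examples <- comp$examples
  tab <- comp$table
  if (nrow(tab) == 0) stop("cohort compiled to zero examples", call. = FALSE)
  feats <- feature_matrix(examples, records)
  y_bin <- as.numeric(tab$label == "hypotensive")

  folds <- partition_by_record(tab$record_id, config$n_folds,
                               seed = derive_seed(config$seed, 202L))
  ex_fold <- folds[tab$record_id]

  runs <- list()
  for (f in seq_len(config$n_folds)) {
    te <- which(ex_fold == f)
    tr <- which(ex_fold != f)
    # record-level hygiene: no record may feed both sides of any run
    stopifnot(length(intersect(tab$record_id[tr], tab$record_id[te])) == 0)
    for (s in seq_len(config$n_subsamples)) {
      run_seed <- derive_seed(config$seed, f, s)
      run <- c(fold = f, subsample = s)
      if (config$task == "classification") {
        if (length(unique(y_bin[tr])) < 2 ||
            length(unique(y_bin[te])) < 2) {
          warning(sprintf(
            "fold %d: single-class training or test set; run excluded", f),
            call. = FALSE)
          runs[[length(runs) + 1]] <- c(run, valid = 0)
          next
        }
        bal <- tr[balance_by_subsampling(y_bin[tr], seed = run_seed)]
        red <- fit_reducer(feats[bal, , drop = FALSE],
                           config$variance_target)
        clf <- train_classifier(apply_reducer(red, feats[bal, , drop = FALSE]),
                                y_bin[bal],
                                seed = derive_seed(run_seed, 1L),
                                hidden = config$hidden,
                                max_epochs = config$max_epochs,
                                patience = config$patience)
        scores <- predict_probability(clf,
                                      apply_reducer(red, feats[te, , drop = FALSE]))
        met <- classification_metrics(scores, y_bin[te], clf$threshold)
        runs[[length(runs) + 1]] <- c(run, valid = 1, k = red$k, met)
      } else {
        sub <- if (config$mode == "multiple" &&
                     length(tr) > config$regression_train_size) {
          with_seed(run_seed,
                    sample(tr, config$regression_train_size))
        } else {
          tr
        }
        red <- fit_reducer(feats[sub, , drop = FALSE],
                           config$variance_target)
        reg <- train_regressor(apply_reducer(red, feats[sub, , drop = FALSE]),
                               tab$target_median_map[sub],
                               seed = derive_seed(run_seed, 1L),
                               hidden = config$hidden,
                               max_epochs = config$max_epochs,
                               patience = config$patience)
        pred <- predict_map(reg,
                            apply_reducer(red, feats[te, , drop = FALSE]))
        met <- regression_metrics(pred, tab$target_median_map[te])
        runs[[length(runs) + 1]] <- c(run, valid = 1, k = red$k, met)
      }
    }
  }
  run_df <- as.data.frame(do.call(rbind, lapply(runs, function(r) {
    # pad excluded runs with NA metric columns
    full <- runs[[which(vapply(runs, length, integer(1)) ==
                          max(vapply(runs, length, integer(1))))[1]]]
    out <- rep(NA_real_, length(full))
    names(out) <- names(full)
    out[names(r)] <- r
    out
  })))
  valid <- run_df[run_df$valid == 1, , drop = FALSE]
  metric_cols <- setdiff(names(run_df), c("fold", "subsample", "valid"))
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(valid[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(valid[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  structure(list(runs = run_df, aggregate = aggregate,
                 n_examples = nrow(tab),
                 prevalence = mean(y_bin),
                 fold_of_record = folds,
                 config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<evaluation_report> %s, %s compilation, obs %d / gap %d min\n",
    cfg$task, cfg$mode, cfg$spec$obs, cfg$spec$gap))
  cat(sprintf("  %d examples (%.1f%% hypotensive), %d x %d runs (%d valid)\n",
              x$n_examples, 100 * x$prevalence, cfg$n_folds,
              cfg$n_subsamples, sum(x$runs$valid == 1, na.rm = TRUE)))
  agg <- x$aggregate[x$aggregate$metric != "k", ]
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %7.3f +/- %.3f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Mean metric from an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param metric Metric name, e.g. `"auc"` or `"mae_pct"`.
#' @return The mean over valid runs.
#' @export
report_mean <- function(report, metric) {
  agg <- report$aggregate
  if (!metric %in% agg$metric) {
    stop("no metric '", metric, "' in this report", call. = FALSE)
  }
  agg$mean[agg$metric == metric]
}
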