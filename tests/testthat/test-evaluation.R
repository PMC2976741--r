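test_that("fold assignment partitions records evenly and deterministically", {
  ids <- paste0("r", 1:10)
  f <- partition_by_record(ids, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(f, partition_by_record(ids, 5, seed = 2))
  expect_error(partition_by_record(ids[1:3], 5), "at least 5")
})

test_that("sub-sampling balances to exactly 1:1 without replacement", {
  y <- c(rep("control", 100), rep("hypotensive", 10))
  idx <- balance_by_subsampling(y, seed = 6)
  expect_length(idx, 20)
  expect_true(all(table(y[idx]) == 10))
  expect_false(anyDuplicated(idx) > 0)
  # already balanced input returns everything
  yb <- rep(c("a", "b"), 15)
  expect_length(balance_by_subsampling(yb, seed = 1), 30)
  expect_error(balance_by_subsampling(rep("a", 5), seed = 1), "two classes")
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  sc <- c(rep(0.9, 10), rep(0.1, 2), rep(0.9, 90), rep(0.1, 810))
  y <- c(rep(1, 12), rep(0, 900))
  m <- classification_metrics(sc, y, threshold = 0.5)
  expect_equal(unname(m["ppv"]), 0.1)
  expect_equal(unname(m["sensitivity"]), 10 / 12)
  expect_equal(unname(m["specificity"]), 810 / 900)
  expect_equal(unname(m["npv"]), 810 / 812)
  # perfect separation
  mp <- classification_metrics(c(0.9, 0.8, 0.2), c(1, 1, 0), 0.5)
  expect_equal(unname(mp["auc"]), 1)
  expect_error(classification_metrics(c(0.5, 0.6), c(1, 1), 0.5),
               "single class")
})

test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    sc <- round(runif(n), 2)  # ties on purpose
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    a1 <- classification_metrics(sc, y, 0.5)[["auc"]]
    expect_equal(a1, trapezoid_auc(sc, y), tolerance = 1e-10)
  }
})

test_that("the PPV-prevalence identity holds on enumerated confusion matrices", {
  cases <- expand.grid(sens = c(0.5, 0.8, 0.95), spec = c(0.6, 0.85),
                       prev = c(0.026, 0.2, 0.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    n_pos <- 1000 * cs$prev; n_neg <- 1000 - n_pos
    tp <- round(n_pos * cs$sens); fn <- n_pos - tp
    tn <- round(n_neg * cs$spec); fp <- n_neg - tn
    sc <- c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn))
    y <- c(rep(1, tp + fn), rep(0, fp + tn))
    m <- classification_metrics(sc, y, 0.5)
    sens <- m[["sensitivity"]]; spec <- m[["specificity"]]
    p <- mean(y)
    expect_equal(m[["ppv"]],
                 sens * p / (sens * p + (1 - spec) * (1 - p)),
                 tolerance = 1e-12)
  }
})

test_that("regression metrics follow the percentage-error definition and robust fit", {
  m <- regression_metrics(c(80, 70, 60), c(80, 70, 60))
  expect_equal(unname(m), c(0, 1, 1, 0), tolerance = 1e-8)
  # hand arithmetic on a toy case
  m2 <- regression_metrics(c(90, 100, 60), c(100, 80, 60))
  expect_equal(m2[["mae_pct"]], (10 / 100 + 20 / 80 + 0) / 3 * 100)
  expect_error(regression_metrics(c(80, 70, 60), c(80, -1, 60)), "positive")
  expect_error(regression_metrics(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the bisquare line resists a gross outlier where least squares does not", {
  set.seed(77)
  x <- seq(60, 100, length.out = 40)
  y <- 1.02 * x - 1 + rnorm(40, 0, 0.5)
  clean_slope <- regression_metrics(y, x)[["slope"]]
  y_out <- y; y_out[5] <- 250
  robust_slope <- regression_metrics(y_out, x)[["slope"]]
  ols_slope <- unname(coef(lm(y_out ~ x))[2])
  expect_lt(abs(robust_slope - clean_slope) / clean_slope, 0.01)
  expect_gt(abs(ols_slope - clean_slope), abs(robust_slope - clean_slope))
})

test_that("run_experiment executes the full protocol with record hygiene", {
  recs <- cached_cohort("strong", n_records = 15, seed = 77)
  ec <- experiment_config(task = "classification", n_folds = 3,
                          n_subsamples = 2, seed = 5)
  rep <- suppressWarnings(run_experiment(recs, ec))
  expect_equal(nrow(rep$runs), 6)
  expect_true(all(rep$runs$valid %in% c(0, 1)))
  # fold map is a proper partition of the records that yielded examples
  folds <- rep$fold_of_record
  expect_false(anyDuplicated(names(folds)) > 0)
  # determinism of the whole experiment
  rep2 <- suppressWarnings(run_experiment(recs, ec))
  expect_equal(rep$runs, rep2$runs)
  # regression protocol on the same cohort
  ecr <- experiment_config(task = "regression", n_folds = 3,
                           n_subsamples = 2, regression_train_size = 300,
                           seed = 5)
  repr <- suppressWarnings(run_experiment(recs, ecr))
  expect_equal(nrow(repr$runs), 6)
  expect_true(all(c("mae_pct", "pearson_r", "slope", "intercept_mmHg")
                  %in% repr$aggregate$metric))
  expect_true(report_mean(repr, "mae_pct") > 0)
})
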