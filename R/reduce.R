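#' Fit the normalization + PCA reducer on training features
#'
#' Features are z-scored with training-set means and SDs (constant features
#' are centered but scaled by 1, with a warning), then projected onto the
#' principal components with the largest eigenvalues. The retained count `k`
#' is the smallest number of components whose cumulative explained-variance
#' ratio reaches `variance_target`. Loading signs are fixed by making the
#' largest-magnitude element of each loading positive, which removes the
#' eigenvector sign ambiguity. The reducer is refit for every training-set
#' variant (each fold and each sub-sample), never on test data.
#'
#' @param train_features Numeric matrix, one row per training example.
#' @param variance_target Fraction of total variance to capture (default
#'   0.90).
#' @return An object of class `"fitted_reducer"`: list with `center`,
#'   `scale` (per-feature statistics), `loadings` (p x k), `k`,
#'   `cum_var_ratio`, and `eigenvalues`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' r <- fit_reducer(x)
#' dim(apply_reducer(r, x))
#' @export
fit_reducer <- function(train_features, variance_target = 0.90) {
  x <- as.matrix(train_features)
  if (nrow(x) < 2) stop("fit_reducer needs at least 2 rows", call. = FALSE)
  if (anyNA(x)) stop("fit_reducer requires complete features", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (any(const)) {
    warning(sum(const), " constant feature(s) scaled by 1: ",
            paste(utils::head(colnames(x)[const], 5), collapse = ", "),
            call. = FALSE)
    scl[const] <- 1
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- cumsum(ev) / sum(ev)
  k <- which(ratio >= variance_target)[1]
  if (is.na(k)) k <- length(ev)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude element of each loading positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  structure(list(center = ctr, scale = scl, loadings = load,
                 k = as.integer(k), cum_var_ratio = ratio[k],
                 eigenvalues = ev),
            class = "fitted_reducer")
}

#' @export
print.fitted_reducer <- function(x, ...) {
  cat(sprintf(
    "<fitted_reducer> %d features -> %d components (%.1f%% of variance)\n",
    length(x$center), x$k, 100 * x$cum_var_ratio))
  invisible(x)
}

#' Project features through a fitted reducer
#'
#' Applies the training-set normalization and loadings to new rows; training
#' and test data always pass through the identical transform.
#'
#' @param reducer A [fit_reducer()] result.
#' @param features Numeric matrix (or single vector) with the same columns
#'   as the training features.
#' @return Numeric matrix, `nrow(features)` x `reducer$k`.
#' @export
apply_reducer <- function(reducer, features) {
  x <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (ncol(x) != length(reducer$center)) {
    stop("feature count mismatch: reducer fitted on ",
         length(reducer$center), " columns, got ", ncol(x), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, reducer$center), 2, reducer$scale, "/")
  z %*% reducer$loadings
}
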