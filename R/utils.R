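# Internal helpers shared across the pipeline: scoped RNG, seed derivation,
# gap imputation for the uniform minute grid.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from a parent seed and one or more
# integer tags (record index, fold, sub-sample, ...). Linear congruential
# mixing keeps the result a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 48271 + as.numeric(t) + 1) %% 2147483647
  }
  as.integer(s)
}

# Fill missing values on a uniform grid: linear interpolation over interior
# gaps, nearest-value extension at the edges. Errors if everything is missing.
impute_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- !is.na(x)
  if (!any(ok)) stop("cannot impute an all-missing series", call. = FALSE)
  if (sum(ok) == 1L) return(rep(x[ok], length(x)))
  idx <- seq_along(x)
  stats::approx(idx[ok], x[ok], xout = idx, method = "linear", rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
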