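# Feed-forward 3-layer networks (k inputs -> 20 hidden -> 1 output) trained
# by full-batch Adam on the task loss, with a seeded random 20% validation
# split and early stopping. The classifier uses log-sigmoid activations in
# both layers so the output is a posterior probability; the regressor uses a
# tanh hidden layer and a linear output for unbounded swing.

logistic <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(p, hidden) {
  list(W1 = matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden),
       b1 = rep(0, hidden),
       W2 = matrix(stats::rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1),
       b2 = 0)
}

mlp_forward <- function(w, X, task) {
  A1 <- X %*% w$W1
  A1 <- sweep(A1, 2, w$b1, "+")
  H <- if (task == "classify") logistic(A1) else tanh(A1)
  out <- as.numeric(H %*% w$W2 + w$b2)
  if (task == "classify") out <- logistic(out)
  list(H = H, out = out)
}

mlp_loss <- function(out, y, task) {
  if (task == "classify") {
    eps <- 1e-12
    -mean(y * log(out + eps) + (1 - y) * log(1 - out + eps))
  } else {
    mean((out - y)^2)
  }
}

# Backprop gradients. For both losses the output-layer error simplifies to
# (out - y) (cross-entropy with logistic output; half-MSE scaled by 2 for
# the linear output).
mlp_grad <- function(w, X, y, fwd, task) {
  n <- nrow(X)
  delta_out <- (fwd$out - y) * (if (task == "classify") 1 else 2) / n
  dW2 <- t(fwd$H) %*% delta_out
  db2 <- sum(delta_out)
  dact <- if (task == "classify") fwd$H * (1 - fwd$H) else 1 - fwd$H^2
  delta_h <- (matrix(delta_out, ncol = 1) %*% t(w$W2)) * dact
  list(W1 = t(X) %*% delta_h, b1 = colSums(delta_h),
       W2 = dW2, b2 = db2)
}

mlp_train <- function(X, y, task, seed, hidden = 20L, max_epochs = 500L,
                      patience = 10L, learn_rate = 0.02, val_frac = 0.2) {
  X <- as.matrix(X)
  n <- nrow(X)
  with_seed(seed, {
    w <- mlp_init(ncol(X), hidden)
    n_val <- max(1L, round(val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

    m <- lapply(w, function(a) a * 0)
    v <- lapply(w, function(a) a * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(w = w, val = Inf, epoch = 0L)
    stall <- 0L
    epoch <- 0L
    stop_reason <- "max_epochs"
    val_final <- NA_real_
    while (epoch < max_epochs) {
      epoch <- epoch + 1L
      fwd <- mlp_forward(w, Xtr, task)
      g <- mlp_grad(w, Xtr, ytr, fwd, task)
      for (nm in names(w)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^epoch)
        vhat <- v[[nm]] / (1 - b2^epoch)
        w[[nm]] <- w[[nm]] - learn_rate * mhat / (sqrt(vhat) + eps)
      }
      val_final <- mlp_loss(mlp_forward(w, Xva, task)$out, yva, task)
      if (val_final < best$val - 1e-9) {
        best <- list(w = w, val = val_final, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) {
          stop_reason <- "early_stopping"
          break
        }
      }
    }
    list(weights = best$w, task = task,
         meta = list(seed = seed, epochs_run = epoch,
                     best_epoch = best$epoch, stop_reason = stop_reason,
                     val_loss_best = best$val, val_loss_final = val_final))
  })
}

#' Train the hypotension classifier
#'
#' Fits the 3-layer log-sigmoid network on reduced features with binary
#' labels (1 = hypotensive), using a seeded 20% validation split with early
#' stopping, then selects the decision threshold on the full training rows
#' by [select_threshold()].
#'
#' @param train_reduced Numeric matrix of reduced training features.
#' @param labels 0/1 vector (1 = hypotensive), both classes present.
#' @param seed Integer seed controlling initialization and the validation
#'   split.
#' @param hidden Hidden-layer width (default 20).
#' @param max_epochs,patience Training budget and early-stopping patience.
#' @return An object of class `"map_classifier"` with fields `weights`,
#'   `threshold` and `meta` (seed, epochs run, stopping reason, validation
#'   losses).
#' @export
train_classifier <- function(train_reduced, labels, seed = 1L,
                             hidden = 20L, max_epochs = 500L,
                             patience = 10L) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  fit <- mlp_train(train_reduced, y, "classify", seed, hidden, max_epochs,
                   patience)
  model <- structure(fit, class = "map_classifier")
  scores <- predict_probability(model, train_reduced)
  model$threshold <- select_threshold(scores, y)
  model
}

#' Select the decision threshold maximizing sensitivity + specificity
#'
#' Sweeps every distinct score (plus 0 and 1) as a candidate threshold and
#' returns the one maximizing `sensitivity(Th) + specificity(Th)`, with a
#' case called positive when its score is at or above the threshold. Ties go
#' to the smallest threshold, favoring sensitivity.
#'
#' @param scores Posterior probabilities in (0, 1).
#' @param labels 0/1 vector, both classes present.
#' @return The selected threshold, a value in \[0, 1\].
#' @export
select_threshold <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    stop("threshold selection needs both classes", call. = FALSE)
  }
  cand <- sort(unique(c(0, scores, 1)))
  P <- sum(y == 1); N <- sum(y == 0)
  sums <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & y == 1) / P + sum(!pred & y == 0) / N
  }, numeric(1))
  cand[which.max(sums)]
}

#' Posterior probability of impending hypotension
#'
#' Forward pass of a trained classifier; outputs lie strictly in (0, 1).
#' The hard decision rule is `probability >= model$threshold`.
#'
#' @param model A `map_classifier`.
#' @param reduced_rows Matrix (or single vector) of reduced features.
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(model, reduced_rows) {
  X <- if (is.null(dim(reduced_rows))) matrix(reduced_rows, nrow = 1)
       else as.matrix(reduced_rows)
  if (ncol(X) != nrow(model$weights$W1)) {
    stop("input dimension mismatch: model expects ",
         nrow(model$weights$W1), " columns, got ", ncol(X), call. = FALSE)
  }
  mlp_forward(model$weights, X, "classify")$out
}

#' Train the future-median-MAP regressor
#'
#' Same topology as the classifier with tanh hidden units and a linear
#' output, fit by mean squared error on standardized targets (the
#' prediction is de-standardized back to mmHg). Uses the same seeded 20%
#' validation split and early stopping.
#'
#' @param train_reduced Numeric matrix of reduced training features.
#' @param target_map Target-window median MAP per row (mmHg).
#' @inheritParams train_classifier
#' @return An object of class `"map_regressor"`.
#' @export
train_regressor <- function(train_reduced, target_map, seed = 1L,
                            hidden = 20L, max_epochs = 500L,
                            patience = 10L) {
  y <- as.numeric(target_map)
  if (length(y) < 10) {
    stop("regression training needs at least 10 rows", call. = FALSE)
  }
  y_ctr <- mean(y); y_scl <- stats::sd(y)
  if (!is.finite(y_scl) || y_scl == 0) {
    stop("degenerate (constant) regression targets", call. = FALSE)
  }
  fit <- mlp_train(train_reduced, (y - y_ctr) / y_scl, "regress", seed,
                   hidden, max_epochs, patience)
  fit$target_center <- y_ctr
  fit$target_scale <- y_scl
  structure(fit, class = "map_regressor")
}

#' Predicted target-window median MAP
#'
#' @param model A `map_regressor`.
#' @param reduced_rows Matrix (or single vector) of reduced features.
#' @return Numeric vector of MAP predictions in mmHg.
#' @export
predict_map <- function(model, reduced_rows) {
  X <- if (is.null(dim(reduced_rows))) matrix(reduced_rows, nrow = 1)
       else as.matrix(reduced_rows)
  if (ncol(X) != nrow(model$weights$W1)) {
    stop("input dimension mismatch: model expects ",
         nrow(model$weights$W1), " columns, got ", ncol(X), call. = FALSE)
  }
  mlp_forward(model$weights, X, "regress")$out * model$target_scale +
    model$target_center
}

#' @export
print.map_classifier <- function(x, ...) {
  cat(sprintf(
    "<map_classifier> %d -> %d -> 1 (log-sigmoid), threshold %.3f; %s after %d epochs\n",
    nrow(x$weights$W1), ncol(x$weights$W1), x$threshold,
    x$meta$stop_reason, x$meta$epochs_run))
  invisible(x)
}

#' @export
print.map_regressor <- function(x, ...) {
  cat(sprintf(
    "<map_regressor> %d -> %d -> 1 (tanh/linear); %s after %d epochs\n",
    nrow(x$weights$W1), ncol(x$weights$W1), x$meta$stop_reason,
    x$meta$epochs_run))
  invisible(x)
}
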