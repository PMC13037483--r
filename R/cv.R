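# Shared cross-validation machinery used by the GA fitness, sigma
# selection and leave-group-out validation.

# Shuffled contiguous fold assignment, deterministic given seed.
make_folds <- function(n, k, seed) {
  if (k < 2 || k > n) abort(sprintf("fold count must be in [2, %d]", n))
  withr::with_seed(seed, {
    ord <- sample.int(n)
  })
  # contiguous blocks over the shuffled order
  fold <- integer(n)
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold[ord] <- rep(seq_len(k), times = sizes)
  fold
}

# Fit one of the matrix-level estimators on raw (unscaled) X.
# spec: list(model = "pls"|"kpls", n_lv, sigma = NULL)
fit_matrix_model <- function(X, y, spec) {
  X <- as.matrix(X)
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0)) abort("zero-variance column in training fold")
  Xs <- scale_matrix(X, means, sds)
  n_lv <- min(spec$n_lv, ncol(X), nrow(X) - 1)
  if (identical(spec$model, "pls")) {
    y_mean <- mean(y)
    core <- nipals_pls(Xs, y - y_mean, n_lv = n_lv)
    list(predict = function(Xnew) {
      Xn <- scale_matrix(as.matrix(Xnew), means, sds)
      as.vector(Xn %*% core$coefficients) + y_mean
    })
  } else if (identical(spec$model, "kpls")) {
    sigma <- spec$sigma %||% median_pairwise_distance(Xs)
    K <- rbf_kernel(Xs, sigma = sigma)
    core <- kpls_fit(K, y, n_lv = n_lv)
    list(predict = function(Xnew) {
      Xn <- scale_matrix(as.matrix(Xnew), means, sds)
      Kt <- rbf_kernel(Xn, Xs, sigma = sigma)
      if (is.null(dim(Kt))) Kt <- matrix(Kt, nrow = 1)
      Ktc <- center_test_kernel(Kt, core$row_means, core$grand_mean)
      as.vector(Ktc %*% core$dual_coef) + core$y_mean
    })
  } else {
    abort(sprintf("unknown estimator '%s'", spec$model))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sum of squared out-of-fold prediction errors. The scaler is refit
# inside every fold so no held-out information leaks.
cv_press <- function(X, y, spec, fold_id) {
  press <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- fit_matrix_model(X[tr, , drop = FALSE], y[tr], spec)
    pred <- fit$predict(X[!tr, , drop = FALSE])
    press <- press + sum((y[!tr] - pred)^2)
  }
  press
}

#' Declare a model specification for cross-validation
#'
#' A lightweight description of an estimator, consumed by [lgo_cv()]
#' and the genetic-algorithm fitness.
#'
#' @param model `"pls"` or `"kpls"`.
#' @param n_lv Latent variables (capped automatically at the fold's
#'   achievable rank).
#' @param sigma Kernel width for `"kpls"`; `NULL` uses the median
#'   pairwise training distance of each fit.
#' @return A list of class `qsrr_model_spec`.
#' @export
model_spec <- function(model = c("pls", "kpls"), n_lv = 4, sigma = NULL) {
  model <- match.arg(model)
  structure(list(model = model, n_lv = n_lv, sigma = sigma),
            class = "qsrr_model_spec")
}
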