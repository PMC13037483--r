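#' NIPALS partial least squares on matrices
#'
#' Low-level engine: extracts `n_lv` latent variables from an autoscaled
#' predictor matrix and a centered response by NIPALS deflation. For a
#' single response the weight vector of each component is the (normalized)
#' covariance X'y, so extraction is exact and non-iterative.
#'
#' @param X Numeric matrix, n x K, columns autoscaled.
#' @param y Numeric length-n response, centered.
#' @param n_lv Number of latent variables, `0 <= n_lv <= min(n-1, K)`.
#' @param tol Collapse tolerance on the residual covariance norm.
#' @return List with `weights` (K x a), `loadings` (K x a),
#'   `y_loadings` (length a), `scores` (n x a), `coefficients`
#'   (length K, for centered/scaled data), `fitted` (length n,
#'   centered scale).
#' @export
nipals_pls <- function(X, y, n_lv, tol = 1e-12) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); K <- ncol(X)
  if (length(y) != n) abort("X and y have incompatible sizes")
  if (n_lv < 0 || n_lv > min(n - 1, K)) {
    abort(sprintf("n_lv must be in [0, %d]", min(n - 1, K)))
  }
  W <- P <- matrix(0, K, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xr <- X; yr <- y
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      abort(sprintf(
        "predictor covariance collapsed at component %d; achievable rank is %d",
        a, a - 1L))
    }
    w <- w / nw
    t_a <- as.vector(Xr %*% w)
    tt <- sum(t_a^2)
    if (tt < tol) {
      abort(sprintf(
        "score norm collapsed at component %d; achievable rank is %d",
        a, a - 1L))
    }
    p <- crossprod(Xr, t_a) / tt
    q_a <- sum(yr * t_a) / tt
    Xr <- Xr - tcrossprod(t_a, p)
    yr <- yr - q_a * t_a
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t_a; q[a] <- q_a
  }
  coef <- if (n_lv == 0) numeric(K) else {
    as.vector(W %*% solve(crossprod(P, W), q))
  }
  list(weights = W, loadings = P, y_loadings = q, scores = Tm,
       coefficients = coef, fitted = as.vector(X %*% coef))
}

#' Fit a PLS retention model
#'
#' Fits a NIPALS partial-least-squares regression of retention time on
#' the descriptor columns. Descriptors are autoscaled and the response
#' centered on the training rows (the rows labelled `"train"` when a
#' `partition` column is present, else all rows); latent variables
#' maximize descriptor-response covariance. The default of 4 latent
#' variables matches common practice for compact GC retention models.
#'
#' @param data Tibble with `compound`, response and descriptor columns.
#' @param response Name of the response column (minutes).
#' @param n_lv Number of latent variables.
#' @param id Identifier column name.
#' @return An object of class `qsrr_pls` with the fitted latent
#'   structure, coefficients in original descriptor units, and the
#'   training scaler. Supports [predict()][predict.qsrr_pls()],
#'   `tidy()` and `glance()`.
#' @examples
#' sim <- simulate_qsrr(n = 40, n_desc = 12, n_true = 3, seed = 3)
#' fit <- qsrr_pls(sim$data, n_lv = 3)
#' glance(fit)
#' @export
qsrr_pls <- function(data, response = "rt", n_lv = 4, id = "compound") {
  rows <- training_rows(data)
  scaler <- fit_scaler(data, rows = rows, response = response, id = id)
  X <- scale_matrix(as.matrix(data[rows, scaler$descriptors, drop = FALSE]),
                    scaler$means, scaler$sds)
  y <- data[[response]][rows]
  y_mean <- mean(y)
  core <- nipals_pls(X, y - y_mean, n_lv = n_lv)

  # coefficients on the original descriptor scale
  b_scaled <- core$coefficients
  b_orig <- b_scaled / scaler$sds
  intercept <- y_mean - sum(b_orig * scaler$means)

  structure(
    list(core = core, scaler = scaler, n_lv = n_lv,
         y_mean = y_mean, response = response, id = id,
         coefficients = stats::setNames(b_orig, scaler$descriptors),
         intercept = intercept,
         training_rows = rows,
         train_y = y,
         fitted = core$fitted + y_mean),
    class = "qsrr_pls"
  )
}

training_rows <- function(data) {
  if ("partition" %in% names(data)) {
    tr <- which(data$partition == "train")
    if (length(tr) >= 2) return(tr)
  }
  seq_len(nrow(data))
}

#' Predict retention times from a PLS model
#'
#' @param object A `qsrr_pls` model.
#' @param newdata Tibble containing the model's descriptor columns;
#'   defaults to predicting the training rows' stored fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted retention times (minutes).
#' @export
predict.qsrr_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nms <- object$scaler$descriptors
  missing <- setdiff(nms, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata lacks descriptor column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[nms])
  as.vector(X %*% object$coefficients) + object$intercept
}

#' @export
print.qsrr_pls <- function(x, ...) {
  cat(sprintf("PLS retention model: %d latent variables, %d descriptors, %d training compounds\n",
              x$n_lv, length(x$coefficients), length(x$training_rows)))
  invisible(x)
}

#' @describeIn qsrr_pls One row per descriptor with its regression
#'   coefficient (original units) and first-component weight.
#' @param x A fitted `qsrr_pls`.
#' @param ... Unused.
#' @export
tidy.qsrr_pls <- function(x, ...) {
  w1 <- if (x$n_lv >= 1) x$core$weights[, 1] else rep(NA_real_,
                                                      length(x$coefficients))
  tibble(descriptor = names(x$coefficients),
         coefficient = unname(x$coefficients),
         weight_lv1 = w1)
}

#' @describeIn qsrr_pls One-row model summary (n, descriptors, latent
#'   variables, training RMSE and R-squared).
#' @export
glance.qsrr_pls <- function(x, ...) {
  tibble(n = length(x$training_rows),
         n_descriptors = length(x$coefficients),
         n_lv = x$n_lv,
         train_rmse = sqrt(mean((x$train_y - x$fitted)^2)),
         train_r2 = 1 - sum((x$train_y - x$fitted)^2) /
           sum((x$train_y - mean(x$train_y))^2))
}
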