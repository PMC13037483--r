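#' Gaussian radial-basis-function kernel
#'
#' \eqn{k(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}: similarity
#' in (0, 1], equal to 1 exactly when the two descriptor vectors
#' coincide, with the width `sigma` controlling the degree of
#' nonlinearity.
#'
#' @param X Numeric matrix (rows are compounds) or a single vector.
#' @param Y Optional second matrix/vector; defaults to `X`.
#' @param sigma Kernel width, positive.
#' @return The kernel matrix `nrow(X) x nrow(Y)`.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(X, Y = NULL, sigma) {
  if (sigma <= 0) abort("sigma must be positive")
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  self <- is.null(Y)
  if (self) Y <- X
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  if (ncol(X) != ncol(Y)) abort("descriptor vectors have unequal length")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # numerical round-off
  if (self) diag(d2) <- 0  # self-similarity is exactly 1
  out <- exp(-d2 / (2 * sigma^2))
  if (nrow(out) == 1 && ncol(out) == 1) out <- out[1, 1]
  out
}

#' Kernel PLS on a precomputed kernel matrix
#'
#' Low-level engine: double-centers the training kernel, extracts
#' components by iterated score updates with deflation
#' `K <- (I - tt')K(I - tt')`, and returns the dual structure needed to
#' predict new compounds from their (centered) kernel rows.
#'
#' @param K Training kernel matrix, n x n, symmetric.
#' @param y Numeric response, length n (uncentered).
#' @param n_lv Number of latent variables, at most n - 1.
#' @param max_iter,tol Iteration cap and score-change tolerance per
#'   component.
#' @return List with `scores` (orthonormal columns), `y_scores`,
#'   `dual_coef` (length n), `y_mean`, `row_means`/`grand_mean`
#'   centering statistics, and `fitted` (response scale).
#' @export
kpls_fit <- function(K, y, n_lv, max_iter = 500, tol = 1e-10) {
  K <- as.matrix(K); y <- as.numeric(y)
  n <- nrow(K)
  if (ncol(K) != n || length(y) != n) abort("K and y have incompatible sizes")
  if (n_lv < 1 || n_lv > n - 1) abort(sprintf("n_lv must be in [1, %d]", n - 1))
  row_means <- colMeans(K)  # symmetric: row means = column means
  grand_mean <- mean(K)
  Kc <- K - matrix(row_means, n, n, byrow = TRUE) -
    matrix(row_means, n, n) + grand_mean
  y_mean <- mean(y)
  yr <- y - y_mean

  Tm <- matrix(0, n, n_lv)
  U <- matrix(0, n, n_lv)
  Kd <- Kc
  for (a in seq_len(n_lv)) {
    u <- yr
    if (sqrt(sum(u^2)) < tol) {
      abort(sprintf("response residual collapsed at component %d", a))
    }
    t_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      t_a <- as.vector(Kd %*% u)
      nt <- sqrt(sum(t_a^2))
      if (nt < tol) {
        abort(sprintf("kernel component %d collapsed (score norm ~ 0)", a))
      }
      t_a <- t_a / nt
      c_a <- sum(yr * t_a)
      u_new <- yr * c_a
      u_new <- u_new / sqrt(sum(u_new^2))
      if (sqrt(sum((t_a - t_old)^2)) < tol) { converged <- TRUE; u <- u_new; break }
      t_old <- t_a
      u <- u_new
    }
    if (!converged) {
      abort(sprintf("kernel PLS component %d did not converge in %d iterations",
                    a, max_iter))
    }
    Tm[, a] <- t_a
    U[, a] <- u
    proj <- diag(n) - tcrossprod(t_a)
    Kd <- proj %*% Kd %*% proj
    yr <- yr - t_a * sum(t_a * yr)
  }
  # dual regression coefficients: predictions = Kc_new %*% dual_coef + y_mean
  M <- crossprod(Tm, Kc %*% U)
  dual_coef <- as.vector(U %*% solve(M, crossprod(Tm, y - y_mean)))
  list(scores = Tm, y_scores = U, dual_coef = dual_coef,
       y_mean = y_mean, row_means = row_means, grand_mean = grand_mean,
       fitted = as.vector(Kc %*% dual_coef) + y_mean)
}

# Center kernel rows of new points against the training statistics.
center_test_kernel <- function(Kt, row_means, grand_mean) {
  n <- length(row_means)
  Kt - matrix(rowMeans(Kt), nrow(Kt), n) -
    matrix(row_means, nrow(Kt), n, byrow = TRUE) + grand_mean
}

#' Fit an RBF kernel PLS retention model
#'
#' Kernel partial least squares maps the autoscaled descriptor space
#' into the feature space induced by a Gaussian kernel and runs PLS
#' there, capturing smooth nonlinear descriptor-retention
#' relationships. The default of 3 latent variables matches compact
#' nonlinear GC retention models.
#'
#' @param data Tibble with `compound`, response and descriptor columns.
#' @param response Name of the response column (minutes).
#' @param sigma Kernel width in autoscaled descriptor units; default
#'   the median pairwise training distance (a standard heuristic), or
#'   choose by [choose_sigma()].
#' @param n_lv Number of latent variables.
#' @param id Identifier column name.
#' @return An object of class `qsrr_kpls` supporting `predict()` and
#'   `glance()`.
#' @export
qsrr_kpls <- function(data, response = "rt", sigma = NULL, n_lv = 3,
                      id = "compound") {
  rows <- training_rows(data)
  scaler <- fit_scaler(data, rows = rows, response = response, id = id)
  X <- scale_matrix(as.matrix(data[rows, scaler$descriptors, drop = FALSE]),
                    scaler$means, scaler$sds)
  y <- data[[response]][rows]
  if (is.null(sigma)) sigma <- median_pairwise_distance(X)
  K <- rbf_kernel(X, sigma = sigma)
  core <- kpls_fit(K, y, n_lv = n_lv)
  structure(
    list(core = core, scaler = scaler, sigma = sigma, n_lv = n_lv,
         training_matrix = X, train_y = y, training_rows = rows,
         response = response, id = id, fitted = core$fitted),
    class = "qsrr_kpls"
  )
}

median_pairwise_distance <- function(X) {
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) abort("degenerate descriptor distances: all compounds identical")
  m
}

#' Predict retention times from a kernel PLS model
#'
#' @param object A `qsrr_kpls` model.
#' @param newdata Tibble with the model's descriptor columns; default
#'   returns the stored training fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted retention times (minutes).
#' @export
predict.qsrr_kpls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nms <- object$scaler$descriptors
  missing <- setdiff(nms, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata lacks descriptor column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  Xs <- scale_matrix(as.matrix(newdata[nms]), object$scaler$means,
                     object$scaler$sds)
  Kt <- rbf_kernel(Xs, object$training_matrix, sigma = object$sigma)
  if (is.null(dim(Kt))) Kt <- matrix(Kt, nrow = 1)
  Ktc <- center_test_kernel(Kt, object$core$row_means,
                            object$core$grand_mean)
  as.vector(Ktc %*% object$core$dual_coef) + object$core$y_mean
}

#' @export
print.qsrr_kpls <- function(x, ...) {
  cat(sprintf("RBF kernel PLS retention model: sigma = %.4g, %d latent variables, %d descriptors\n",
              x$sigma, x$n_lv, length(x$scaler$descriptors)))
  invisible(x)
}

#' @describeIn qsrr_kpls One-row summary with sigma, latent variables
#'   and training fit.
#' @param x A fitted `qsrr_kpls`.
#' @param ... Unused.
#' @export
glance.qsrr_kpls <- function(x, ...) {
  tibble(n = length(x$train_y),
         n_descriptors = length(x$scaler$descriptors),
         n_lv = x$n_lv, sigma = x$sigma,
         train_rmse = sqrt(mean((x$train_y - x$fitted)^2)),
         train_r2 = 1 - sum((x$train_y - x$fitted)^2) /
           sum((x$train_y - mean(x$train_y))^2))
}

#' Choose the RBF kernel width by cross-validation
#'
#' Evaluates a grid of widths, each a multiplier of the median pairwise
#' training distance in autoscaled descriptor space, by k-fold
#' cross-validated RMSE of a kernel PLS model, and returns the width
#' minimizing RMSECV (ties broken toward the smaller width).
#'
#' @param data Tibble with `compound`, response and descriptor columns.
#' @param response Response column name.
#' @param grid Positive multipliers of the median pairwise distance.
#' @param n_lv Latent variables of the candidate models.
#' @param folds Fold count.
#' @param seed Integer seed for the fold assignment.
#' @param id Identifier column.
#' @return The selected `sigma` (absolute width, not the multiplier),
#'   with the evaluated grid as attribute `"grid"` (tibble of
#'   `multiplier`, `sigma`, `rmsecv`).
#' @export
choose_sigma <- function(data, response = "rt", grid = c(0.25, 0.5, 1, 2, 4),
                         n_lv = 3, folds = 5, seed = 1L, id = "compound") {
  if (length(grid) == 0) abort("sigma grid is empty")
  rows <- training_rows(data)
  scaler <- fit_scaler(data, rows = rows, response = response, id = id)
  X <- scale_matrix(as.matrix(data[rows, scaler$descriptors, drop = FALSE]),
                    scaler$means, scaler$sds)
  y <- data[[response]][rows]
  m <- median_pairwise_distance(X)
  sigmas <- sort(grid) * m
  fold_id <- make_folds(length(y), folds, seed)
  rmse <- vapply(sigmas, function(s) {
    press <- cv_press(X, y, spec = list(model = "kpls", n_lv = n_lv,
                                        sigma = s), fold_id = fold_id)
    sqrt(press / length(y))
  }, double(1))
  best <- which.min(rmse)  # which.min takes the first (smallest sigma) on ties
  out <- sigmas[best]
  attr(out, "grid") <- tibble(multiplier = sort(grid), sigma = sigmas,
                              rmsecv = rmse)
  out
}
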