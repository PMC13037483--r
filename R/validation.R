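#' Regression performance metrics for retention models
#'
#' Computes the standard QSRR metric suite for one set of predictions:
#' \itemize{
#'   \item MSE = sum((y - yhat)^2) / n, minutes squared
#'   \item RMSE = sqrt(MSE), minutes
#'   \item R2 = 1 - RSS/TSS
#'   \item adjusted R2 = 1 - (1 - R2)(n - 1)/(n - p - 1)
#'   \item SE = sample standard deviation of the residuals
#'     (n - 1 denominator), minutes
#'   \item Pearson r between experimental and predicted values
#' }
#'
#' @param y_exp Experimental retention times (minutes).
#' @param y_pred Predicted retention times (minutes).
#' @param p Number of independent variables entering the model (used
#'   by the adjusted R2 correction).
#' @return One-row tibble with columns `n`, `p`, `r2`, `adj_r2`,
#'   `rmse`, `se`, `mse`, `pearson_r`. `adj_r2` is `NA` with a warning
#'   when `n <= p + 1`; `pearson_r` is `NA` for constant predictions.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 1, 4), p = 1)
#' @export
regression_metrics <- function(y_exp, y_pred, p = 1L) {
  if (length(y_exp) != length(y_pred)) abort("unequal prediction lengths")
  n <- length(y_exp)
  if (n < 2) abort("at least two observations are required")
  resid <- y_exp - y_pred
  rss <- sum(resid^2)
  tss <- sum((y_exp - mean(y_exp))^2)
  if (tss == 0) abort("zero variance in y_exp: R2 is undefined")
  mse <- rss / n
  r2 <- 1 - rss / tss
  if (n > p + 1) {
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else {
    warn("n <= p + 1: adjusted R2 omitted")
    adj_r2 <- NA_real_
  }
  # constant predictions leave Pearson r undefined; report NA quietly
  pearson_r <- if (stats::sd(y_pred) == 0) NA_real_ else
    stats::cor(y_exp, y_pred)
  tibble(n = n, p = as.integer(p), r2 = r2, adj_r2 = adj_r2,
         rmse = sqrt(mse), se = stats::sd(resid), mse = mse,
         pearson_r = pearson_r)
}

#' Leave-group-out cross-validation
#'
#' Shuffles the rows into contiguous groups of about `group_size`
#' compounds, then refits the model (scaler included) with each group
#' held out in turn, predicting the held-out group. Reports
#' \eqn{Q^2 = 1 - PRESS/TSS} and \eqn{RMSECV = \sqrt{PRESS/n}}.
#'
#' @param data Tibble with `compound`, response and descriptor columns.
#' @param response Response column name.
#' @param spec A [model_spec()] describing the estimator to refit.
#' @param group_size Compounds per left-out group (default 7, within
#'   the conventional 5-10 range).
#' @param seed Integer seed for the random grouping.
#' @param id Identifier column.
#' @return Object of class `qsrr_cv`: list with `predictions` (tibble
#'   `id`, `group`, `y_exp`, `y_pred`), `q2`, `rmsecv`, `group_size`,
#'   `seed`.
#' @export
lgo_cv <- function(data, response = "rt", spec = model_spec("pls"),
                   group_size = 7L, seed = 1L, id = "compound") {
  n <- nrow(data)
  if (n < 2 * group_size) {
    abort(sprintf("need at least %d rows for group_size = %d",
                  2 * group_size, group_size))
  }
  nms <- descriptor_names(data, response = response, id = id)
  X <- as.matrix(data[nms])
  y <- data[[response]]
  k <- ceiling(n / group_size)
  fold_id <- make_folds(n, k, seed)
  y_pred <- rep(NA_real_, n)
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- tryCatch(
      fit_matrix_model(X[tr, , drop = FALSE], y[tr], spec),
      error = function(e) abort(sprintf("model failed in fold %d: %s",
                                        f, conditionMessage(e))))
    y_pred[!tr] <- fit$predict(X[!tr, , drop = FALSE])
  }
  press <- sum((y - y_pred)^2)
  tss <- sum((y - mean(y))^2)
  ids <- if (id %in% names(data)) as.character(data[[id]]) else
    as.character(seq_len(n))
  structure(
    list(predictions = tibble(id = ids, group = fold_id, y_exp = y,
                              y_pred = y_pred),
         q2 = 1 - press / tss, rmsecv = sqrt(press / n),
         group_size = group_size, seed = seed, spec = spec),
    class = "qsrr_cv"
  )
}

#' @export
print.qsrr_cv <- function(x, ...) {
  cat(sprintf("Leave-group-out CV (%s, groups of ~%d): Q2 = %.4f, RMSECV = %.4f min\n",
              x$spec$model, x$group_size, x$q2, x$rmsecv))
  invisible(x)
}

#' @describeIn lgo_cv One-row summary (`q2`, `rmsecv`, `n`,
#'   `group_size`).
#' @param x A `qsrr_cv` object.
#' @param ... Unused.
#' @export
glance.qsrr_cv <- function(x, ...) {
  tibble(n = nrow(x$predictions), group_size = x$group_size,
         q2 = x$q2, rmsecv = x$rmsecv)
}

#' Evaluate a fitted model on training and test partitions
#'
#' Produces the train/test metric blocks (all six metrics) and the
#' full residual table (`e = y_exp - y_pred`, minutes) for a fitted
#' retention model on a partitioned dataset.
#'
#' @param model A fitted `qsrr_pls`, `qsrr_kpls` or `qsrr_ann` model.
#' @param data Partitioned tibble the model applies to (a `partition`
#'   column over train/val/test; `val` rows are reported with the
#'   training block's residuals but contribute to no metric block).
#' @param response Response column name.
#' @param p Number of independent variables; default the model's
#'   descriptor count.
#' @param id Identifier column.
#' @return Object of class `qsrr_eval`: list with `metrics` (tibble,
#'   one row per partition) and `residuals` (tibble `id`, `y_exp`,
#'   `y_pred`, `residual`, `partition`).
#' @export
evaluate_model <- function(model, data, response = "rt", p = NULL,
                           id = "compound") {
  if (!"partition" %in% names(data)) {
    data$partition <- "train"
  }
  if (is.null(p)) {
    p <- length(if (inherits(model, "qsrr_ann")) model$scaler$descriptors
                else model$scaler$descriptors)
  }
  y_pred <- stats::predict(model, data)
  res <- tibble(
    id = if (id %in% names(data)) as.character(data[[id]]) else
      as.character(seq_len(nrow(data))),
    y_exp = data[[response]],
    y_pred = y_pred,
    residual = data[[response]] - y_pred,
    partition = data$partition
  )
  metrics <- dplyr::bind_rows(lapply(c("train", "test"), function(pt) {
    rows <- res$partition == pt
    if (!any(rows)) {
      if (pt == "test") warn("empty test partition: test block omitted")
      return(NULL)
    }
    dplyr::mutate(regression_metrics(res$y_exp[rows], res$y_pred[rows],
                                     p = p),
                  partition = pt, .before = 1)
  }))
  structure(list(metrics = metrics, residuals = res, p = p),
            class = "qsrr_eval")
}

#' @export
print.qsrr_eval <- function(x, ...) {
  cat("Model evaluation:\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @describeIn evaluate_model The metric blocks as a tibble.
#' @param x A `qsrr_eval` object.
#' @param ... Unused.
#' @export
tidy.qsrr_eval <- function(x, ...) x$metrics

#' Permutation (y-scrambling) check of cross-validated fitness
#'
#' Refits the leave-group-out CV after randomly permuting the response,
#' repeated `n_perm` times. A sound model's Q2 collapses to about or
#' below zero under scrambling; values comparable to the unscrambled
#' Q2 indicate chance correlation.
#'
#' @inheritParams lgo_cv
#' @param n_perm Number of permutations.
#' @return Tibble with one row per permutation (`perm`, `q2`,
#'   `rmsecv`).
#' @export
y_scramble <- function(data, response = "rt", spec = model_spec("pls"),
                       group_size = 7L, seed = 1L, n_perm = 20L,
                       id = "compound") {
  purrr::map_dfr(seq_len(n_perm), function(i) {
    perm_seed <- derive_seed(seed, "scramble", i)
    d <- data
    withr::with_seed(perm_seed, {
      d[[response]] <- sample(d[[response]])
    })
    cv <- lgo_cv(d, response = response, spec = spec,
                 group_size = group_size,
                 seed = derive_seed(seed, "scramble_folds", i), id = id)
    tibble(perm = i, q2 = cv$q2, rmsecv = cv$rmsecv)
  })
}
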