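#' Configuration for the Levenberg-Marquardt neural network
#'
#' Defaults follow compact QSRR practice: hidden sizes scanned from 2
#' to 10, at most 150 training epochs (hard cap 200 for the scan),
#' early stopping after 10 epochs without validation improvement, an
#' initial damping of 0.01 adapted by factors 10 / 0.1, and 15
#' independent restarts for stability statistics.
#'
#' @param hidden_range Integer vector of hidden sizes to scan.
#' @param max_epochs Training epoch limit (capped at 200).
#' @param patience Early-stopping patience, epochs.
#' @param lambda0 Initial Levenberg-Marquardt damping.
#' @param lambda_up,lambda_down Damping multipliers on rejected /
#'   accepted steps.
#' @param n_restarts Number of independently seeded trainings.
#' @return A list of class `qsrr_ann_config`.
#' @export
ann_config <- function(hidden_range = 2:10, max_epochs = 150, patience = 10,
                       lambda0 = 0.01, lambda_up = 10, lambda_down = 0.1,
                       n_restarts = 15) {
  if (length(hidden_range) == 0) abort("hidden_range is empty")
  if (any(hidden_range < 1 | hidden_range > 50)) {
    abort("hidden sizes must be within [1, 50]")
  }
  if (patience < 1) abort("patience must be at least 1")
  if (lambda0 <= 0) abort("lambda0 must be positive")
  max_epochs <- min(max_epochs, 200L)
  structure(list(hidden_range = as.integer(hidden_range),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lambda0 = lambda0, lambda_up = lambda_up,
                 lambda_down = lambda_down,
                 n_restarts = as.integer(n_restarts)),
            class = "qsrr_ann_config")
}

# ---- parameter packing -------------------------------------------------

ann_n_params <- function(d, h) h * (d + 1) + (h + 1)

ann_unpack <- function(w, d, h) {
  n1 <- h * (d + 1)
  list(W1 = matrix(w[seq_len(n1)], h, d + 1),
       w2 = w[n1 + seq_len(h + 1)])
}

ann_pack <- function(W1, w2) c(as.vector(W1), w2)

#' Forward pass of the perceptron
#'
#' Computes `w2 . [1, tanh(W1 [1, x])]` for each row of `X`: one tanh
#' hidden layer, linear output.
#'
#' @param net List with `W1` (h x (d+1), bias first column) and `w2`
#'   (length h+1, bias first), as stored in a fitted `qsrr_ann`.
#' @param X Numeric matrix of autoscaled descriptors, n x d, or a
#'   single descriptor vector.
#' @return Numeric vector of network outputs.
#' @export
ann_forward <- function(net, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  d <- ncol(net$W1) - 1L
  if (ncol(X) != d) {
    abort(sprintf("input has %d columns but the network expects %d",
                  ncol(X), d))
  }
  A <- cbind(1, X)
  H <- tanh(A %*% t(net$W1))
  as.vector(cbind(1, H) %*% net$w2)
}

# Analytic Jacobian of the outputs with respect to the packed weights.
ann_jacobian <- function(net, X) {
  A <- cbind(1, X)
  H <- tanh(A %*% t(net$W1))
  h <- nrow(net$W1)
  w2out <- net$w2[-1]
  G <- (1 - H^2) * matrix(w2out, nrow(X), h, byrow = TRUE)
  J1 <- do.call(cbind, lapply(seq_len(ncol(A)), function(k) G * A[, k]))
  cbind(J1, 1, H)
}

#' Train the perceptron by Levenberg-Marquardt
#'
#' Full-batch damped Gauss-Newton: each epoch solves
#' `(J'J + lambda I) dw = J'e` on the training set, accepting the step
#' (and shrinking the damping) only if the training SSE decreases,
#' otherwise inflating the damping and retrying. Validation RMSE is
#' tracked every epoch; training stops at the epoch limit, when the
#' validation error has not improved for `patience` epochs, or when no
#' step can be accepted before the damping overflows (a converged
#' stall, not an error). The returned weights are those of the best
#' validation epoch.
#'
#' @param X_train,X_val Autoscaled descriptor matrices.
#' @param y_train,y_val Responses (minutes).
#' @param hidden Hidden-layer size.
#' @param config An [ann_config()].
#' @param seed Integer seed for the U(-0.5, 0.5) weight
#'   initialization.
#' @return List of class `qsrr_ann_net`: `W1`, `w2`, `hidden`,
#'   `best_val_rmse`, `epochs_run`, `stalled`, `trace` (tibble with
#'   per-epoch `train_rmse`, `val_rmse`, `lambda`), `seed`.
#' @export
train_ann <- function(X_train, y_train, X_val, y_val, hidden,
                      config = ann_config(), seed = 1L) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  d <- ncol(X_train)
  n_par <- ann_n_params(d, hidden)
  w <- withr::with_seed(seed, stats::runif(n_par, -0.5, 0.5))
  net <- ann_unpack(w, d, hidden)

  sse <- sum((y_train - ann_forward(net, X_train))^2)
  if (!is.finite(sse)) abort("non-finite training loss at initialization")
  lambda <- config$lambda0
  best_val <- Inf
  best_w <- w
  best_epoch <- 0L
  wait <- 0L
  stalled <- FALSE
  trace <- vector("list", config$max_epochs)
  epochs_run <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    e <- y_train - ann_forward(net, X_train)
    J <- ann_jacobian(net, X_train)
    JtJ <- crossprod(J)
    Jte <- crossprod(J, e)
    accepted <- FALSE
    repeat {
      delta <- tryCatch(solve(JtJ + diag(lambda, n_par), Jte),
                        error = function(err) NULL)
      if (!is.null(delta)) {
        w_new <- w + as.vector(delta)
        net_new <- ann_unpack(w_new, d, hidden)
        sse_new <- sum((y_train - ann_forward(net_new, X_train))^2)
        if (!is.finite(sse_new)) abort("non-finite training loss")
        if (sse_new < sse) {
          w <- w_new; net <- net_new; sse <- sse_new
          lambda <- max(lambda * config$lambda_down, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * config$lambda_up
      if (lambda > 1e10) break
    }
    if (!accepted) { stalled <- TRUE; break }
    epochs_run <- epoch
    val_rmse <- sqrt(mean((y_val - ann_forward(net, X_val))^2))
    trace[[epoch]] <- tibble(epoch = epoch,
                             train_rmse = sqrt(sse / length(y_train)),
                             val_rmse = val_rmse, lambda = lambda)
    if (val_rmse < best_val) {
      best_val <- val_rmse; best_w <- w; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  best_net <- ann_unpack(best_w, d, hidden)
  structure(
    list(W1 = best_net$W1, w2 = best_net$w2, hidden = as.integer(hidden),
         best_val_rmse = best_val, best_epoch = best_epoch,
         epochs_run = epochs_run, stalled = stalled,
         trace = dplyr::bind_rows(trace[seq_len(epochs_run)]),
         seed = seed),
    class = "qsrr_ann_net"
  )
}

#' Scan hidden-layer sizes on the validation set
#'
#' Trains each candidate size with a reduced number of restarts (at
#' least 3) and selects the size with the lowest median validation
#' RMSE, breaking ties toward fewer neurons.
#'
#' @inheritParams train_ann
#' @param config An [ann_config()]; `hidden_range` defines the scan.
#' @return List with `best_hidden` and `table` (tibble of `hidden`,
#'   `median_val_rmse`, `median_val_r2`).
#' @export
select_hidden <- function(X_train, y_train, X_val, y_val,
                          config = ann_config(), seed = 1L) {
  scan_restarts <- max(3L, config$n_restarts %/% 5L)
  tss_val <- sum((y_val - mean(y_val))^2)
  rows <- purrr::map_dfr(config$hidden_range, function(h) {
    vals <- vapply(seq_len(scan_restarts), function(r) {
      fit <- train_ann(X_train, y_train, X_val, y_val, hidden = h,
                       config = config,
                       seed = derive_seed(seed, "scan", h * 1000L + r))
      fit$best_val_rmse
    }, double(1))
    med <- stats::median(vals)
    tibble(hidden = h, median_val_rmse = med,
           median_val_r2 = 1 - (med^2 * length(y_val)) / tss_val)
  })
  best <- rows$hidden[which.min(rows$median_val_rmse)]
  list(best_hidden = best, table = rows)
}

#' Multi-restart training for stability assessment
#'
#' Repeats the full training with independently derived seeds and
#' returns the model with the lowest validation RMSE together with the
#' per-restart table and its mean and standard deviation.
#'
#' @inheritParams train_ann
#' @return List with `best` (a `qsrr_ann_net`), `table` (tibble of
#'   `restart`, `seed`, `hidden`, `epochs`, `train_rmse`, `val_rmse`)
#'   and `summary` (mean and sd of both RMSE columns).
#' @export
ann_restarts <- function(X_train, y_train, X_val, y_val, hidden,
                         config = ann_config(), seed = 1L) {
  fits <- lapply(seq_len(config$n_restarts), function(r) {
    train_ann(X_train, y_train, X_val, y_val, hidden = hidden,
              config = config, seed = derive_seed(seed, "restart", r))
  })
  table <- purrr::map_dfr(seq_along(fits), function(r) {
    f <- fits[[r]]
    tibble(restart = r, seed = f$seed, hidden = f$hidden,
           epochs = f$epochs_run,
           train_rmse = if (nrow(f$trace) > 0)
             f$trace$train_rmse[f$best_epoch] else NA_real_,
           val_rmse = f$best_val_rmse)
  })
  best <- fits[[which.min(table$val_rmse)]]
  summary <- tibble(
    metric = c("train_rmse", "val_rmse"),
    mean = c(mean(table$train_rmse), mean(table$val_rmse)),
    sd = c(stats::sd(table$train_rmse), stats::sd(table$val_rmse))
  )
  list(best = best, table = table, summary = summary)
}

#' Fit a neural-network retention model
#'
#' High-level interface: autoscales descriptors on the training rows,
#' splits off a validation set when the partition lacks one
#' (stratified on the response), optionally scans hidden sizes, then
#' trains with multi-restart stability and keeps the best-validation
#' network.
#'
#' @param data Tibble with `compound`, response and descriptor
#'   columns. A `partition` column over train/val/test is used as
#'   given; if absent, a stratified 70/15/15 split is drawn; if it has
#'   no `"val"` rows, 15\% of the training rows are moved to
#'   validation.
#' @param response Response column name.
#' @param hidden Hidden-layer size; `NULL` scans `config$hidden_range`.
#' @param config An [ann_config()].
#' @param seed Master seed for splitting, initialization and restarts.
#' @param id Identifier column.
#' @return Object of class `qsrr_ann` with the best network, its
#'   scaler, the restart table, the architecture-scan table (when
#'   scanned) and the partitioned data actually used. Supports
#'   `predict()` and `glance()`.
#' @export
qsrr_ann <- function(data, response = "rt", hidden = NULL,
                     config = ann_config(), seed = 1L, id = "compound") {
  if (!"partition" %in% names(data)) {
    data <- make_partition(data, "stratified_70_15_15", response = response,
                           seed = derive_seed(seed, "split"))
  } else if (!"val" %in% data$partition) {
    data <- carve_validation(data, response, derive_seed(seed, "carve"))
  }
  tr <- which(data$partition == "train")
  va <- which(data$partition == "val")
  scaler <- fit_scaler(data, rows = tr, response = response, id = id)
  Xall <- scale_matrix(as.matrix(data[scaler$descriptors]),
                       scaler$means, scaler$sds)
  y <- data[[response]]
  scan <- NULL
  if (is.null(hidden)) {
    scan <- select_hidden(Xall[tr, , drop = FALSE], y[tr],
                          Xall[va, , drop = FALSE], y[va],
                          config = config, seed = seed)
    hidden <- scan$best_hidden
  }
  runs <- ann_restarts(Xall[tr, , drop = FALSE], y[tr],
                       Xall[va, , drop = FALSE], y[va],
                       hidden = hidden, config = config, seed = seed)
  structure(
    list(net = runs$best, scaler = scaler, hidden = as.integer(hidden),
         restarts = runs$table, restart_summary = runs$summary,
         scan = scan, config = config, seed = seed,
         data = data, response = response, id = id,
         train_y = y[tr], training_rows = tr,
         fitted = ann_forward(runs$best, Xall[tr, , drop = FALSE])),
    class = "qsrr_ann"
  )
}

# Move ~15% of training rows to validation, stratified on the response.
carve_validation <- function(data, response, seed) {
  tr <- which(data$partition == "train")
  n_val <- max(2L, round(0.15 * nrow(data)))
  ord <- tr[order(data[[response]][tr])]
  strata <- split(ord, ceiling(seq_along(ord) / ceiling(length(ord) / n_val)))
  withr::with_seed(seed, {
    picks <- vapply(strata, function(s) s[sample.int(length(s), 1L)],
                    integer(1))
  })
  data$partition[picks[seq_len(min(n_val, length(picks)))]] <- "val"
  data
}

#' Predict retention times from a neural-network model
#'
#' @param object A fitted `qsrr_ann`.
#' @param newdata Tibble with the model's descriptor columns; default
#'   returns the stored training fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted retention times (minutes).
#' @export
predict.qsrr_ann <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nms <- object$scaler$descriptors
  missing <- setdiff(nms, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata lacks descriptor column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  Xs <- scale_matrix(as.matrix(newdata[nms]), object$scaler$means,
                     object$scaler$sds)
  ann_forward(object$net, Xs)
}

#' @export
print.qsrr_ann <- function(x, ...) {
  d <- length(x$scaler$descriptors)
  cat(sprintf("LM-ANN retention model: %d-%d-1 topology (%d weights), best validation RMSE %.4f min over %d restarts\n",
              d, x$hidden, ann_n_params(d, x$hidden),
              x$net$best_val_rmse, nrow(x$restarts)))
  invisible(x)
}

#' @describeIn qsrr_ann One-row summary (topology, parameter count,
#'   restart mean and sd of validation RMSE).
#' @param x A fitted `qsrr_ann`.
#' @param ... Unused.
#' @export
glance.qsrr_ann <- function(x, ...) {
  d <- length(x$scaler$descriptors)
  tibble(n_train = length(x$train_y), n_inputs = d, hidden = x$hidden,
         n_params = ann_n_params(d, x$hidden),
         best_val_rmse = x$net$best_val_rmse,
         val_rmse_mean = x$restart_summary$mean[2],
         val_rmse_sd = x$restart_summary$sd[2],
         train_rmse = sqrt(mean((x$train_y - x$fitted)^2)))
}

#' Perturbation sensitivity analysis of descriptor influence
#'
#' Perturbs each autoscaled descriptor column multiplicatively by
#' -10\%, -5\%, +5\% and +10\% with the others fixed, and records the
#' mean absolute change in predicted retention time over compounds and
#' model realizations. Because the perturbation is multiplicative in
#' standardized space, entries at exactly the training mean
#' (standardized value 0) contribute zero change.
#'
#' @param models A list of `qsrr_ann_net` networks (or `qsrr_ann`
#'   fits, whose networks are extracted), all with the same input
#'   dimension.
#' @param X Autoscaled descriptor matrix on which to evaluate.
#' @param deltas Relative perturbations (default \code{c(-0.10, -0.05,
#'   0.05, 0.10)}).
#' @param descriptors Optional descriptor names for the output.
#' @return Tibble of class `qsrr_sensitivity`: one row per descriptor
#'   with the mean absolute predicted-RT change at each perturbation,
#'   their overall mean (`mean_abs_change`, minutes) and the
#'   importance `rank` (1 = most influential).
#' @export
ann_sensitivity <- function(models, X, deltas = c(-0.10, -0.05, 0.05, 0.10),
                            descriptors = NULL) {
  if (!is.list(models) || length(models) == 0) abort("need at least one model")
  nets <- lapply(models, function(m) {
    if (inherits(m, "qsrr_ann")) m$net else m
  })
  X <- as.matrix(X)
  if (nrow(X) == 0) abort("X is empty")
  d <- ncol(X)
  sens <- matrix(0, d, length(deltas))
  for (net in nets) {
    base <- ann_forward(net, X)
    for (j in seq_len(d)) {
      for (k in seq_along(deltas)) {
        Xp <- X
        Xp[, j] <- X[, j] * (1 + deltas[k])
        sens[j, k] <- sens[j, k] + mean(abs(ann_forward(net, Xp) - base))
      }
    }
  }
  sens <- sens / length(nets)
  out <- as_tibble(sens, .name_repair = ~ sprintf(
    "delta_%s", sub("-", "m", format(deltas * 100, trim = TRUE))))
  out <- dplyr::mutate(
    out,
    descriptor = descriptors %||% colnames(X) %||% sprintf("x%d", seq_len(d)),
    mean_abs_change = rowMeans(sens),
    rank = rank(-rowMeans(sens), ties.method = "first"),
    .before = 1)
  class(out) <- c("qsrr_sensitivity", class(out))
  out
}
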