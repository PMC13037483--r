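#' Simulate a descriptor matrix with known ground truth
#'
#' Generates a high-dimensional, block-correlated descriptor matrix with
#' a retention-time response driven by a small informative subset, the
#' statistical structure a QSRR descriptor-selection benchmark needs:
#' equicorrelated Gaussian blocks (shared-factor construction
#' \eqn{x = \sqrt{\rho} z_{block} + \sqrt{1-\rho}\,\epsilon}), exactly
#' one informative column per distinct block, a linear or smooth
#' nonlinear response surface affinely rescaled into a realistic
#' retention-time range before Gaussian noise is added, and injected
#' constant and near-constant columns that the pre-treatment stage must
#' catch.
#'
#' The last `n_constant + n_near_constant` of the `n_desc` columns are
#' the injected degenerate columns; informative columns are drawn from
#' the correlated blocks that fill the remaining columns.
#'
#' @param n Number of compounds (rows).
#' @param n_desc Total number of descriptor columns, including injected
#'   degenerate columns.
#' @param n_true Number of informative descriptors.
#' @param block_size Width of each equicorrelated block.
#' @param rho Within-block correlation, in [0, 1).
#' @param surface `"linear"` (y = X beta) or `"nonlinear"`
#'   (y = sum beta_j tanh(x_j) plus one pairwise interaction among the
#'   informative columns).
#' @param noise_sd Gaussian response noise, minutes.
#' @param n_constant Number of injected zero-variance columns.
#' @param n_near_constant Number of injected columns whose modal value
#'   occupies more than 95\% of rows.
#' @param rt_range Length-2 numeric: the retention-time range (minutes)
#'   the noiseless response is rescaled into.
#' @param seed Integer seed; the same spec and seed reproduce the
#'   dataset bitwise.
#' @return An object of class `qsrr_sim`: a list with `data` (tibble
#'   with `compound`, `rt` and descriptor columns `D001`...),
#'   `truth` (tibble `descriptor`, `is_true`, `coefficient`),
#'   `rt_noiseless`, `rescale` (intercept/slope of the affine map),
#'   `interaction` (nonlinear surface only), and the generating
#'   parameters.
#' @examples
#' sim <- simulate_qsrr(n = 30, n_desc = 20, n_true = 3, seed = 1)
#' dplyr::filter(sim$truth, is_true)
#' @export
simulate_qsrr <- function(n = 75, n_desc = 200, n_true = 7, block_size = 5,
                          rho = 0.9, surface = c("linear", "nonlinear"),
                          noise_sd = 0.03, n_constant = 3,
                          n_near_constant = 3, rt_range = c(0.9, 2.2),
                          seed = 1L) {
  surface <- match.arg(surface)
  if (n_true < 1) abort("n_true must be at least 1")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (rt_range[1] >= rt_range[2]) abort("rt_range must be increasing")
  K_blocks <- n_desc - n_constant - n_near_constant
  if (K_blocks < n_true) abort("n_desc too small for the requested columns")
  n_blocks <- ceiling(K_blocks / block_size)
  if (n_true > n_blocks) {
    abort(sprintf(
      "n_true (%d) exceeds the number of correlated blocks (%d); %s",
      n_true, n_blocks, "increase n_desc or reduce block_size"))
  }

  withr::with_seed(seed, {
    block_id <- rep(seq_len(n_blocks), each = block_size)[seq_len(K_blocks)]
    Z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    E <- matrix(stats::rnorm(n * K_blocks), n, K_blocks)
    X <- sqrt(rho) * Z[, block_id, drop = FALSE] + sqrt(1 - rho) * E

    # one informative column per distinct block
    true_blocks <- sort(sample.int(n_blocks, n_true))
    true_idx <- vapply(true_blocks,
                       function(b) {
                         cols <- which(block_id == b)
                         cols[sample.int(length(cols), 1L)]
                       }, integer(1))
    beta <- stats::runif(n_true, 0.5, 1.5) *
      sample(c(-1, 1), n_true, replace = TRUE)

    interaction <- NULL
    if (surface == "linear") {
      y0 <- as.vector(X[, true_idx, drop = FALSE] %*% beta)
    } else {
      y0 <- as.vector(tanh(X[, true_idx, drop = FALSE]) %*% beta)
      if (n_true >= 2) {
        ab <- sample(seq_len(n_true), 2L)
        gamma <- 0.5
        y0 <- y0 + gamma * X[, true_idx[ab[1]]] * X[, true_idx[ab[2]]]
        interaction <- list(cols = true_idx[ab], gamma = gamma)
      }
    }

    rng <- range(y0)
    if (diff(rng) <= 0) abort("degenerate response surface")
    slope <- diff(rt_range) / diff(rng)
    intercept <- rt_range[1] - slope * rng[1]
    y_clean <- intercept + slope * y0
    y <- y_clean + stats::rnorm(n, 0, noise_sd)

    # degenerate columns, appended last
    X_const <- matrix(rep(stats::runif(n_constant, -1, 1), each = n),
                      n, max(n_constant, 0))
    X_nc <- matrix(0, n, max(n_near_constant, 0))
    for (j in seq_len(n_near_constant)) {
      v <- rep(stats::runif(1, -1, 1), n)
      n_jitter <- max(1L, floor(0.04 * n))  # modal frequency > 95%
      rows <- sample.int(n, n_jitter)
      v[rows] <- v[rows] + stats::rnorm(n_jitter, 0, 0.05)
      X_nc[, j] <- v
    }
    full <- cbind(X, X_const, X_nc)
  })

  dn <- sprintf("D%03d", seq_len(n_desc))
  colnames(full) <- dn
  is_true <- rep(FALSE, n_desc)
  is_true[true_idx] <- TRUE
  coef_full <- rep(0, n_desc)
  coef_full[true_idx] <- beta

  data <- dplyr::bind_cols(
    tibble(compound = sprintf("C%03d", seq_len(n)), rt = y),
    as_tibble(full)
  )
  structure(
    list(data = data,
         truth = tibble(descriptor = dn, is_true = is_true,
                        coefficient = coef_full),
         rt_noiseless = y_clean,
         rescale = c(intercept = intercept, slope = slope),
         interaction = interaction,
         surface = surface, noise_sd = noise_sd, rho = rho,
         block_size = block_size, n_true = n_true, seed = seed),
    class = "qsrr_sim"
  )
}

#' @export
print.qsrr_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic QSRR dataset: %d compounds x %d descriptors (%d informative)\n",
    nrow(x$data), nrow(x$truth), x$n_true))
  cat(sprintf("surface: %s, within-block rho = %.2f, noise sd = %.3f min\n",
              x$surface, x$rho, x$noise_sd))
  invisible(x)
}

#' Score a selected descriptor set against the simulation truth
#'
#' @param sim A `qsrr_sim` object.
#' @param selected Character vector of selected descriptor names.
#' @return One-row tibble with `tp`, `fp`, `fn` and the `jaccard` index
#'   of the selected set against the informative set.
#' @export
selection_recovery <- function(sim, selected) {
  stopifnot(inherits(sim, "qsrr_sim"))
  unknown <- setdiff(selected, sim$truth$descriptor)
  if (length(unknown) > 0) {
    abort(sprintf("unknown descriptor name(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  truth <- sim$truth$descriptor[sim$truth$is_true]
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  un <- length(union(selected, truth))
  tibble(tp = tp, fp = fp, fn = fn,
         jaccard = if (un == 0) 0 else tp / un)
}

#' Write a simulated dataset and its truth sidecar
#'
#' Emits the dataset in the package CSV dialect plus a
#' `*_truth.csv` sidecar (`descriptor`, `is_true`, `coefficient`).
#'
#' @param sim A `qsrr_sim` object.
#' @param path Output CSV path for the data table.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "qsrr_sim"))
  write_descriptor_table(sim$data, path)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.csv")
  readr::write_csv(sim$truth, truth_path, progress = FALSE)
  invisible(path)
}
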