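#' Descriptor pre-treatment
#'
#' Removes degenerate and redundant descriptors before modelling, in
#' three passes: (1) zero-variance columns; (2) near-constant columns,
#' defined as a modal value occupying at least `near_constant_fraction`
#' of rows; (3) one member of every descriptor pair whose absolute
#' Pearson correlation exceeds `r_threshold`. By default the member
#' kept is the one more correlated (in absolute value) with the
#' response; with `response_aware = FALSE` the earlier column is kept.
#' When a `partition` column is present, correlations are computed on
#' training rows only so no test-set information leaks into the filter.
#'
#' @param data Tibble with `compound`, response and descriptor columns.
#' @param response Name of the response column.
#' @param r_threshold Absolute-correlation threshold above which a pair
#'   is considered redundant (default 0.90).
#' @param near_constant_fraction Modal-frequency threshold defining a
#'   near-constant column (default 0.95).
#' @param response_aware Keep the pair member more correlated with the
#'   response (default `TRUE`).
#' @param id Name of the identifier column.
#' @return An object of class `qsrr_pretreat`: a list with the reduced
#'   `data` tibble and report fields `removed_constant`,
#'   `removed_near_constant`, `removed_correlated` (tibble of
#'   `kept`, `dropped`, `r`), and `surviving`.
#' @examples
#' sim <- simulate_qsrr(n = 40, n_desc = 30, n_true = 3, seed = 2)
#' pt <- pretreat(sim$data)
#' pt$removed_constant
#' @export
pretreat <- function(data, response = "rt", r_threshold = 0.90,
                     near_constant_fraction = 0.95, response_aware = TRUE,
                     id = "compound") {
  if (nrow(data) < 3) abort("pre-treatment needs at least 3 rows")
  nms <- descriptor_names(data, response = response, id = id)
  if (length(nms) == 0) abort("no descriptor columns found")
  X <- as.matrix(data[nms])
  y <- data[[response]]

  rows <- seq_len(nrow(data))
  if ("partition" %in% names(data)) {
    tr <- which(data$partition == "train")
    if (length(tr) >= 3) rows <- tr
  }
  Xf <- X[rows, , drop = FALSE]
  yf <- y[rows]

  sds <- apply(Xf, 2, stats::sd)
  constant <- nms[sds == 0]

  modal_freq <- apply(Xf, 2, function(v) max(table(v)) / length(v))
  near_constant <- setdiff(nms[modal_freq >= near_constant_fraction], constant)

  keep <- setdiff(nms, c(constant, near_constant))
  removed_corr <- tibble(kept = character(), dropped = character(),
                         r = double())
  if (length(keep) >= 2) {
    C <- suppressWarnings(stats::cor(Xf[, keep, drop = FALSE]))
    ry <- abs(suppressWarnings(stats::cor(Xf[, keep, drop = FALSE], yf)))[, 1]
    ry[is.na(ry)] <- 0
    dropped <- rep(FALSE, length(keep))
    for (i in seq_len(length(keep) - 1)) {
      if (dropped[i]) next
      for (j in seq(i + 1, length(keep))) {
        if (dropped[j]) next
        r <- C[i, j]
        if (is.na(r) || abs(r) <= r_threshold) next
        # decide which member of the redundant pair to drop
        drop_j <- TRUE
        if (response_aware && ry[i] < ry[j]) drop_j <- FALSE
        if (drop_j) {
          dropped[j] <- TRUE
          removed_corr <- dplyr::add_row(removed_corr, kept = keep[i],
                                         dropped = keep[j], r = r)
        } else {
          dropped[i] <- TRUE
          removed_corr <- dplyr::add_row(removed_corr, kept = keep[j],
                                         dropped = keep[i], r = r)
          break
        }
      }
    }
    keep <- keep[!dropped]
  }
  if (length(keep) == 0) abort("no descriptors survive pre-treatment")

  out_cols <- c(intersect(c(id, response, "partition"), names(data)), keep)
  structure(
    list(data = as_tibble(data[out_cols]),
         removed_constant = constant,
         removed_near_constant = near_constant,
         removed_correlated = removed_corr,
         surviving = keep,
         r_threshold = r_threshold,
         near_constant_fraction = near_constant_fraction),
    class = "qsrr_pretreat"
  )
}

#' @export
print.qsrr_pretreat <- function(x, ...) {
  cat(sprintf(
    "Descriptor pre-treatment: %d surviving, %d constant, %d near-constant, %d collinear (|r| > %.2f) removed\n",
    length(x$surviving), length(x$removed_constant),
    length(x$removed_near_constant), nrow(x$removed_correlated),
    x$r_threshold))
  invisible(x)
}

#' @describeIn pretreat Tidy the pre-treatment report: one row per input
#'   descriptor with its fate (`kept`, `constant`, `near_constant`,
#'   `collinear`) and, for collinear removals, the partner kept and the
#'   offending correlation.
#' @param x A `qsrr_pretreat` object.
#' @param ... Unused.
#' @export
tidy.qsrr_pretreat <- function(x, ...) {
  dplyr::bind_rows(
    tibble(descriptor = x$surviving, fate = "kept",
           partner = NA_character_, r = NA_real_),
    tibble(descriptor = x$removed_constant, fate = "constant",
           partner = NA_character_, r = NA_real_),
    tibble(descriptor = x$removed_near_constant, fate = "near_constant",
           partner = NA_character_, r = NA_real_),
    tibble(descriptor = x$removed_correlated$dropped, fate = "collinear",
           partner = x$removed_correlated$kept,
           r = x$removed_correlated$r)
  )
}

#' Fit a train-set autoscaler
#'
#' Computes per-descriptor means and standard deviations (n-1
#' denominator) on the given rows, for z-score standardization of both
#' training and held-out rows with training statistics only.
#'
#' @param data Tibble with descriptor columns.
#' @param rows Integer row indices to fit on; default all rows, or the
#'   training rows when a `partition` column is present.
#' @param response,id Column names excluded from scaling.
#' @return An object of class `qsrr_scaler`.
#' @export
fit_scaler <- function(data, rows = NULL, response = "rt", id = "compound") {
  nms <- descriptor_names(data, response = response, id = id)
  if (is.null(rows)) {
    rows <- seq_len(nrow(data))
    if ("partition" %in% names(data)) {
      tr <- which(data$partition == "train")
      if (length(tr) >= 2) rows <- tr
    }
  }
  X <- as.matrix(data[rows, nms, drop = FALSE])
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0)) {
    abort(sprintf(
      "zero standard deviation in column(s) %s; run pretreat() first",
      paste(nms[sds <= 0], collapse = ", ")))
  }
  structure(list(means = means, sds = sds, descriptors = nms,
                 fitted_on = rows),
            class = "qsrr_scaler")
}

#' Apply or invert an autoscaler
#'
#' @param scaler A `qsrr_scaler`.
#' @param data Tibble containing the scaler's descriptor columns.
#' @return `data` with the descriptor columns standardized
#'   (or restored, for [invert_scaler()]).
#' @export
apply_scaler <- function(scaler, data) {
  stopifnot(inherits(scaler, "qsrr_scaler"))
  missing <- setdiff(scaler$descriptors, names(data))
  if (length(missing) > 0) {
    abort(sprintf("data lacks scaled column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (j in scaler$descriptors) {
    data[[j]] <- (data[[j]] - scaler$means[[j]]) / scaler$sds[[j]]
  }
  data
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, data) {
  stopifnot(inherits(scaler, "qsrr_scaler"))
  for (j in scaler$descriptors) {
    data[[j]] <- data[[j]] * scaler$sds[[j]] + scaler$means[[j]]
  }
  data
}

# Matrix-level scaling used by the model engines.
scale_matrix <- function(X, means, sds) {
  sweep(sweep(X, 2, means, "-"), 2, sds, "/")
}
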