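# Small dataset builders shared across tests. Everything is generated
# in code; no stored fixtures beyond the packaged drug table.

# Independent N(0,1) descriptors with a linear response (optionally
# noiseless) in the package's tibble layout.
linear_table <- function(n = 30, k = 4, beta = NULL, noise_sd = 0,
                         seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * k), n, k)
    if (is.null(beta)) beta <- seq_len(k)
    y <- as.vector(X %*% beta) + stats::rnorm(n, 0, noise_sd)
  })
  d <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(d) <- sprintf("D%03d", seq_len(k))
  dplyr::bind_cols(
    tibble::tibble(compound = sprintf("C%03d", seq_len(n)), rt = y), d)
}

# Additive tanh response surface rescaled into the GC retention range,
# mirroring the generator's conventions (beta ~ U(0.5, 1.5) with random
# signs, affine rescale to [0.9, 2.2] before noise).
tanh_table <- function(n = 75, k = 7, noise_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * k), n, k)
    beta <- stats::runif(k, 0.5, 1.5) * sample(c(-1, 1), k, TRUE)
    y0 <- as.vector(tanh(X) %*% beta)
    rng <- range(y0)
    y <- 0.9 + (2.2 - 0.9) * (y0 - rng[1]) / diff(rng) +
      stats::rnorm(n, 0, noise_sd)
  })
  d <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(d) <- sprintf("D%03d", seq_len(k))
  dplyr::bind_cols(
    tibble::tibble(compound = sprintf("C%03d", seq_len(n)), rt = y), d)
}

# Scaled matrix + centered response pair for the low-level engines.
scaled_xy <- function(data, response = "rt") {
  nms <- descriptor_names(data, response = response)
  X <- scale(as.matrix(data[nms]))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, y = data[[response]] - mean(data[[response]]),
       y_raw = data[[response]])
}
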