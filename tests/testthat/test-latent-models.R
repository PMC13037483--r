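test_that("RBF kernel evaluates the Gaussian similarity exactly", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), sigma = 0.7), 1.0)
  # hand-computed: squared distance 2, exponent -2/2 = -1
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), sigma = 1), exp(-1),
               tolerance = 1e-12)
  # monotone approach to 1 as sigma grows
  vals <- vapply(c(1, 2, 5, 10, 100), function(s)
    rbf_kernel(c(0, 0), c(1, 1), sigma = s), double(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(1 - vals[length(vals)], 1e-4)
  expect_error(rbf_kernel(c(0, 0), c(1, 1), sigma = 0), "positive")
  expect_error(rbf_kernel(c(0, 0), c(1, 1, 1), sigma = 1), "unequal")
})

test_that("kernel matrices are symmetric positive semidefinite", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      X <- matrix(stats::rnorm(20 * 4), 20, 4)
    })
    K <- rbf_kernel(X, sigma = 1.5)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_true(all(diag(K) == 1))
  }
})

test_that("exact linear relationships are recovered with full latent rank", {
  tab <- linear_table(n = 20, k = 3, noise_sd = 0, seed = 11)
  xy <- scaled_xy(tab)
  fit <- nipals_pls(xy$X, xy$y, n_lv = 3)
  r2 <- 1 - sum((xy$y - fit$fitted)^2) / sum(xy$y^2)
  expect_equal(r2, 1, tolerance = 1e-8)
})

test_that("full-rank NIPALS PLS equals the normal-equations solution", {
  for (seed in 1:5) {
    tab <- linear_table(n = 30, k = 4, noise_sd = 1, seed = 100 + seed)
    xy <- scaled_xy(tab)
    fit <- nipals_pls(xy$X, xy$y, n_lv = 4)
    beta_ols <- solve(crossprod(xy$X), crossprod(xy$X, xy$y))
    expect_lt(max(abs(fit$fitted - xy$X %*% beta_ols)), 1e-6)
  }
})

test_that("the first latent variable follows the dominant covariance", {
  withr::with_seed(17, {
    X <- scale(matrix(stats::rnorm(50 * 4), 50, 4))
    y <- 5 * X[, 2] + stats::rnorm(50, 0, 0.1)
  })
  y <- y - mean(y)
  # brute-force covariances identify the relevant column
  expect_equal(which.max(abs(crossprod(X, y))), 2L)
  fit <- nipals_pls(X, y, n_lv = 1)
  expect_equal(which.max(abs(fit$weights[, 1])), 2L)
})

test_that("PLS scores are orthogonal and training R2 grows with rank", {
  tab <- linear_table(n = 40, k = 6, noise_sd = 2, seed = 23)
  xy <- scaled_xy(tab)
  fit <- nipals_pls(xy$X, xy$y, n_lv = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  r2 <- vapply(1:5, function(a) {
    f <- nipals_pls(xy$X, xy$y, n_lv = a)
    1 - sum((xy$y - f$fitted)^2) / sum(xy$y^2)
  }, double(1))
  expect_true(all(diff(r2) > -1e-12))
})

test_that("rank collapse is reported with the achievable rank", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(20), 20, 1)
  })
  X2 <- cbind(X, X)  # rank 1
  y <- X[, 1] * 2
  expect_error(nipals_pls(scale(X2) / 1, y - mean(y), n_lv = 2), "rank is 1")
})

test_that("high-level PLS predicts new data and honours the partition", {
  tab <- linear_table(n = 50, k = 4, noise_sd = 0.2, seed = 31)
  tab$partition <- rep(c("train", "test"), c(40, 10))
  fit <- qsrr_pls(tab, n_lv = 4)
  expect_equal(length(fit$training_rows), 40)
  # predict on training rows reproduces stored fitted values
  expect_equal(predict(fit, tab[1:40, ]), fit$fitted, tolerance = 1e-10)
  # tidy/glance contracts
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(c("coefficient", "weight_lv1") %in% names(td)))
  expect_gt(glance(fit)$train_r2, 0.99)
  expect_error(predict(fit, tab[, 1:3]), "lacks descriptor")
})

test_that("zero latent variables predict the training mean", {
  tab <- linear_table(n = 20, k = 3, noise_sd = 1, seed = 5)
  fit <- qsrr_pls(tab, n_lv = 0)
  expect_equal(unique(round(predict(fit, tab), 10)),
               round(mean(tab$rt), 10))
})

test_that("linear-kernel KPLS reproduces PLS predictions", {
  for (seed in 1:10) {
    tab <- linear_table(n = 25, k = 4, noise_sd = 1, seed = 300 + seed)
    xy <- scaled_xy(tab)
    n_lv <- 3
    kp <- kpls_fit(tcrossprod(xy$X), xy$y_raw, n_lv = n_lv)
    pl <- nipals_pls(xy$X, xy$y, n_lv = n_lv)
    expect_lt(max(abs(kp$fitted - (pl$fitted + mean(xy$y_raw)))), 1e-6)
  }
})

test_that("KPLS interpolates noiseless targets at full kernel rank", {
  tab <- linear_table(n = 15, k = 3, noise_sd = 0, seed = 41)
  fit <- qsrr_kpls(tab, sigma = 2, n_lv = 14)
  expect_lt(max(abs(fit$fitted - tab$rt)), 1e-6)
  # a duplicated training point predicts that row's target
  probe <- tab[3, ]
  expect_equal(predict(fit, probe), tab$rt[3], tolerance = 1e-6)
})

test_that("KPLS predictions on training rows equal stored fitted values", {
  tab <- tanh_table(n = 40, k = 3, noise_sd = 0.05, seed = 51)
  fit <- qsrr_kpls(tab, n_lv = 3)
  expect_equal(predict(fit, tab), fit$fitted, tolerance = 1e-10)
  expect_gte(length(unique(round(predict(fit, tab[1:5, ]), 12))), 2)
})

test_that("a tuned kernel width captures a smooth nonlinear surface", {
  withr::with_seed(9, {
    n <- 60
    tab <- tibble::tibble(compound = as.character(1:n),
                          x1 = stats::rnorm(n))
    tab$rt <- sin(tab$x1)
  })
  sig <- choose_sigma(tab, grid = c(0.1, 0.25, 0.5, 1, 2, 4), n_lv = 3,
                      seed = 2)
  fit <- qsrr_kpls(tab, sigma = as.numeric(sig), n_lv = 3)
  expect_gte(glance(fit)$train_r2, 0.99)
})

test_that("sigma selection is an argmin over the grid and reproducible", {
  tab <- tanh_table(n = 40, k = 2, noise_sd = 0.05, seed = 61)
  one <- choose_sigma(tab, grid = 1.5, n_lv = 2, seed = 3)
  expect_equal(as.numeric(one),
               1.5 * gcqsrr:::median_pairwise_distance(
                 scale(as.matrix(tab[c("D001", "D002")]))))
  sig <- choose_sigma(tab, grid = c(0.5, 1, 2), n_lv = 2, seed = 3)
  grid <- attr(sig, "grid")
  expect_equal(as.numeric(sig), grid$sigma[which.min(grid$rmsecv)])
  expect_equal(as.numeric(sig),
               as.numeric(choose_sigma(tab, grid = c(0.5, 1, 2), n_lv = 2,
                                       seed = 3)))
  expect_error(choose_sigma(tab, grid = numeric(0)), "empty")
  degen <- tibble::tibble(compound = c("a", "b", "c"), rt = 1:3,
                          x = c(1, 1, 1))
  expect_error(choose_sigma(degen), "")
})

test_that("training R2 of KPLS is non-decreasing in the latent count", {
  tab <- tanh_table(n = 35, k = 3, noise_sd = 0.1, seed = 71)
  r2 <- vapply(1:6, function(a) {
    glance(qsrr_kpls(tab, sigma = 2, n_lv = a))$train_r2
  }, double(1))
  expect_true(all(diff(r2) > -1e-10))
})
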