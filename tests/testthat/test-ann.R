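test_that("forward pass matches hand arithmetic", {
  # all weights zero -> zero output
  net0 <- list(W1 = matrix(0, 3, 4), w2 = rep(0, 4))
  expect_equal(ann_forward(net0, matrix(stats::rnorm(6), 2, 3)), c(0, 0))

  # zero hidden weights, output bias b -> constant b
  netb <- list(W1 = matrix(0, 2, 3), w2 = c(1.7, 0, 0))
  expect_equal(ann_forward(netb, matrix(stats::rnorm(10), 5, 2)),
               rep(1.7, 5))

  # single hidden unit, hand-set weights, x = 0:
  # output = w2_bias + w2_1 * tanh(w1_bias)
  net1 <- list(W1 = matrix(c(0.3, 0.8), 1, 2), w2 = c(0.1, 2))
  expect_equal(ann_forward(net1, matrix(0, 1, 1)),
               0.1 + 2 * tanh(0.3), tolerance = 1e-12)

  expect_error(ann_forward(net1, matrix(0, 1, 2)), "expects")
})

test_that("parameter count follows h(d+1) + h + 1", {
  expect_equal(gcqsrr:::ann_n_params(7, 4), 37)  # compact 7-4-1 topology
  w <- seq_len(gcqsrr:::ann_n_params(3, 2))
  net <- gcqsrr:::ann_unpack(w, 3, 2)
  expect_equal(dim(net$W1), c(2, 4))
  expect_equal(length(net$w2), 3)
  expect_equal(gcqsrr:::ann_pack(net$W1, net$w2), w)
})

test_that("analytic Jacobian matches central finite differences", {
  withr::with_seed(5, {
    X <- matrix(stats::rnorm(12), 4, 3)
    w <- stats::runif(gcqsrr:::ann_n_params(3, 2), -0.5, 0.5)
  })
  net <- gcqsrr:::ann_unpack(w, 3, 2)
  J <- gcqsrr:::ann_jacobian(net, X)
  eps <- 1e-6
  J_fd <- sapply(seq_along(w), function(p) {
    wp <- w; wm <- w
    wp[p] <- wp[p] + eps; wm[p] <- wm[p] - eps
    (ann_forward(gcqsrr:::ann_unpack(wp, 3, 2), X) -
       ann_forward(gcqsrr:::ann_unpack(wm, 3, 2), X)) / (2 * eps)
  })
  expect_lt(max(abs(J - J_fd)) / max(abs(J)), 1e-6)
})

test_that("LM training drives a noiseless linear target below 1e-3 RMSE", {
  withr::with_seed(2, {
    Xtr <- matrix(stats::rnorm(40), 40, 1)
    Xv <- matrix(stats::rnorm(10), 10, 1)
  })
  ytr <- 2 * Xtr[, 1] + 1
  yv <- 2 * Xv[, 1] + 1
  net <- train_ann(Xtr, ytr, Xv, yv, hidden = 2, seed = 3)
  expect_lt(utils::tail(net$trace$train_rmse, 1), 1e-3)
  expect_lte(net$epochs_run, 150)
})

test_that("accepted LM steps never increase training SSE", {
  tab <- tanh_table(n = 50, k = 3, noise_sd = 0.05, seed = 77)
  X <- scale(as.matrix(tab[descriptor_names(tab)]))
  net <- train_ann(X[1:40, ], tab$rt[1:40], X[41:50, ], tab$rt[41:50],
                   hidden = 3, seed = 9)
  expect_true(all(diff(net$trace$train_rmse) <= 1e-12))
})

test_that("early stopping returns the best-validation weights", {
  net_patience <- ann_config(patience = 10)
  tab <- tanh_table(n = 60, k = 2, noise_sd = 0.02, seed = 99)
  X <- scale(as.matrix(tab[descriptor_names(tab)]))
  # an adversarial validation set: y_val = -y pattern makes validation
  # worsen as training improves
  Xv <- X[51:60, ]
  yv <- -tab$rt[51:60] + 2 * mean(tab$rt)
  fit <- train_ann(X[1:50, ], tab$rt[1:50], Xv, yv, hidden = 3,
                   config = net_patience, seed = 21)
  if (nrow(fit$trace) > 1 && which.min(fit$trace$val_rmse) == 1) {
    expect_lte(fit$epochs_run, 11)
    expect_equal(fit$best_epoch, 1L)
  }
  # best-weights contract: returned validation RMSE is the trace minimum
  expect_equal(fit$best_val_rmse, min(fit$trace$val_rmse))
})

test_that("training is deterministic given the seed", {
  tab <- tanh_table(n = 40, k = 2, noise_sd = 0.05, seed = 13)
  X <- scale(as.matrix(tab[descriptor_names(tab)]))
  a <- train_ann(X[1:30, ], tab$rt[1:30], X[31:40, ], tab$rt[31:40],
                 hidden = 3, seed = 7)
  b <- train_ann(X[1:30, ], tab$rt[1:30], X[31:40, ], tab$rt[31:40],
                 hidden = 3, seed = 7)
  expect_identical(a$W1, b$W1)
  expect_identical(a$w2, b$w2)
  expect_identical(a$trace, b$trace)
})

test_that("architecture scan returns the argmin size with ties to fewer", {
  tab <- tanh_table(n = 60, k = 2, noise_sd = 0.02, seed = 45)
  X <- scale(as.matrix(tab[descriptor_names(tab)]))
  cfg1 <- ann_config(hidden_range = 3, n_restarts = 3)
  one <- select_hidden(X[1:45, ], tab$rt[1:45], X[46:60, ], tab$rt[46:60],
                       config = cfg1, seed = 5)
  expect_equal(one$best_hidden, 3L)

  cfg <- ann_config(hidden_range = c(2, 4, 6), n_restarts = 3,
                    max_epochs = 60)
  scan <- select_hidden(X[1:45, ], tab$rt[1:45], X[46:60, ], tab$rt[46:60],
                        config = cfg, seed = 5)
  expect_equal(scan$best_hidden,
               scan$table$hidden[which.min(scan$table$median_val_rmse)])
  expect_error(ann_config(hidden_range = integer(0)), "empty")
})

test_that("a strongly linear target gains little from extra neurons", {
  withr::with_seed(55, {
    X <- matrix(stats::rnorm(70 * 2), 70, 2)
    y <- X %*% c(1, -0.5) + stats::rnorm(70, 0, 0.01)
  })
  cfg <- ann_config(hidden_range = c(2, 6, 10), n_restarts = 3,
                    max_epochs = 80)
  scan <- select_hidden(X[1:55, ], y[1:55], X[56:70, ], y[56:70],
                        config = cfg, seed = 8)
  rmse2 <- scan$table$median_val_rmse[scan$table$hidden == 2]
  expect_lt(min(scan$table$median_val_rmse), rmse2 * 1.05 + 1e-12)
})

test_that("multi-restart reporting aggregates and reproduces", {
  tab <- tanh_table(n = 50, k = 2, noise_sd = 0.02, seed = 33)
  X <- scale(as.matrix(tab[descriptor_names(tab)]))
  cfg1 <- ann_config(n_restarts = 1)
  single <- ann_restarts(X[1:40, ], tab$rt[1:40], X[41:50, ], tab$rt[41:50],
                         hidden = 3, config = cfg1, seed = 2)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best$best_val_rmse, single$table$val_rmse[1])

  cfg <- ann_config(n_restarts = 5, max_epochs = 80)
  runs <- ann_restarts(X[1:40, ], tab$rt[1:40], X[41:50, ], tab$rt[41:50],
                       hidden = 3, config = cfg, seed = 2)
  expect_equal(nrow(runs$table), 5)
  expect_equal(runs$best$best_val_rmse, min(runs$table$val_rmse))
  expect_equal(runs$summary$mean[2], mean(runs$table$val_rmse))
  rerun <- ann_restarts(X[1:40, ], tab$rt[1:40], X[41:50, ], tab$rt[41:50],
                        hidden = 3, config = cfg, seed = 2)
  expect_identical(runs$table, rerun$table)
})

test_that("restart scatter on a noiseless linear target is tiny", {
  withr::with_seed(4, {
    X <- matrix(stats::rnorm(60), 60, 1)
  })
  y <- 1.5 * X[, 1] + 0.5
  cfg <- ann_config(n_restarts = 15)
  runs <- ann_restarts(X[1:48, , drop = FALSE], y[1:48],
                       X[49:60, , drop = FALSE], y[49:60],
                       hidden = 2, config = cfg, seed = 6)
  expect_lt(stats::sd(runs$table$train_rmse), 1e-2)
})

test_that("sensitivity analysis matches the closed form for a linear net", {
  # single-input identity-like network: y = w2_bias + w2 * tanh(w1 * x)
  # use small weights so tanh is effectively linear: y ~ w2 * w1 * x
  net <- list(W1 = matrix(c(0, 0.01), 1, 2), w2 = c(0, 100))
  withr::with_seed(8, {
    X <- matrix(stats::rnorm(200), 200, 1)
  })
  rep_ <- ann_sensitivity(list(net), X, deltas = c(0.05))
  # |dy| = |w * delta * x| with w = 100 * 0.01 = 1 (to tanh's curvature)
  expect_equal(rep_$mean_abs_change, mean(abs(1 * 0.05 * X[, 1])),
               tolerance = 1e-3)

  # a descriptor with zero weights has zero sensitivity and lowest rank;
  # W1 columns are (bias, x1, x2) with x2 disconnected
  net2 <- list(W1 = matrix(c(0, 0.5, 0), 1, 3), w2 = c(0.2, 1.4))
  X2 <- matrix(stats::rnorm(60), 30, 2)
  rep2 <- ann_sensitivity(list(net2), X2)
  expect_equal(rep2$mean_abs_change[2], 0)
  expect_equal(rep2$rank[2], 2)
  expect_true(all(rep2$mean_abs_change >= 0))
  expect_setequal(rep2$rank, 1:2)

  # duplicating a model leaves the averaged report unchanged
  rep3 <- ann_sensitivity(list(net2, net2), X2)
  expect_equal(rep3$mean_abs_change, rep2$mean_abs_change)
})

test_that("the tidy ANN interface partitions, scans and predicts", {
  tab <- tanh_table(n = 75, k = 3, noise_sd = 0.02, seed = 19)
  cfg <- ann_config(hidden_range = c(2, 4), n_restarts = 3, max_epochs = 80)
  fit <- qsrr_ann(tab, hidden = NULL, config = cfg, seed = 10)
  expect_s3_class(fit, "qsrr_ann")
  expect_setequal(unique(fit$data$partition), c("train", "val", "test"))
  expect_equal(nrow(fit$restarts), 3)
  g <- glance(fit)
  expect_equal(g$n_params,
               gcqsrr:::ann_n_params(3, fit$hidden))
  pred <- predict(fit, fit$data)
  expect_equal(length(pred), 75)
  expect_true(all(is.finite(pred)))
  expect_error(predict(fit, fit$data[, 1:2]), "lacks")
})
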