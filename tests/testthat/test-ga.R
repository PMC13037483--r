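test_that("crossover follows the cut-and-swap contract", {
  a <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  b <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # force crossover (p = 1) and search for the cut after position 3:
  # children are 000000 (repaired to one bit) and 111111
  found <- FALSE
  for (s in 1:50) {
    kids <- withr::with_seed(s, ga_crossover(a, b, p = 1))
    if (all(kids[[2]])) {  # cut at 3 gives the all-ones child
      expect_equal(sum(kids[[1]]), 1)  # repaired empty child
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # identical parents are invariant under any cut
  kids <- withr::with_seed(1, ga_crossover(a, a, p = 1))
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)

  # p = 0 copies the parents
  kids0 <- withr::with_seed(2, ga_crossover(a, b, p = 0))
  expect_identical(kids0[[1]], a)
  expect_identical(kids0[[2]], b)
  expect_error(ga_crossover(a, b[1:3]), "unequal")
})

test_that("mutation flips at the configured per-gene rate", {
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  expect_identical(withr::with_seed(1, ga_mutate(mask, p = 0)), mask)
  # rate 1 complements (then repairs if empty)
  expect_identical(withr::with_seed(1, ga_mutate(mask, p = 1)),
                   !mask)
  all_on <- rep(TRUE, 3)
  repaired <- withr::with_seed(1, ga_mutate(all_on, p = 1))
  expect_equal(sum(repaired), 1)  # complement is empty -> one bit restored

  # Monte-Carlo check of the binomial expectation: K = 1000, p = 0.01
  K <- 1000
  base <- rep(FALSE, K)
  flips <- withr::with_seed(7, {
    vapply(1:2000, function(i) sum(ga_mutate(base, p = 0.01)), double(1))
  })
  expect_gt(mean(flips), 10 - 0.3)
  expect_lt(mean(flips), 10 + 0.3)
})

test_that("fitness rewards fit and penalizes descriptor count", {
  tab <- linear_table(n = 40, k = 6, noise_sd = 0, seed = 3)
  X <- as.matrix(tab[descriptor_names(tab)])
  y <- tab$rt
  cfg0 <- ga_config(alpha = 0, n_lv = 6)  # full rank fits exactly
  full <- ga_fitness(rep(TRUE, 6), X, y, cfg0, seed = 1)
  expect_gt(full, 1 - 1e-6)  # perfect noiseless linear data: Q2 -> 1

  # equal Q2 (a duplicated column leaves one-component PLS predictions
  # unchanged), fewer descriptors -> strictly higher penalized fitness
  cfg <- ga_config(alpha = 0.05, n_lv = 1)
  fold_id <- gcqsrr:::make_folds(40, 5, 1)
  Xd <- cbind(X, X[, 1])
  lean <- c(TRUE, rep(FALSE, 6))
  fat <- c(TRUE, rep(FALSE, 5), TRUE)
  f_lean <- ga_fitness(lean, Xd, y, cfg, fold_id = fold_id)
  f_fat <- ga_fitness(fat, Xd, y, cfg, fold_id = fold_id)
  expect_equal(f_lean - f_fat, cfg$alpha * 1 / 7, tolerance = 1e-10)
  expect_gt(f_lean, f_fat)

  # empty mask is culled
  expect_identical(ga_fitness(rep(FALSE, 6), X, y, cfg, seed = 1), -Inf)
})

test_that("pure-noise masks score near or below zero", {
  withr::with_seed(12, {
    X <- matrix(stats::rnorm(40 * 5), 40, 5)
    y <- stats::rnorm(40)
  })
  cfg <- ga_config(alpha = 0, n_lv = 4)
  f <- ga_fitness(rep(TRUE, 5), X, y, cfg, seed = 4)
  expect_lte(f, 0.2)
})

test_that("GA finds the exhaustive optimum on a tiny problem", {
  sim <- simulate_qsrr(n = 40, n_desc = 6, n_true = 2, block_size = 1,
                       rho = 0, noise_sd = 0, n_constant = 0,
                       n_near_constant = 0, seed = 5)
  X <- as.matrix(sim$data[sim$truth$descriptor])
  y <- sim$data$rt
  cfg <- ga_config(max_generations = 50, stall_patience = 50, n_lv = 2)
  res <- run_ga(X, y, cfg, run_seed = 11)
  expect_true(all(which(sim$truth$is_true) %in% which(res$best_mask)))

  # exhaustive 2^6 enumeration with the run's own fold assignment
  fold_id <- gcqsrr:::make_folds(40, 5, gcqsrr:::derive_seed(11, "folds"))
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), 6))[-1, ]
  fits <- apply(as.matrix(masks), 1, function(m) {
    ga_fitness(m, X, y, cfg, fold_id = fold_id)
  })
  expect_gte(res$best_fitness, max(fits) - cfg$stall_tol)
})

test_that("a flat fitness landscape stalls out quickly", {
  # four identical columns and no parsimony penalty: every mask has the
  # same one-component fit, so the landscape is exactly constant
  withr::with_seed(2, {
    x <- stats::rnorm(30)
    y <- x + stats::rnorm(30, 0, 0.1)
  })
  X <- cbind(x, x, x, x)
  cfg <- ga_config(max_generations = 500, stall_patience = 15, n_lv = 1,
                   alpha = 0)
  res <- run_ga(X, y, cfg, run_seed = 3)
  expect_lte(res$generations_run, 16)
  expect_equal(length(unique(res$fitness_trace)), 1)
})

test_that("GA runs are deterministic and elitist-monotone", {
  sim <- simulate_qsrr(n = 35, n_desc = 10, n_true = 2, block_size = 2,
                       rho = 0.5, noise_sd = 0.05, n_constant = 0,
                       n_near_constant = 0, seed = 6)
  X <- as.matrix(sim$data[sim$truth$descriptor])
  y <- sim$data$rt
  cfg <- ga_config(max_generations = 25, stall_patience = 25, n_lv = 2)
  a <- run_ga(X, y, cfg, run_seed = 8)
  b <- run_ga(X, y, cfg, run_seed = 8)
  expect_identical(a$fitness_trace, b$fitness_trace)
  expect_identical(a$best_mask, b$best_mask)
  # monotone non-decreasing elitist trace
  expect_true(all(diff(a$fitness_trace) > -1e-12))
})

test_that("GA beats a random-mask baseline", {
  sim <- simulate_qsrr(n = 40, n_desc = 12, n_true = 3, block_size = 2,
                       rho = 0.6, noise_sd = 0.05, n_constant = 0,
                       n_near_constant = 0, seed = 14)
  X <- as.matrix(sim$data[sim$truth$descriptor])
  y <- sim$data$rt
  cfg <- ga_config(max_generations = 40, stall_patience = 40, n_lv = 3)
  res <- run_ga(X, y, cfg, run_seed = 4)
  fold_id <- gcqsrr:::make_folds(40, 5, gcqsrr:::derive_seed(4, "folds"))
  baseline <- withr::with_seed(99, {
    max(vapply(1:100, function(i) {
      m <- gcqsrr:::repair_mask(stats::runif(12) < 0.3)
      ga_fitness(m, X, y, cfg, fold_id = fold_id)
    }, double(1)))
  })
  expect_gte(res$best_fitness, baseline - 1e-12)
})

test_that("consensus frequencies and the final mask follow the runs", {
  sim <- simulate_qsrr(n = 40, n_desc = 8, n_true = 2, block_size = 1,
                       rho = 0, noise_sd = 0, n_constant = 0,
                       n_near_constant = 0, seed = 17)
  X <- as.matrix(sim$data[sim$truth$descriptor])
  y <- sim$data$rt
  cfg <- ga_config(max_generations = 30, stall_patience = 30, n_lv = 2,
                   n_runs = 3)
  runs <- lapply(1:3, function(r) run_ga(X, y, cfg, run_seed = 100 + r))
  cons <- ga_consensus(runs, X, y, cfg, seed = 1,
                       descriptors = sim$truth$descriptor)
  expect_true(all(cons$frequency$frequency >= 0 &
                    cons$frequency$frequency <= 1))
  # the final mask is one of the run-best masks
  expect_true(any(vapply(runs, function(r)
    identical(r$best_mask, cons$final_mask), logical(1))))

  # all runs agreeing forces frequencies into {0, 1}
  same <- ga_consensus(runs[c(1, 1, 1)], X, y, cfg, seed = 1)
  expect_true(all(same$frequency$frequency %in% c(0, 1)))
  expect_identical(same$final_mask, runs[[1]]$best_mask)

  # single run: its best mask is final
  one <- ga_consensus(runs[1], X, y, cfg, seed = 1)
  expect_identical(one$final_mask, runs[[1]]$best_mask)

  # tidy/glance surface
  td <- tidy(cons)
  expect_true(all(diff(td$frequency) <= 0))
  expect_equal(glance(cons)$n_runs, 3)
})
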