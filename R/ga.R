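#' Configuration for genetic-algorithm descriptor selection
#'
#' Defaults follow standard wrapper-selection practice for QSRR:
#' population of 30 binary chromosomes, single-point crossover with
#' probability 0.5, per-gene mutation rate 0.01, up to 1000
#' generations with early stopping after 100 generations without a
#' best-fitness improvement of at least 0.001, 20 independent runs for
#' the consensus, and a parsimony penalty `alpha` on the selected
#' fraction of descriptors.
#'
#' @param pop_size Population size.
#' @param p_crossover Single-point crossover probability.
#' @param p_mutation Per-gene mutation probability.
#' @param max_generations Generation limit.
#' @param stall_patience Generations without significant improvement
#'   before stopping.
#' @param stall_tol Minimum best-fitness improvement counted as
#'   significant.
#' @param n_runs Independent GA runs for the consensus.
#' @param alpha Parsimony weight: fitness is Q2_cv minus
#'   `alpha * k/K` for `k` selected of `K` descriptors.
#' @param inner_folds Fold count of the inner cross-validation
#'   (set to the number of training rows for leave-one-out).
#' @param estimator `"pls"` or `"kpls"` as the wrapped model.
#' @param n_lv Latent variables of the wrapped model (capped at each
#'   mask's achievable rank).
#' @param sigma Kernel width for `estimator = "kpls"`; `NULL` uses the
#'   median-distance heuristic per fit.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param init_prob Per-bit inclusion probability of the initial
#'   population.
#' @return A list of class `qsrr_ga_config`.
#' @export
ga_config <- function(pop_size = 30, p_crossover = 0.5, p_mutation = 0.01,
                      max_generations = 1000, stall_patience = 100,
                      stall_tol = 0.001, n_runs = 20, alpha = 0.05,
                      inner_folds = 5, estimator = c("pls", "kpls"),
                      n_lv = 4, sigma = NULL, elitism = 1,
                      init_prob = 0.1) {
  estimator <- match.arg(estimator)
  if (pop_size < 2) abort("pop_size must be at least 2")
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  if (alpha < 0) abort("alpha must be non-negative")
  structure(list(pop_size = as.integer(pop_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 max_generations = as.integer(max_generations),
                 stall_patience = as.integer(stall_patience),
                 stall_tol = stall_tol, n_runs = as.integer(n_runs),
                 alpha = alpha, inner_folds = as.integer(inner_folds),
                 estimator = estimator, n_lv = n_lv, sigma = sigma,
                 elitism = as.integer(elitism), init_prob = init_prob),
            class = "qsrr_ga_config")
}

# Ensure a chromosome has at least one active bit.
repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

#' Penalized cross-validated fitness of a descriptor mask
#'
#' Fitness is `Q2_cv - alpha * k/K` where `Q2_cv = 1 - PRESS/TSS` from
#' an inner k-fold cross-validation of the configured estimator
#' restricted to the masked columns, `k` the number of selected
#' descriptors and `K` the total. Autoscaling is refit inside every
#' fold. An estimator failure on a degenerate mask yields `-Inf` so
#' the chromosome is culled. Higher is better.
#'
#' @param mask Logical vector over the descriptor columns.
#' @param X Numeric descriptor matrix (pretreated, unscaled).
#' @param y Response vector (minutes).
#' @param config A [ga_config()].
#' @param fold_id Optional fold assignment; defaults to folds derived
#'   from `seed`.
#' @param seed Integer seed for the fold assignment when `fold_id` is
#'   not given.
#' @return Scalar fitness.
#' @export
ga_fitness <- function(mask, X, y, config = ga_config(), fold_id = NULL,
                       seed = 1L) {
  mask <- as.logical(mask)
  if (!any(mask)) return(-Inf)
  if (is.null(fold_id)) {
    fold_id <- make_folds(length(y), min(config$inner_folds, length(y)), seed)
  }
  spec <- list(model = config$estimator, n_lv = config$n_lv,
               sigma = config$sigma)
  press <- tryCatch(
    cv_press(X[, mask, drop = FALSE], y, spec, fold_id),
    error = function(e) NA_real_)
  if (!is.finite(press)) return(-Inf)
  tss <- sum((y - mean(y))^2)
  q2 <- 1 - press / tss
  q2 - config$alpha * sum(mask) / ncol(X)
}

#' Single-point crossover of two chromosomes
#'
#' With probability `p`, a cut point is drawn uniformly in
#' `1..K-1` and the suffixes are swapped; otherwise the parents are
#' copied. Children left empty are repaired by activating one random
#' bit. Uses the current RNG state.
#'
#' @param a,b Logical parent chromosomes of equal length.
#' @param p Crossover probability.
#' @return List of two child chromosomes.
#' @export
ga_crossover <- function(a, b, p = 0.5) {
  if (length(a) != length(b)) abort("parents have unequal length")
  K <- length(a)
  if (K >= 2 && stats::runif(1) < p) {
    cut <- sample.int(K - 1L, 1L)
    child_a <- c(a[seq_len(cut)], b[seq(cut + 1L, K)])
    child_b <- c(b[seq_len(cut)], a[seq(cut + 1L, K)])
  } else {
    child_a <- a; child_b <- b
  }
  list(repair_mask(child_a), repair_mask(child_b))
}

#' Per-gene mutation of a chromosome
#'
#' Flips each bit independently with probability `p`; an empty result
#' is repaired. Uses the current RNG state.
#'
#' @param mask Logical chromosome.
#' @param p Per-gene mutation probability.
#' @return Mutated chromosome.
#' @export
ga_mutate <- function(mask, p = 0.01) {
  flips <- stats::runif(length(mask)) < p
  repair_mask(xor(mask, flips))
}

#' One genetic-algorithm run
#'
#' Evolves a population of binary descriptor masks by tournament
#' selection (size 2), single-point crossover, per-gene mutation, and
#' elitism, maximizing the penalized cross-validated fitness of
#' [ga_fitness()]. The inner-CV fold assignment is fixed per run
#' (derived from `run_seed`) so fitness values are comparable across
#' chromosomes and generations. Stops at the generation limit or when
#' the elitist best fitness has not improved by at least `stall_tol`
#' over `stall_patience` consecutive generations. Fully deterministic
#' given `run_seed`.
#'
#' @param X Numeric descriptor matrix (pretreated, unscaled).
#' @param y Response vector.
#' @param config A [ga_config()].
#' @param run_seed Integer seed of this run.
#' @return Object of class `qsrr_ga_run`: `best_mask` (logical),
#'   `best_fitness`, `fitness_trace` (per-generation best),
#'   `generations_run`, `run_seed`.
#' @export
run_ga <- function(X, y, config = ga_config(), run_seed = 1L) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (K < 2) abort("need at least 2 descriptor columns")
  fold_id <- make_folds(length(y),
                        min(config$inner_folds, length(y)),
                        derive_seed(run_seed, "folds"))
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  fit_of <- function(mask) {
    key <- rawToChar(as.raw(as.integer(mask) + 48L))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- ga_fitness(mask, X, y, config, fold_id = fold_id)
    cache[[key]] <- val
    val
  }

  withr::with_seed(run_seed, {
    pop <- lapply(seq_len(config$pop_size), function(i) {
      repair_mask(stats::runif(K) < config$init_prob)
    })
    fits <- vapply(pop, fit_of, double(1))
    trace <- numeric(config$max_generations)
    best_overall <- max(fits)
    stall <- 0L
    gen_run <- 0L
    for (gen in seq_len(config$max_generations)) {
      ord <- order(fits, decreasing = TRUE)
      elite <- pop[ord[seq_len(config$elitism)]]
      new_pop <- elite
      while (length(new_pop) < config$pop_size) {
        pa <- tournament_pick(fits)
        pb <- tournament_pick(fits)
        kids <- ga_crossover(pop[[pa]], pop[[pb]], config$p_crossover)
        kids <- lapply(kids, ga_mutate, p = config$p_mutation)
        new_pop <- c(new_pop, kids)
      }
      pop <- new_pop[seq_len(config$pop_size)]
      fits <- vapply(pop, fit_of, double(1))
      gen_best <- max(fits)
      gen_run <- gen
      trace[gen] <- gen_best
      if (gen_best > best_overall + config$stall_tol) {
        best_overall <- gen_best
        stall <- 0L
      } else {
        best_overall <- max(best_overall, gen_best)
        stall <- stall + 1L
        if (stall >= config$stall_patience) break
      }
    }
    ord <- order(fits, decreasing = TRUE)
    structure(
      list(best_mask = pop[[ord[1]]], best_fitness = fits[ord[1]],
           fitness_trace = trace[seq_len(gen_run)],
           generations_run = gen_run, run_seed = run_seed),
      class = "qsrr_ga_run"
    )
  })
}

# Tournament selection of size 2: index of the fitter of two random
# chromosomes.
tournament_pick <- function(fits) {
  idx <- sample.int(length(fits), 2L, replace = TRUE)
  idx[which.max(fits[idx])]
}

#' Consensus over independent GA runs
#'
#' Computes per-descriptor selection frequencies over the run-best
#' masks and picks the final mask as the run-best mask with the
#' highest re-evaluated cross-validated fitness under a fresh fold
#' assignment; ties go to the mask whose members have the higher mean
#' selection frequency, then to the smaller mask.
#'
#' @param runs List of `qsrr_ga_run` objects.
#' @param X,y Data the runs were performed on.
#' @param config The [ga_config()] used.
#' @param seed Seed of the fresh fold assignment for re-evaluation.
#' @param descriptors Optional descriptor names.
#' @return Object of class `qsrr_ga`: `frequency` (tibble
#'   `descriptor`, `frequency`, `in_final`), `final_mask` (logical),
#'   `final_fitness`, `runs`, `run_table`.
#' @export
ga_consensus <- function(runs, X, y, config = ga_config(), seed = 1L,
                         descriptors = NULL) {
  if (length(runs) == 0) abort("need at least one GA run")
  X <- as.matrix(X)
  K <- ncol(X)
  descriptors <- descriptors %||% colnames(X) %||% sprintf("x%d", seq_len(K))
  masks <- lapply(runs, `[[`, "best_mask")
  freq <- Reduce(`+`, lapply(masks, as.integer)) / length(masks)

  fold_id <- make_folds(length(y), min(config$inner_folds, length(y)),
                        derive_seed(seed, "consensus"))
  refit <- vapply(masks, function(m) {
    ga_fitness(m, X, y, config, fold_id = fold_id)
  }, double(1))
  mean_freq <- vapply(masks, function(m) mean(freq[m]), double(1))
  sizes <- vapply(masks, sum, double(1))
  ord <- order(-refit, -mean_freq, sizes)
  best <- ord[1]

  run_table <- purrr::map_dfr(seq_along(runs), function(i) {
    tibble(run = i, run_seed = runs[[i]]$run_seed,
           generations = runs[[i]]$generations_run,
           n_selected = sum(masks[[i]]),
           run_fitness = runs[[i]]$best_fitness,
           refit_fitness = refit[i])
  })
  structure(
    list(frequency = tibble(descriptor = descriptors, frequency = freq,
                            in_final = masks[[best]]),
         final_mask = masks[[best]], final_fitness = refit[best],
         runs = runs, run_table = run_table, config = config),
    class = "qsrr_ga"
  )
}

#' Genetic-algorithm descriptor selection with multi-run consensus
#'
#' Runs `config$n_runs` independent GA searches (seeds derived from
#' `seed`) on the descriptor columns of `data` and combines them by
#' [ga_consensus()].
#'
#' @param data Tibble with `compound`, response and descriptor
#'   columns (already pretreated). When a `partition` column is
#'   present only training rows drive the selection.
#' @param response Response column name.
#' @param config A [ga_config()].
#' @param seed Master seed; run seeds are derived from it.
#' @param id Identifier column.
#' @return A `qsrr_ga` consensus object; `selected_descriptors()`
#'   extracts the final names, `tidy()` the frequency table.
#' @examples
#' sim <- simulate_qsrr(n = 40, n_desc = 12, n_true = 2, noise_sd = 0,
#'                      n_constant = 0, n_near_constant = 0, seed = 4)
#' cfg <- ga_config(max_generations = 30, stall_patience = 10, n_runs = 2)
#' sel <- ga_select(sim$data, config = cfg, seed = 1)
#' selected_descriptors(sel)
#' @export
ga_select <- function(data, response = "rt", config = ga_config(),
                      seed = 1L, id = "compound") {
  rows <- training_rows(data)
  nms <- descriptor_names(data, response = response, id = id)
  X <- as.matrix(data[rows, nms, drop = FALSE])
  y <- data[[response]][rows]
  runs <- lapply(seq_len(config$n_runs), function(r) {
    run_ga(X, y, config, run_seed = derive_seed(seed, "ga_run", r))
  })
  ga_consensus(runs, X, y, config, seed = seed, descriptors = nms)
}

#' Extract the final selected descriptor names
#'
#' @param x A `qsrr_ga` consensus object.
#' @return Character vector of descriptor names in the final mask.
#' @export
selected_descriptors <- function(x) {
  stopifnot(inherits(x, "qsrr_ga"))
  x$frequency$descriptor[x$final_mask]
}

#' @export
print.qsrr_ga <- function(x, ...) {
  cat(sprintf("GA descriptor selection: %d runs, %d descriptors in final mask (fitness %.4f)\n",
              length(x$runs), sum(x$final_mask), x$final_fitness))
  cat("final: ", paste(selected_descriptors(x), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn ga_select Selection-frequency table, most frequent
#'   first.
#' @param x A `qsrr_ga` object.
#' @param ... Unused.
#' @export
tidy.qsrr_ga <- function(x, ...) {
  dplyr::arrange(x$frequency, dplyr::desc(.data$frequency))
}

#' @describeIn ga_select One-row consensus summary.
#' @export
glance.qsrr_ga <- function(x, ...) {
  tibble(n_runs = length(x$runs),
         n_selected = sum(x$final_mask),
         final_fitness = x$final_fitness,
         mean_generations = mean(x$run_table$generations))
}
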