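#' Assemble a pipeline run configuration
#'
#' Bundles every stage's settings for [run_qsrr_pipeline()]. Either a
#' `dataset` path (CSV in the [read_descriptor_table()] dialect) or a
#' `synthetic` list of [simulate_qsrr()] arguments must be given. The
#' master `seed` deterministically derives all stage seeds, so a rerun
#' of the same configuration is reproducible bit for bit.
#'
#' @param dataset Optional path to a descriptor CSV.
#' @param synthetic Optional named list passed to [simulate_qsrr()].
#' @param partition_scheme `"fixed_80_20"` or `"stratified_70_15_15"`.
#' @param r_threshold,near_constant_fraction Pre-treatment thresholds.
#' @param ga A [ga_config()].
#' @param model Final model: `"pls"`, `"kpls"` or `"ann"`.
#' @param n_lv Latent variables for `"pls"`/`"kpls"`.
#' @param sigma Kernel width for `"kpls"` (`NULL`: median heuristic).
#' @param ann An [ann_config()] for `model = "ann"`.
#' @param hidden Hidden size for `"ann"`; `NULL` scans.
#' @param group_size Leave-group-out group size.
#' @param seed Master seed.
#' @return A list of class `qsrr_config`.
#' @export
qsrr_config <- function(dataset = NULL, synthetic = NULL,
                        partition_scheme = c("fixed_80_20",
                                             "stratified_70_15_15"),
                        r_threshold = 0.90, near_constant_fraction = 0.95,
                        ga = ga_config(), model = c("pls", "kpls", "ann"),
                        n_lv = NULL, sigma = NULL, ann = ann_config(),
                        hidden = NULL, group_size = 7L, seed = 1L) {
  partition_scheme <- match.arg(partition_scheme)
  model <- match.arg(model)
  if (is.null(dataset) && is.null(synthetic)) {
    abort("config needs either a dataset path or a synthetic spec")
  }
  if (!is.null(dataset) && !is.null(synthetic)) {
    abort("give either a dataset path or a synthetic spec, not both")
  }
  if (!is.null(synthetic)) {
    unknown <- setdiff(names(synthetic), names(formals(simulate_qsrr)))
    if (length(unknown) > 0) {
      abort(sprintf("unknown synthetic spec key(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  if (is.null(n_lv)) n_lv <- if (model == "kpls") 3L else 4L
  structure(list(dataset = dataset, synthetic = synthetic,
                 partition_scheme = partition_scheme,
                 r_threshold = r_threshold,
                 near_constant_fraction = near_constant_fraction,
                 ga = ga, model = model, n_lv = n_lv, sigma = sigma,
                 ann = ann, hidden = hidden,
                 group_size = as.integer(group_size),
                 seed = as.integer(seed)),
            class = "qsrr_config")
}

#' Run the full QSRR pipeline
#'
#' Executes the stages in order -- load or simulate, partition,
#' pre-treat, GA descriptor selection, final model fit,
#' leave-group-out and external-test validation -- writing every
#' intermediate artifact to `out_dir` and returning (and writing) a
#' run manifest with the configuration echo, per-stage seeds, stage
#' timings and an MD5 inventory of the outputs.
#'
#' @param config A [qsrr_config()].
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly, as a list (also written to
#'   `manifest.json`). Output files: `data.csv`, `pretreat_report.csv`,
#'   `ga_frequency.csv`, `model.json`, `metrics.csv`, `residuals.csv`,
#'   `cv.csv`.
#' @export
run_qsrr_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "qsrr_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  data <- stage("data", {
    if (!is.null(config$dataset)) {
      read_descriptor_table(config$dataset)
    } else {
      args <- config$synthetic
      args$seed <- args$seed %||% derive_seed(seed, "simulate")
      do.call(simulate_qsrr, args)$data
    }
  })
  data <- stage("partition", {
    make_partition(data, config$partition_scheme,
                   seed = derive_seed(seed, "partition"))
  })
  write_descriptor_table(data, file.path(out_dir, "data.csv"))

  pt <- stage("pretreat", {
    pretreat(data, r_threshold = config$r_threshold,
             near_constant_fraction = config$near_constant_fraction)
  })
  readr::write_csv(tidy.qsrr_pretreat(pt),
                   file.path(out_dir, "pretreat_report.csv"),
                   progress = FALSE)

  sel <- stage("select", {
    ga_select(pt$data, config = config$ga,
              seed = derive_seed(seed, "ga"))
  })
  readr::write_csv(sel$frequency, file.path(out_dir, "ga_frequency.csv"),
                   progress = FALSE)

  keep <- c(intersect(c("compound", "rt", "partition"), names(pt$data)),
            selected_descriptors(sel))
  model_data <- pt$data[keep]

  fit <- stage("fit", {
    switch(config$model,
      pls = qsrr_pls(model_data, n_lv = config$n_lv),
      kpls = qsrr_kpls(model_data, sigma = config$sigma,
                       n_lv = config$n_lv),
      ann = qsrr_ann(model_data, hidden = config$hidden,
                     config = config$ann,
                     seed = derive_seed(seed, "ann"))
    )
  })
  writeLines(jsonlite::toJSON(serialize_model(fit), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "model.json"))

  val <- stage("validate", {
    cv <- lgo_cv(model_data[training_rows(model_data), , drop = FALSE],
                 spec = model_spec(
                   if (config$model == "ann") "pls" else config$model,
                   n_lv = config$n_lv, sigma = config$sigma),
                 group_size = config$group_size,
                 seed = derive_seed(seed, "cv"))
    ev <- evaluate_model(fit, model_data)
    list(cv = cv, eval = ev)
  })
  readr::write_csv(dplyr::mutate(val$eval$metrics, model = config$model,
                                 .before = 1),
                   file.path(out_dir, "metrics.csv"), progress = FALSE)
  write_predictions(val$eval$residuals, file.path(out_dir, "residuals.csv"))
  readr::write_csv(
    dplyr::bind_cols(val$cv$predictions,
                     tibble(q2 = val$cv$q2, rmsecv = val$cv$rmsecv)),
    file.path(out_dir, "cv.csv"), progress = FALSE)

  files <- c("data.csv", "pretreat_report.csv", "ga_frequency.csv",
             "model.json", "metrics.csv", "residuals.csv", "cv.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gcqsrr")),
    config = config_echo(config),
    seeds = list(master = seed,
                 simulate = derive_seed(seed, "simulate"),
                 partition = derive_seed(seed, "partition"),
                 ga = derive_seed(seed, "ga"),
                 ann = derive_seed(seed, "ann"),
                 cv = derive_seed(seed, "cv")),
    timings_s = timings,
    outputs = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$outputs) <- files
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# JSON-friendly echo of a config (drops NULLs, flattens classes).
config_echo <- function(config) {
  e <- unclass(config)
  e$ga <- unclass(e$ga)
  e$ann <- unclass(e$ann)
  e[!vapply(e, is.null, logical(1))]
}

# JSON-serializable summary of any fitted retention model.
serialize_model <- function(fit) {
  if (inherits(fit, "qsrr_pls")) {
    list(model = "pls", n_lv = fit$n_lv,
         descriptors = fit$scaler$descriptors,
         coefficients = as.list(fit$coefficients),
         intercept = fit$intercept,
         scaler = list(means = as.list(fit$scaler$means),
                       sds = as.list(fit$scaler$sds)))
  } else if (inherits(fit, "qsrr_kpls")) {
    list(model = "kpls", n_lv = fit$n_lv, sigma = fit$sigma,
         descriptors = fit$scaler$descriptors,
         dual_coef = fit$core$dual_coef,
         y_mean = fit$core$y_mean,
         kernel_row_means = fit$core$row_means,
         kernel_grand_mean = fit$core$grand_mean,
         scaler = list(means = as.list(fit$scaler$means),
                       sds = as.list(fit$scaler$sds)))
  } else if (inherits(fit, "qsrr_ann")) {
    list(model = "ann", hidden = fit$hidden,
         descriptors = fit$scaler$descriptors,
         input_weights = fit$net$W1, output_weights = fit$net$w2,
         best_val_rmse = fit$net$best_val_rmse,
         scaler = list(means = as.list(fit$scaler$means),
                       sds = as.list(fit$scaler$sds)))
  } else {
    abort("unknown model class")
  }
}

#' Compare pipeline runs side by side
#'
#' Joins the metric blocks of several manifest directories produced by
#' [run_qsrr_pipeline()] over the same dataset into one table, ordered
#' by test RMSE.
#'
#' @param out_dirs Character vector of pipeline output directories.
#' @return Tibble with one row per model and partition block.
#' @export
compare_models <- function(out_dirs) {
  if (length(out_dirs) < 2) abort("need at least two runs to compare")
  checks <- vapply(out_dirs, function(d) {
    unname(tools::md5sum(file.path(d, "data.csv")))
  }, character(1))
  if (length(unique(checks)) > 1) {
    abort("runs were made on different datasets; comparison is not meaningful")
  }
  tabs <- purrr::map_dfr(out_dirs, function(d) {
    m <- readr::read_csv(file.path(d, "metrics.csv"),
                         col_types = readr::cols(), progress = FALSE)
    res <- readr::read_csv(file.path(d, "residuals.csv"),
                           col_types = readr::cols(), progress = FALSE)
    dplyr::mutate(m, pearson_r_check = vapply(m$partition, function(pt) {
      rows <- res$partition == pt
      stats::cor(res$y_exp[rows], res$y_pred[rows])
    }, double(1)), dir = d)
  })
  test_order <- dplyr::arrange(dplyr::filter(tabs, .data$partition == "test"),
                               .data$rmse)
  dplyr::arrange(tabs, match(.data$model, test_order$model),
                 .data$partition)
}
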