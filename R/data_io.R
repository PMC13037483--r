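#' Retention times of 75 narcotic and hazardous drugs
#'
#' Loads the packaged dataset of 75 narcotic and hazardous drugs measured
#' by gas chromatography on a non-polar HP-5 column: experimental
#' retention time (minutes), compound class, molecular weight (g/mol),
#' XlogP3 hydrophobicity, hydrogen-bond donor count, and the fixed
#' train/test partition (compounds 1-60 train, 61-75 test).
#'
#' @return A tibble with 75 rows and columns `index`, `name`,
#'   `rt_exp_min`, `category`, `mw`, `xlogp3`, `hbd`, `partition`.
#' @examples
#' drugs <- load_drug_rt()
#' dplyr::count(drugs, partition)
#' @export
load_drug_rt <- function() {
  path <- system.file("extdata", "drug_retention.csv", package = "gcqsrr",
                      mustWork = TRUE)
  spec <- readr::cols(
    index = readr::col_integer(),
    name = readr::col_character(),
    rt_exp_min = readr::col_double(),
    category = readr::col_character(),
    mw = readr::col_double(),
    xlogp3 = readr::col_double(),
    hbd = readr::col_integer(),
    partition = readr::col_character()
  )
  x <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_compound_records(x)
  x
}

validate_compound_records <- function(x) {
  for (col in c("index", "name", "rt_exp_min", "mw", "xlogp3", "hbd",
                "partition")) {
    if (!col %in% names(x)) abort(sprintf("fixture is missing column '%s'", col))
  }
  for (col in c("rt_exp_min", "mw", "xlogp3", "hbd")) {
    bad <- which(is.na(x[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("malformed fixture: column '%s' unparseable at row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
  }
  if (anyDuplicated(x$name)) {
    abort(sprintf("duplicate compound name(s): %s",
                  paste(unique(x$name[duplicated(x$name)]), collapse = ", ")))
  }
  if (any(x$rt_exp_min <= 0)) abort("retention times must be positive")
  if (any(x$mw <= 0)) abort("molecular weights must be positive")
  if (any(x$hbd < 0)) abort("hydrogen-bond donor counts must be non-negative")
  if (!all(x$partition %in% c("train", "test"))) {
    abort("partition labels must be 'train' or 'test'")
  }
  invisible(x)
}

#' Read a descriptor table from delimited text
#'
#' Reads a compounds-by-descriptors matrix from a delimited text file with
#' a header row of descriptor names, one identifier column and one
#' response column (retention time, minutes). All remaining columns must
#' be numeric descriptors.
#'
#' @param path Path to a delimited text file.
#' @param response Name of the response column in the file.
#' @param id Name of the identifier column in the file.
#' @param delim Field delimiter (default comma).
#' @return A tibble with columns `compound`, `rt` and one numeric column
#'   per descriptor, in file order. A `partition` column is carried
#'   through when present in the file.
#' @export
read_descriptor_table <- function(path, response = "rt", id = "compound",
                                  delim = ",") {
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort(sprintf("duplicated descriptor name(s) in header: %s",
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (!response %in% names(raw)) {
    abort(sprintf("response column '%s' not found in '%s'", response, path))
  }
  if (!id %in% names(raw)) {
    abort(sprintf("id column '%s' not found in '%s'", id, path))
  }
  if (anyDuplicated(names(raw))) {
    abort(sprintf("duplicated descriptor name(s) in header: %s",
                  paste(unique(names(raw)[duplicated(names(raw))]),
                        collapse = ", ")))
  }
  out <- raw
  names(out)[names(out) == id] <- "compound"
  names(out)[names(out) == response] <- "rt"
  out$compound <- as.character(out$compound)
  if (anyDuplicated(out$compound)) abort("duplicate compound identifiers")
  desc <- setdiff(names(out), c("compound", "rt", "partition"))
  for (col in c("rt", desc)) {
    if (!is.numeric(out[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(out[[col]]))))
      abort(sprintf("non-numeric value in column '%s' at row(s) %s",
                    col, paste(utils::head(bad, 5), collapse = ", ")))
    }
    check_numeric_col(out[[col]], col)
  }
  dplyr::relocate(as_tibble(out), "compound", "rt")
}

#' Write a descriptor table to delimited text
#'
#' Inverse of [read_descriptor_table()]: values round-trip to full
#' double precision.
#'
#' @param data Tibble with `compound`, `rt` and descriptor columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a prediction/residual table
#'
#' Writes one row per compound with columns
#' (`id`, `y_exp`, `y_pred`, `residual`, `partition`), residuals being
#' experimental minus predicted retention time in minutes.
#'
#' @param residuals Tibble as produced by [evaluate_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(residuals, path) {
  need <- c("id", "y_exp", "y_pred", "residual", "partition")
  if (!all(need %in% names(residuals))) {
    abort(sprintf("residual table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  readr::write_csv(residuals[need], path, progress = FALSE)
  invisible(path)
}

#' Convert the packaged drug dataset to a modelling table
#'
#' Maps the fixture's bulk physicochemical columns (`mw`, `xlogp3`,
#' `hbd`) into the `compound`/`rt`/descriptor layout that the modelling
#' functions expect, keeping the printed train/test partition.
#'
#' @param drugs Tibble from [load_drug_rt()].
#' @return A modelling tibble with columns `compound`, `rt`,
#'   `partition`, `mw`, `xlogp3`, `hbd`.
#' @export
drug_rt_table <- function(drugs = load_drug_rt()) {
  tibble(
    compound = drugs$name,
    rt = drugs$rt_exp_min,
    partition = drugs$partition,
    mw = drugs$mw,
    xlogp3 = drugs$xlogp3,
    hbd = as.double(drugs$hbd)
  )
}

#' Assign a train/validation/test partition
#'
#' Two schemes are supported. `"fixed_80_20"` honours an existing
#' `partition` column when present; otherwise rows are ranked by the
#' response and every fifth rank is held out as test (an RT-sorted
#' round-robin), giving ceiling(0.8 n) training rows. The scheme used by
#' the neural-network workflow, `"stratified_70_15_15"`, sorts rows by
#' response, forms consecutive strata of about 7 compounds, and samples
#' validation and test rows within each stratum so that the global split
#' is 70/15/15 and every part of the retention-time distribution is
#' represented in all three sets.
#'
#' @param data Tibble with a response column.
#' @param scheme `"fixed_80_20"` or `"stratified_70_15_15"`.
#' @param response Name of the response column.
#' @param seed Integer seed controlling the within-stratum draws.
#' @param stratum_size Target stratum size for the stratified scheme.
#' @return `data` with a `partition` column over
#'   \{"train", "val", "test"\} (no `"val"` under `fixed_80_20`).
#' @export
make_partition <- function(data, scheme = c("fixed_80_20",
                                            "stratified_70_15_15"),
                           response = "rt", seed = 1L, stratum_size = 7L) {
  scheme <- match.arg(scheme)
  n <- nrow(data)
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("response column '%s' not found", response))
  if (scheme == "fixed_80_20") {
    if ("partition" %in% names(data) &&
        all(data$partition %in% c("train", "test"))) {
      return(data)
    }
    rk <- rank(y, ties.method = "first")
    part <- ifelse(rk %% 5L == 0L, "test", "train")
    data$partition <- part
    return(as_tibble(data))
  }
  if (n < 10) abort("stratified_70_15_15 needs at least 10 rows")
  ord <- order(y)
  strata <- split(ord, ceiling(seq_along(ord) / stratum_size))
  n_val_target <- round(0.15 * n)
  n_test_target <- round(0.15 * n)
  part <- rep("train", n)
  withr::with_seed(seed, {
    sizes <- cumsum(lengths(strata))
    val_cum <- round(0.15 * sizes)
    test_cum <- round(0.15 * sizes)
    # Cumulative rounding gives exact global counts while spreading the
    # held-out rows across the response distribution.
    val_cum[length(val_cum)] <- n_val_target
    test_cum[length(test_cum)] <- n_test_target
    v_prev <- 0L; t_prev <- 0L
    for (s in seq_along(strata)) {
      rows <- strata[[s]][sample.int(length(strata[[s]]))]
      nv <- val_cum[s] - v_prev
      nt <- test_cum[s] - t_prev
      if (nv + nt > length(rows)) abort("stratum too small for split")
      if (nv > 0) part[rows[seq_len(nv)]] <- "val"
      if (nt > 0) part[rows[nv + seq_len(nt)]] <- "test"
      v_prev <- val_cum[s]; t_prev <- test_cum[s]
    }
  })
  data$partition <- part
  as_tibble(data)
}
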