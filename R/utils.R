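#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Columns that are never treated as molecular descriptors.
.reserved_cols <- c("compound", "rt", "partition", "index", "name",
                    "rt_exp_min", "category", "partition_label")

#' List descriptor columns of a QSRR table
#'
#' Descriptor columns are all numeric columns that are not the compound
#' identifier, the response, or a partition label.
#'
#' @param data A data frame of compounds by descriptors.
#' @param response Name of the response column (retention time, minutes).
#' @param id Name of the compound identifier column.
#' @return Character vector of descriptor column names, in table order.
#' @export
descriptor_names <- function(data, response = "rt", id = "compound") {
  stopifnot(is.data.frame(data))
  cand <- setdiff(names(data), c(response, id, .reserved_cols))
  cand[vapply(data[cand], is.numeric, logical(1))]
}

# Extract the descriptor matrix (n x K) with rownames from the id column.
descriptor_matrix <- function(data, response = "rt", id = "compound") {
  nms <- descriptor_names(data, response = response, id = id)
  X <- as.matrix(data[nms])
  if (id %in% names(data)) rownames(X) <- as.character(data[[id]])
  storage.mode(X) <- "double"
  X
}

# Deterministic small-integer seed derived from a master seed and a label.
# Keeps results below 2^31 - 1 so the value is a valid R integer seed.
derive_seed <- function(master, label, index = 0L) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 31 + as.double(index)) %% 2147483647)
}

# Validate that a numeric vector is finite and non-missing.
check_numeric_col <- function(x, colname) {
  bad <- which(!is.finite(x))
  if (length(bad) > 0) {
    abort(sprintf("column '%s' has missing or non-numeric values at row(s) %s",
                  colname, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
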