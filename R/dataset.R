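# Property datasets: SMILES strings with one or more labelled tasks.

#' Construct a property dataset
#'
#' @param smiles Character vector.
#' @param y Numeric matrix (one column per task); `NA` entries are masked.
#' @param task_names Character vector of task names.
#' @param task_type `"classification"` or `"regression"`.
#' @param validate Parse every SMILES and drop failures (with a warning
#'   giving the count); default `TRUE`.
#' @return An object of class `property_dataset`: `smiles`, `y`, `mask`
#'   (logical, `TRUE` = observed), `task_names`, `task_type`.
#' @export
property_dataset <- function(smiles, y, task_names = NULL,
                             task_type = c("classification", "regression"),
                             validate = TRUE) {
  task_type <- match.arg(task_type)
  y <- as.matrix(y)
  stopifnot(length(smiles) == nrow(y))
  if (is.null(task_names))
    task_names <- colnames(y) %||% paste0("task", seq_len(ncol(y)))
  if (validate) {
    ok <- vapply(smiles, function(s)
      !inherits(tryCatch(parse_smiles(s), error = function(e) e), "error"),
      logical(1))
    if (any(!ok)) {
      warning("dropped ", sum(!ok), " record(s) with unparsable SMILES")
      smiles <- smiles[ok]
      y <- y[ok, , drop = FALSE]
    }
  }
  mask <- !is.na(y)
  if (task_type == "classification") {
    bad <- mask & !(y %in% c(0, 1))
    if (any(bad)) stop("classification labels must be 0/1 where observed")
  }
  structure(list(smiles = smiles, y = y, mask = mask,
                 task_names = task_names, task_type = task_type),
            class = "property_dataset")
}

#' Load a property dataset from CSV
#'
#' Rows whose SMILES fail to parse are dropped with a warning carrying the
#' count; empty or `NA` label cells are masked (they never enter a loss).
#'
#' @param path CSV file path.
#' @param smiles_column Name of the SMILES column (default `"smiles"`).
#' @param task_columns Character vector of label column names; default:
#'   every column except the SMILES column.
#' @param task_type `"classification"` or `"regression"`.
#' @return A `property_dataset`.
#' @export
load_dataset <- function(path, smiles_column = "smiles", task_columns = NULL,
                         task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_column %in% names(df))
    stop("configuration error: SMILES column '", smiles_column,
         "' not present in ", path)
  if (is.null(task_columns)) task_columns <- setdiff(names(df), smiles_column)
  miss <- setdiff(task_columns, names(df))
  if (length(miss))
    stop("configuration error: task column(s) missing: ",
         paste(miss, collapse = ", "))
  y <- as.matrix(as.data.frame(lapply(df[task_columns], function(col) {
    if (is.character(col)) col[!nzchar(trimws(col))] <- NA
    as.numeric(col)
  })))
  colnames(y) <- task_columns
  property_dataset(df[[smiles_column]], y, task_columns, task_type)
}

#' Write a property dataset to CSV
#' @param ds A `property_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "property_dataset"))
  df <- data.frame(smiles = ds$smiles, stringsAsFactors = FALSE)
  for (k in seq_along(ds$task_names)) df[[ds$task_names[k]]] <- ds$y[, k]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.property_dataset <- function(x, ...) {
  cat(sprintf("<property_dataset> %d molecules, %d %s task(s): %s\n",
              length(x$smiles), ncol(x$y), x$task_type,
              paste(utils::head(x$task_names, 5), collapse = ", ")))
  invisible(x)
}

#' @export
length.property_dataset <- function(x) length(x$smiles)

#' Subset a property dataset by record index
#' @param x A `property_dataset`.
#' @param idx Integer indices.
#' @param ... Unused.
#' @export
`[.property_dataset` <- function(x, idx, ...) {
  structure(list(smiles = x$smiles[idx], y = x$y[idx, , drop = FALSE],
                 mask = x$mask[idx, , drop = FALSE],
                 task_names = x$task_names, task_type = x$task_type),
            class = "property_dataset")
}
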