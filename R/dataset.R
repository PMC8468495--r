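#' Validate an in-memory table against a schema
#'
#' Checks that every schema column is present, every protected-attribute
#' cell is one of its declared levels, and every temporal cell is a finite
#' number. Extra columns are retained untouched as unprotected attributes.
#' Row order is preserved and no value is mutated.
#'
#' @param data A data frame.
#' @param schema A [dataset_schema()].
#' @param role Either `"real"` or `"synthetic"`.
#' @return An object of class `synfair_dataset` with elements `role`,
#'   `data` and `n`.
#' @export
as_tabular_dataset <- function(data, schema, role = c("real", "synthetic")) {
  role <- match.arg(role)
  stopifnot(inherits(schema, "synfair_schema"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) < 1) {
    stop("dataset must contain at least one row", call. = FALSE)
  }
  missing_cols <- setdiff(schema_columns(schema), names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error: column(s) missing from data: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (attr in names(schema$protected_attrs)) {
    vals <- as.character(data[[attr]])
    bad <- which(is.na(vals) | !(vals %in% schema$protected_attrs[[attr]]))
    if (length(bad) > 0) {
      stop(sprintf(
        "level error: row %d, column '%s': value '%s' is not a declared level",
        bad[1], attr, vals[bad[1]]), call. = FALSE)
    }
    data[[attr]] <- vals
  }
  for (col in unlist(schema$temporal_features, use.names = FALSE)) {
    vals <- data[[col]]
    if (is.character(vals)) {
      suppressWarnings(num <- as.numeric(vals))
      if (anyNA(num) ) {
        bad <- which(is.na(num))[1]
        stop(sprintf(
          "parse error: row %d, column '%s': '%s' is not numeric",
          bad, col, vals[bad]), call. = FALSE)
      }
      vals <- num
    }
    if (!is.numeric(vals) || any(!is.finite(vals))) {
      bad <- which(!is.finite(as.numeric(vals)))[1]
      stop(sprintf("parse error: row %s, column '%s': non-finite temporal value",
                   ifelse(length(bad), bad, "?"), col), call. = FALSE)
    }
    data[[col]] <- as.numeric(vals)
  }
  structure(list(role = role, data = data, n = nrow(data)),
            class = "synfair_dataset")
}

#' Load a delimited-text dataset against a declared schema
#'
#' Reads a UTF-8, comma-separated file with a header row and validates it
#' with [as_tabular_dataset()]. The decimal separator is `"."`.
#'
#' @param path Path to the CSV file.
#' @inheritParams as_tabular_dataset
#' @return A `synfair_dataset`.
#' @examples
#' sch <- dataset_schema(list(gender = c("Male", "Female")))
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(gender = c("Male", "Female")), f, row.names = FALSE)
#' load_dataset(f, sch, role = "real")$n
#' @export
load_dataset <- function(path, schema, role = c("real", "synthetic")) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  }
  data <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  as_tabular_dataset(data, schema, role)
}

#' Write a dataset back to CSV
#'
#' Inverse of [load_dataset()]: writes the table with a header row so that
#' reloading under the same schema reproduces the protected-level counts
#' and temporal values exactly (within decimal text representation).
#'
#' @param dataset A `synfair_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synfair_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bind a real and a synthetic dataset into an auditable pair
#'
#' The real and synthetic tables may have different numbers of rows; they
#' are treated as independent samples throughout. Both must conform to the
#' same schema and carry the matching role.
#'
#' @param real A `synfair_dataset` with role `"real"`.
#' @param synthetic A `synfair_dataset` with role `"synthetic"`.
#' @param schema The shared [dataset_schema()].
#' @return An object of class `synfair_pair`.
#' @export
dataset_pair <- function(real, synthetic, schema) {
  stopifnot(inherits(schema, "synfair_schema"))
  if (!inherits(real, "synfair_dataset") ||
      !inherits(synthetic, "synfair_dataset")) {
    stop("both arguments must be synfair_dataset objects", call. = FALSE)
  }
  if (real$role != "real" || synthetic$role != "synthetic") {
    stop(sprintf("configuration error: roles must be real/synthetic, got %s/%s",
                 real$role, synthetic$role), call. = FALSE)
  }
  for (ds in list(real, synthetic)) {
    missing_cols <- setdiff(schema_columns(schema), names(ds$data))
    if (length(missing_cols) > 0) {
      stop(sprintf("schema error: column(s) missing: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(schema = schema, real = real, synthetic = synthetic),
            class = "synfair_pair")
}

#' @export
print.synfair_dataset <- function(x, ...) {
  cat(sprintf("<synfair_dataset role=%s n=%d cols=%d>\n",
              x$role, x$n, ncol(x$data)))
  invisible(x)
}

#' @export
print.synfair_pair <- function(x, ...) {
  cat(sprintf("<synfair_pair real n=%d, synthetic n=%d, %d protected attr(s), %d temporal feature(s)>\n",
              x$real$n, x$synthetic$n,
              length(x$schema$protected_attrs),
              length(x$schema$temporal_features)))
  invisible(x)
}
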