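#' Declare the schema of a paired real/synthetic dataset
#'
#' A schema names the categorical protected attributes (with their declared
#' levels) and, for longitudinal data, ordered blocks of temporal columns
#' (one block per temporal feature, each with the same number of time
#' points within a feature). All subgroup enumeration and every metric in
#' the package is driven by a schema, so both the real and the synthetic
#' table of a pair must conform to the same one.
#'
#' @param protected_attrs Named list; each element is a character vector of
#'   the declared levels of one protected attribute, in display order.
#'   At least one attribute is required and levels must be unique.
#' @param temporal_features Named list (possibly empty); each element is a
#'   character vector of the column names holding that feature's time
#'   points, in temporal order.
#' @param aggregation_statistic Default statistic used to collapse a
#'   subgroup's rows into one series per temporal feature: `"mean"`,
#'   `"count"` (rows with a nonzero value at each time point, for binary
#'   diagnosis columns) or `"sum"`.
#' @param id_column Optional name of an identifier column; carried through
#'   but ignored by all metrics.
#'
#' @return An object of class `synfair_schema`.
#' @examples
#' sch <- dataset_schema(
#'   protected_attrs = list(gender = c("Male", "Female"),
#'                          age = c("15-24", "25-64", "65+")),
#'   temporal_features = list(sleep = paste0("sleep_h", 1:6))
#' )
#' sch
#' @export
dataset_schema <- function(protected_attrs,
                           temporal_features = list(),
                           aggregation_statistic = c("mean", "count", "sum"),
                           id_column = NULL) {
  aggregation_statistic <- match.arg(aggregation_statistic)
  if (!is.list(protected_attrs) || length(protected_attrs) == 0 ||
      is.null(names(protected_attrs)) || any(names(protected_attrs) == "")) {
    stop("`protected_attrs` must be a non-empty named list of level vectors",
         call. = FALSE)
  }
  if (anyDuplicated(names(protected_attrs))) {
    stop("protected attribute names must be unique", call. = FALSE)
  }
  for (attr in names(protected_attrs)) {
    lv <- protected_attrs[[attr]]
    if (!is.character(lv) || length(lv) == 0 || anyDuplicated(lv) ||
        any(is.na(lv)) || any(lv == "")) {
      stop(sprintf("levels of attribute '%s' must be unique non-empty strings",
                   attr), call. = FALSE)
    }
  }
  if (!is.list(temporal_features)) {
    stop("`temporal_features` must be a (possibly empty) named list",
         call. = FALSE)
  }
  if (length(temporal_features) > 0) {
    if (is.null(names(temporal_features)) || any(names(temporal_features) == "")) {
      stop("temporal features must be named", call. = FALSE)
    }
    for (feat in names(temporal_features)) {
      cols <- temporal_features[[feat]]
      if (!is.character(cols) || length(cols) < 1 || anyDuplicated(cols)) {
        stop(sprintf("temporal feature '%s' needs >= 1 unique column names",
                     feat), call. = FALSE)
      }
    }
    all_cols <- unlist(temporal_features, use.names = FALSE)
    if (anyDuplicated(all_cols)) {
      stop("temporal column names must not be shared between features",
           call. = FALSE)
    }
    if (any(all_cols %in% names(protected_attrs))) {
      stop("temporal column names must be disjoint from protected attributes",
           call. = FALSE)
    }
  }
  if (!is.null(id_column)) {
    stopifnot(is.character(id_column), length(id_column) == 1)
  }
  structure(
    list(protected_attrs = protected_attrs,
         temporal_features = temporal_features,
         aggregation_statistic = aggregation_statistic,
         id_column = id_column),
    class = "synfair_schema"
  )
}

#' @export
print.synfair_schema <- function(x, ...) {
  cat("<synfair_schema>\n")
  cat("  protected attributes:\n")
  for (attr in names(x$protected_attrs)) {
    cat(sprintf("    %s: %s\n", attr,
                paste(x$protected_attrs[[attr]], collapse = ", ")))
  }
  if (length(x$temporal_features) > 0) {
    cat("  temporal features:\n")
    for (feat in names(x$temporal_features)) {
      cat(sprintf("    %s: %d time points\n", feat,
                  length(x$temporal_features[[feat]])))
    }
    cat(sprintf("  aggregation statistic: %s\n", x$aggregation_statistic))
  }
  invisible(x)
}

#' Number of time points of each temporal feature
#' @param schema A [dataset_schema()].
#' @return Named integer vector, one entry per temporal feature.
#' @export
temporal_lengths <- function(schema) {
  stopifnot(inherits(schema, "synfair_schema"))
  vapply(schema$temporal_features, length, integer(1))
}

schema_columns <- function(schema) {
  c(names(schema$protected_attrs),
    unlist(schema$temporal_features, use.names = FALSE))
}

#' Read or write a schema as a YAML config file
#'
#' The config mirrors the schema fields exactly: `protected_attrs` maps
#' attribute name to level list, `temporal_features` maps feature name to
#' column-name list, plus scalar `aggregation_statistic` and optional
#' `id_column`.
#'
#' @param path Path of the YAML file.
#' @return `read_schema_config()` returns a `synfair_schema`;
#'   `write_schema_config()` returns `path` invisibly.
#' @export
read_schema_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("schema config '%s' does not exist", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("protected_attrs")) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("schema config missing required field '%s'", field),
           call. = FALSE)
    }
  }
  dataset_schema(
    protected_attrs = lapply(cfg$protected_attrs, as.character),
    temporal_features = lapply(cfg$temporal_features %||% list(), as.character),
    aggregation_statistic = cfg$aggregation_statistic %||% "mean",
    id_column = cfg$id_column
  )
}

#' @rdname read_schema_config
#' @param schema A [dataset_schema()].
#' @export
write_schema_config <- function(schema, path) {
  stopifnot(inherits(schema, "synfair_schema"))
  cfg <- list(protected_attrs = schema$protected_attrs,
              temporal_features = schema$temporal_features,
              aggregation_statistic = schema$aggregation_statistic)
  if (!is.null(schema$id_column)) cfg$id_column <- schema$id_column
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
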