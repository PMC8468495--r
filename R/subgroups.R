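#' Define a protected subgroup
#'
#' A subgroup is a conjunction of single levels: it assigns exactly one
#' declared level to each of a non-empty subset of the protected
#' attributes. A row belongs to the subgroup (its binary membership
#' g(x) = 1) iff it matches every assigned level; the complement
#' g(x) = 0 is all remaining rows of the same dataset.
#'
#' @param assignment Named character vector mapping attribute names to one
#'   level each.
#' @param schema A [dataset_schema()]; used to validate the assignment and
#'   to order attributes canonically.
#' @return An object of class `synfair_subgroup` with elements
#'   `assignment` (in schema attribute order) and `order`.
#' @examples
#' sch <- dataset_schema(list(gender = c("Male", "Female"),
#'                            age = c("young", "old")))
#' subgroup(c(age = "old", gender = "Female"), sch)
#' @export
subgroup <- function(assignment, schema) {
  stopifnot(inherits(schema, "synfair_schema"))
  assignment <- unlist(assignment)
  if (length(assignment) == 0 || is.null(names(assignment)) ||
      any(names(assignment) == "")) {
    stop("subgroup assignment must be a non-empty named vector", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("subgroup assigns an attribute more than once", call. = FALSE)
  }
  unknown <- setdiff(names(assignment), names(schema$protected_attrs))
  if (length(unknown) > 0) {
    stop(sprintf("schema error: unknown protected attribute(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (attr in names(assignment)) {
    if (!(assignment[[attr]] %in% schema$protected_attrs[[attr]])) {
      stop(sprintf("level error: '%s' is not a declared level of '%s'",
                   assignment[[attr]], attr), call. = FALSE)
    }
  }
  ord <- intersect(names(schema$protected_attrs), names(assignment))
  assignment <- assignment[ord]
  structure(list(assignment = assignment, order = length(assignment)),
            class = "synfair_subgroup")
}

#' Serialize a subgroup as an "attr=level&attr=level" string
#'
#' Attributes appear in schema order. The inverse is [parse_subgroup()].
#'
#' @param sg A `synfair_subgroup`.
#' @return A single string.
#' @export
subgroup_label <- function(sg) {
  stopifnot(inherits(sg, "synfair_subgroup"))
  paste(sprintf("%s=%s", names(sg$assignment), sg$assignment), collapse = "&")
}

#' @rdname subgroup_label
#' @param label A label produced by [subgroup_label()].
#' @param schema The [dataset_schema()] to validate against.
#' @export
parse_subgroup <- function(label, schema) {
  parts <- strsplit(label, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(vapply(kv, length, integer(1)) != 2)) {
    stop(sprintf("malformed subgroup label '%s'", label), call. = FALSE)
  }
  assignment <- vapply(kv, `[`, character(1), 2)
  names(assignment) <- vapply(kv, `[`, character(1), 1)
  subgroup(assignment, schema)
}

#' @export
print.synfair_subgroup <- function(x, ...) {
  cat(sprintf("<subgroup %s>\n", subgroup_label(x)))
  invisible(x)
}

#' @export
format.synfair_subgroup <- function(x, ...) subgroup_label(x)

#' Enumerate the subgroup lattice of a schema
#'
#' Generates every subgroup definable as a conjunction of declared levels
#' over up to `max_order` protected attributes. With `max_order = "all"`
#' and level counts L1, ..., Ld the lattice has prod(Li + 1) - 1 subgroups.
#' Ordering is deterministic: by order ascending, then by attribute-subset
#' position in schema order, then by level order in the schema (earlier
#' attributes vary slowest).
#'
#' @param schema A [dataset_schema()].
#' @param max_order Positive integer, or `"all"` (the default) for the
#'   full lattice.
#' @return A list of `synfair_subgroup` objects.
#' @examples
#' sch <- dataset_schema(list(gender = c("Male", "Female"),
#'                            age = c("young", "old")))
#' length(enumerate_subgroups(sch))          # 3*3 - 1 = 8
#' length(enumerate_subgroups(sch, 1))       # 4
#' @export
enumerate_subgroups <- function(schema, max_order = "all") {
  stopifnot(inherits(schema, "synfair_schema"))
  attrs <- names(schema$protected_attrs)
  d <- length(attrs)
  if (identical(max_order, "all")) {
    max_order <- d
  }
  if (!is.numeric(max_order) || length(max_order) != 1 ||
      max_order != as.integer(max_order) || max_order < 1) {
    stop("`max_order` must be a positive integer or \"all\"", call. = FALSE)
  }
  if (max_order > d) {
    stop(sprintf("`max_order` (%d) exceeds the number of protected attributes (%d)",
                 as.integer(max_order), d), call. = FALSE)
  }
  out <- list()
  for (k in seq_len(max_order)) {
    subsets <- utils::combn(seq_len(d), k, simplify = FALSE)
    for (idx in subsets) {
      level_lists <- schema$protected_attrs[attrs[idx]]
      # odometer over level combinations, last attribute fastest
      grid <- expand.grid(rev(level_lists), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- grid[, rev(seq_along(level_lists)), drop = FALSE]
      names(grid) <- attrs[idx]
      for (i in seq_len(nrow(grid))) {
        assignment <- unlist(grid[i, , drop = FALSE])
        names(assignment) <- attrs[idx]
        out[[length(out) + 1L]] <- subgroup(assignment, schema)
      }
    }
  }
  out
}

#' Evaluate subgroup membership on a dataset
#'
#' `subgroup_mask()` returns the logical membership vector g(x) over the
#' dataset's rows; `membership_counts()` returns how many rows fall in and
#' out of the subgroup (the two always sum to `n`).
#'
#' @param dataset A `synfair_dataset`.
#' @param sg A `synfair_subgroup`.
#' @return `subgroup_mask()`: logical vector of length `n`.
#'   `membership_counts()`: named integer vector with elements `count_in`
#'   and `count_out`.
#' @export
subgroup_mask <- function(dataset, sg) {
  stopifnot(inherits(dataset, "synfair_dataset"),
            inherits(sg, "synfair_subgroup"))
  missing_attr <- setdiff(names(sg$assignment), names(dataset$data))
  if (length(missing_attr) > 0) {
    stop(sprintf("schema error: attribute(s) absent from dataset: %s",
                 paste(missing_attr, collapse = ", ")), call. = FALSE)
  }
  mask <- rep(TRUE, dataset$n)
  for (attr in names(sg$assignment)) {
    mask <- mask & (dataset$data[[attr]] == sg$assignment[[attr]])
  }
  mask
}

#' @rdname subgroup_mask
#' @export
membership_counts <- function(dataset, sg) {
  mask <- subgroup_mask(dataset, sg)
  c(count_in = sum(mask), count_out = sum(!mask))
}

#' Theoretical size of the full subgroup lattice
#' @param schema A [dataset_schema()].
#' @return prod(Li + 1) - 1 over the attributes' level counts Li.
#' @export
lattice_size <- function(schema) {
  stopifnot(inherits(schema, "synfair_schema"))
  prod(vapply(schema$protected_attrs, length, integer(1)) + 1) - 1
}
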