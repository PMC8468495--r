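#' Color palette for the six representativeness levels
#'
#' Fixed, documented hex colors for report exports: teal marks adequate
#' representation and red marks a subgroup missing entirely from the
#' synthetic data; blues shade over-representation and oranges
#' under-representation.
#'
#' @return Named character vector of hex colors, one per category level.
#' @export
category_palette <- function() {
  c(highly_over = "#08519c",
    over = "#6baed6",
    adequate = "#35978f",
    under = "#fdb863",
    highly_under = "#e66101",
    missing = "#d7191c")
}

#' Export rate-disparity results as a flat CSV
#'
#' One row per subgroup with the counts, proportions, log disparity,
#' category, test columns, a `color` column from [category_palette()] and
#' a `starred` column marking subgroups whose real/synthetic difference
#' was *not* statistically significant (the star semantics of the report
#' figures). An empty result set writes a header-only file with a
#' warning.
#'
#' @param results Tibble from [evaluate_rates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_rate_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  if (nrow(out) == 0) {
    warning("exporting an empty result table", call. = FALSE)
    out$color <- character(0)
    out$starred <- logical(0)
  } else {
    out$color <- unname(category_palette()[out$category])
    out$starred <- !is.na(out$significant) & !out$significant
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export time-series disparity results as a long-format CSV
#'
#' @param results Tibble from [evaluate_timeseries()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_timeseries_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  if (nrow(out) == 0) {
    warning("exporting an empty result table", call. = FALSE)
    out$color <- character(0)
  } else {
    out$color <- unname(category_palette()[out$category])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export rate-disparity results as hierarchical sunburst data
#'
#' Builds the nested tree behind a sunburst chart: ring k of the chart
#' holds the order-k subgroups along the declared attribute hierarchy, so
#' each node's children extend its assignment by the next attribute's
#' levels. Every node carries its counts, log disparity, category and
#' significance flag; nodes are only emitted for subgroups present in the
#' results (subgroups absent from the real data have no representation to
#' chart). A subgroup absent only from the synthetic data appears with
#' category `missing`.
#'
#' @param results Tibble from [evaluate_rates()]; must contain all
#'   subgroup orders up to `length(hierarchy)` restricted to the
#'   hierarchy attributes (run with `max_order = "all"` or at least that
#'   depth).
#' @param hierarchy Character vector of protected attribute names, inner
#'   ring first.
#' @param schema The [dataset_schema()].
#' @param path Optional path; when given, the tree is written as JSON.
#' @return The tree (nested lists), invisibly if `path` is given.
#' @export
export_sunburst <- function(results, hierarchy, schema, path = NULL) {
  stopifnot(inherits(schema, "synfair_schema"), is.data.frame(results))
  unknown <- setdiff(hierarchy, names(schema$protected_attrs))
  if (length(unknown) > 0) {
    stop(sprintf("configuration error: hierarchy attribute(s) not in schema: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(hierarchy) == 0) {
    stop("`hierarchy` must name at least one attribute", call. = FALSE)
  }
  row_for <- function(lab) {
    i <- match(lab, results$subgroup)
    if (is.na(i)) NULL else results[i, ]
  }
  # check the needed orders exist at all
  need <- hierarchy[1]
  probe <- sprintf("%s=%s", need, schema$protected_attrs[[need]][1])
  if (is.null(row_for(probe))) {
    stop(sprintf(
      "configuration error: results lack order-1 subgroups for attribute '%s'",
      need), call. = FALSE)
  }
  build <- function(assignment, depth) {
    attr <- hierarchy[depth]
    nodes <- list()
    for (lv in schema$protected_attrs[[attr]]) {
      asg <- c(assignment, stats::setNames(lv, attr))
      sg <- subgroup(asg, schema)
      lab <- subgroup_label(sg)
      row <- row_for(lab)
      if (is.null(row)) next
      node <- list(
        name = sprintf("%s=%s", attr, lv),
        attribute = attr, level = lv, subgroup = lab,
        count_R = row$count_R, count_S = row$count_S,
        log_disparity = row$log_disparity,
        category = row$category,
        color = unname(category_palette()[row$category]),
        significant = row$significant
      )
      if (depth < length(hierarchy)) {
        kids <- build(asg, depth + 1)
        if (length(kids) > 0) node$children <- kids
      }
      nodes[[length(nodes) + 1L]] <- node
    }
    nodes
  }
  tree <- list(hierarchy = as.list(hierarchy),
               children = build(character(0), 1))
  if (!is.null(path)) {
    jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    return(invisible(tree))
  }
  tree
}

#' Bundle a full audit run
#'
#' Runs the rate audit (and the time-series audit when the schema has
#' temporal features) and collects run metadata, result tables and the
#' sunburst tree in one list, ready for export.
#'
#' @param pair A [dataset_pair()].
#' @param max_order Lattice depth for the rate audit.
#' @param hierarchy Attribute order for the sunburst (default: schema
#'   order).
#' @param metric,statistic,mode Passed to [evaluate_timeseries()].
#' @param alpha Significance level.
#' @param timestamp Timestamp string recorded in the metadata; pass a
#'   fixed value for byte-reproducible artifacts.
#' @return List of class `synfair_report` with `meta`, `rates`,
#'   `timeseries` (or `NULL`) and `sunburst`.
#' @export
report_bundle <- function(pair, max_order = "all", hierarchy = NULL,
                          metric = "pcc", statistic = NULL,
                          mode = "per_feature", alpha = 0.05,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(inherits(pair, "synfair_pair"))
  hierarchy <- hierarchy %||% names(pair$schema$protected_attrs)
  rates <- evaluate_rates(pair, max_order = max_order, alpha = alpha)
  ts <- NULL
  if (length(pair$schema$temporal_features) > 0) {
    ts <- evaluate_timeseries(pair, metric = metric, statistic = statistic,
                              mode = mode)
  }
  sb <- export_sunburst(rates, hierarchy, pair$schema)
  structure(list(
    meta = list(timestamp = timestamp, alpha = alpha,
                max_order = max_order, hierarchy = hierarchy,
                n_real = pair$real$n, n_synthetic = pair$synthetic$n),
    rates = rates, timeseries = ts, sunburst = sb
  ), class = "synfair_report")
}
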