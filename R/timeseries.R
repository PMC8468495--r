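#' Aggregate a subgroup's temporal features into one series per feature
#'
#' Collapses the subgroup's rows column-by-column with the chosen
#' statistic: `"mean"` and `"sum"` are arithmetic over the rows;
#' `"count"` counts rows with a nonzero value at each time point (the
#' natural statistic for binary diagnosis columns).
#'
#' @param dataset A `synfair_dataset` whose schema declares temporal
#'   features.
#' @param sg A `synfair_subgroup`, or `NULL` to aggregate over all rows.
#' @param schema The [dataset_schema()] declaring the temporal features.
#' @param statistic `"mean"`, `"count"` or `"sum"`; defaults to the
#'   schema's `aggregation_statistic`.
#' @param complement If `TRUE`, aggregate the complement g(x) = 0 (all
#'   rows not in the subgroup) instead.
#' @return Named list, one numeric series of length T per temporal
#'   feature, in schema order.
#' @export
aggregate_series <- function(dataset, sg, schema,
                             statistic = NULL, complement = FALSE) {
  stopifnot(inherits(dataset, "synfair_dataset"),
            inherits(schema, "synfair_schema"))
  if (length(schema$temporal_features) == 0) {
    stop("schema declares no temporal features", call. = FALSE)
  }
  statistic <- match.arg(statistic %||% schema$aggregation_statistic,
                         c("mean", "count", "sum"))
  mask <- if (is.null(sg)) rep(TRUE, dataset$n) else subgroup_mask(dataset, sg)
  if (complement) mask <- !mask
  if (!any(mask)) {
    synfair_stop("synfair_empty_subgroup",
                 "no rows match the %s in this dataset",
                 if (complement) "subgroup complement" else "subgroup")
  }
  out <- list()
  for (feat in names(schema$temporal_features)) {
    cols <- schema$temporal_features[[feat]]
    block <- as.matrix(dataset$data[mask, cols, drop = FALSE])
    out[[feat]] <- switch(statistic,
      mean = colMeans(block),
      sum = colSums(block),
      count = colSums(block != 0)
    )
    names(out[[feat]]) <- cols
  }
  out
}

#' Pearson-correlation resemblance, mapped to [0, 1]
#'
#' Resemblance of a synthetic series to its real counterpart as the
#' Pearson correlation `r = cov(a, b) / (sigma_a * sigma_b)` affinely
#' mapped from `[-1, 1]` to `[0, 1]` via `(r + 1) / 2`, so that it can
#' enter a log ratio. The same moment convention is used in numerator and
#' denominator, so the sample/population distinction cancels. A constant
#' series has no defined correlation: this raises an
#' undefined-resemblance error naming the offending side.
#'
#' @param a Real-data series (length N >= 2, finite).
#' @param b Synthetic-data series of the same length.
#' @return Value in `[0, 1]`: 1 = perfectly correlated, 0.5 = no linear
#'   association, 0 = perfectly anti-correlated.
#' @examples
#' pcc_mapped(c(1, 2, 3), c(1, 3, 2))  # r = 0.5 -> 0.75
#' @export
pcc_mapped <- function(a, b) {
  check_series(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    synfair_stop("synfair_undefined_resemblance",
                 "zero variance in the %s series: correlation undefined",
                 if (stats::sd(a) == 0) "real" else "synthetic")
  }
  r <- stats::cor(a, b)
  (r + 1) / 2
}

#' Directional-symmetry resemblance
#'
#' Percentage of consecutive steps at which the real and synthetic series
#' move in the same direction:
#' `DS = 100/(N-1) * sum_k [ (a_{k+1}-a_k)(b_{k+1}-b_k) >= 0 ]`.
#' A zero step on either side (a tie) counts as agreement, per the `>= 0`
#' rule.
#'
#' @inheritParams pcc_mapped
#' @return Percentage in `[0, 100]`.
#' @examples
#' directional_symmetry(c(1, 2, 3, 2), c(1, 3, 2, 1))  # 66.67
#' directional_symmetry(c(1, 1), c(1, 2))              # tie -> 100
#' @export
directional_symmetry <- function(a, b) {
  check_series(a, b)
  agree <- (diff(a) * diff(b)) >= 0
  100 * mean(agree)
}

check_series <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop("`a` and `b` must be numeric series of equal length", call. = FALSE)
  }
  if (length(a) < 2) {
    stop("series must have at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("series values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Time-series log disparity
#'
#' Log ratio of the subgroup's real-vs-synthetic resemblance to the
#' complement's resemblance, `log(res_g1 / res_g0)`. Scale factors of the
#' resemblance metric (the DS x100, the PCC mapping denominator) cancel
#' in the ratio. Zero means the subgroup's temporal trends are captured
#' exactly as well as everyone else's; negative means worse.
#'
#' @param res_g1 Resemblance of the subgroup (g(x) = 1), > 0.
#' @param res_g0 Resemblance of the complement (g(x) = 0), > 0, on the
#'   same metric scale.
#' @return Numeric log disparity.
#' @examples
#' ts_log_disparity(0.90, 0.95)  # ~ -0.054: adequate
#' ts_log_disparity(0.70, 0.95)  # ~ -0.305: highly under-represented
#' @export
ts_log_disparity <- function(res_g1, res_g0) {
  stopifnot(is.numeric(res_g1), is.numeric(res_g0),
            res_g1 >= 0, res_g0 >= 0)
  if (res_g1 == 0 || res_g0 == 0) {
    synfair_stop("synfair_undefined_disparity",
                 "a resemblance value is zero: log disparity undefined")
  }
  log(res_g1 / res_g0)
}

#' Audit temporal resemblance over subgroups
#'
#' For each subgroup, aggregates the subgroup's and its complement's rows
#' into one series per temporal feature in both datasets, computes the
#' resemblance between the real and synthetic series on each side, and
#' forms the time-series log disparity `log(res_g1 / res_g0)`, categorized
#' on the same six-level scale as the rate metric.
#'
#' In `per_feature` mode (the primary output for multivariate series) the
#' result has one row per subgroup x feature, plus one `"(mean)"` summary
#' row per subgroup in which the expectation over features is realized as
#' the arithmetic mean of the per-feature resemblances on each side. In
#' `concatenated` mode the features are joined in schema order into a
#' single series of length m*T before computing resemblance, giving one
#' row per subgroup (for a single temporal feature the two modes
#' coincide, minus the summary row).
#'
#' Degenerate subgroups never abort the run: a subgroup with no synthetic
#' rows is reported with category `missing` (flag
#' `missing_in_synthetic`), one with no real rows or no complement rows
#' is flagged, and an undefined resemblance (zero-variance series, zero
#' resemblance) yields a flagged row with `NA` values.
#'
#' @param pair A [dataset_pair()] with temporal features.
#' @param subgroups List of `synfair_subgroup`s; default the univariate
#'   subgroups (`max_order = 1`).
#' @param metric `"pcc"` (mapped Pearson correlation) or `"ds"`
#'   (directional symmetry).
#' @param statistic Aggregation statistic; defaults to the schema's.
#' @param mode `"per_feature"` or `"concatenated"`.
#' @param scale A [category_scale()].
#' @return A tibble with columns `subgroup`, `feature`, `metric`,
#'   `res_g1`, `res_g0`, `ts_log_disparity`, `category`, `flag`.
#' @export
evaluate_timeseries <- function(pair, subgroups = NULL,
                                metric = c("pcc", "ds"),
                                statistic = NULL,
                                mode = c("per_feature", "concatenated"),
                                scale = category_scale()) {
  stopifnot(inherits(pair, "synfair_pair"))
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  schema <- pair$schema
  if (length(schema$temporal_features) == 0) {
    stop("pair has no temporal features", call. = FALSE)
  }
  if (is.null(subgroups)) {
    subgroups <- enumerate_subgroups(schema, max_order = 1)
  }
  if (length(subgroups) == 0) stop("`subgroups` must be non-empty", call. = FALSE)
  res_fun <- if (metric == "pcc") pcc_mapped else directional_symmetry
  feats <- names(schema$temporal_features)

  rows <- list()
  emit <- function(sg_label, feature, res_g1 = NA_real_, res_g0 = NA_real_,
                   ld = NA_real_, category = NA_character_, flag = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      subgroup = sg_label, feature = feature, metric = metric,
      res_g1 = res_g1, res_g0 = res_g0, ts_log_disparity = ld,
      category = category, flag = flag)
  }

  for (sg in subgroups) {
    lab <- subgroup_label(sg)
    in_real <- sum(subgroup_mask(pair$real, sg))
    in_syn <- sum(subgroup_mask(pair$synthetic, sg))
    feats_out <- if (mode == "per_feature") feats else "concatenated"
    if (in_real == 0) {
      for (f in feats_out) emit(lab, f, flag = "absent_in_real")
      next
    }
    if (in_syn == 0) {
      for (f in feats_out) emit(lab, f, category = "missing",
                                flag = "missing_in_synthetic")
      next
    }
    if (in_real == pair$real$n || in_syn == pair$synthetic$n) {
      for (f in feats_out) emit(lab, f, flag = "empty_complement")
      next
    }
    g1_real <- aggregate_series(pair$real, sg, schema, statistic)
    g1_syn <- aggregate_series(pair$synthetic, sg, schema, statistic)
    g0_real <- aggregate_series(pair$real, sg, schema, statistic,
                                complement = TRUE)
    g0_syn <- aggregate_series(pair$synthetic, sg, schema, statistic,
                               complement = TRUE)
    if (mode == "concatenated") {
      g1_real <- list(concatenated = unlist(g1_real, use.names = FALSE))
      g1_syn <- list(concatenated = unlist(g1_syn, use.names = FALSE))
      g0_real <- list(concatenated = unlist(g0_real, use.names = FALSE))
      g0_syn <- list(concatenated = unlist(g0_syn, use.names = FALSE))
    }
    per_r1 <- c(); per_r0 <- c()
    for (f in names(g1_real)) {
      r1 <- tryCatch(res_fun(g1_real[[f]], g1_syn[[f]]),
                     synfair_undefined_resemblance = function(e) e)
      r0 <- tryCatch(res_fun(g0_real[[f]], g0_syn[[f]]),
                     synfair_undefined_resemblance = function(e) e)
      if (inherits(r1, "condition") || inherits(r0, "condition")) {
        emit(lab, f, flag = "undefined_resemblance")
        next
      }
      per_r1 <- c(per_r1, r1); per_r0 <- c(per_r0, r0)
      ld <- tryCatch(ts_log_disparity(r1, r0),
                     synfair_undefined_disparity = function(e) e)
      if (inherits(ld, "condition")) {
        emit(lab, f, res_g1 = r1, res_g0 = r0,
             category = if (r1 == 0) "highly_under" else "highly_over",
             flag = "zero_resemblance")
      } else {
        emit(lab, f, res_g1 = r1, res_g0 = r0, ld = ld,
             category = categorize(ld, scale))
      }
    }
    if (mode == "per_feature" && length(feats) > 1 && length(per_r1) > 0) {
      m1 <- mean(per_r1); m0 <- mean(per_r0)
      if (m1 > 0 && m0 > 0) {
        ld <- ts_log_disparity(m1, m0)
        emit(lab, "(mean)", res_g1 = m1, res_g0 = m0, ld = ld,
             category = categorize(ld, scale))
      }
    }
  }
  do.call(rbind, rows)
}
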