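#' Odds of a proportion
#'
#' `odds(p) = p / (1 - p)`, with `odds(0) = 0`. A proportion of exactly 1
#' means the subgroup is the entire dataset, for which the odds (and hence
#' any odds ratio) are undefined; this raises a degenerate-subgroup error.
#'
#' @param p Proportion in `[0, 1)`.
#' @return Non-negative numeric.
#' @examples
#' odds(0.5)   # 1
#' odds(0)     # 0
#' @export
odds <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must be a proportion in [0, 1]", call. = FALSE)
  }
  if (any(p == 1)) {
    synfair_stop("synfair_degenerate_subgroup",
                 "odds undefined at p = 1: subgroup is the entire dataset")
  }
  p / (1 - p)
}

#' Log disparity of a subgroup's representation rate
#'
#' The central representation-rate metric: the natural log of the ratio of
#' the subgroup's odds of occurrence in the synthetic data to its odds in
#' the real data,
#' `log( (p_S / (1 - p_S)) / (p_R / (1 - p_R)) )`.
#' Zero means perfect parity; positive values mean the subgroup is
#' over-represented in the synthetic data, negative under-represented.
#'
#' A subgroup present in the real data but entirely absent from the
#' synthetic data (`count_S = 0`) is a qualitatively different failure
#' (mode collapse); it is reported as the missing sentinel `NA`, which
#' [categorize()] maps to the `"missing"` category. A subgroup absent from
#' the real data (`count_R = 0`) is not evaluable and raises a reference
#' error. A subgroup equal to either whole dataset raises a
#' degenerate-subgroup error.
#'
#' @param count_S,n_S Subgroup count and total rows in the synthetic data.
#' @param count_R,n_R Subgroup count and total rows in the real data.
#' @param continuity_correction If `TRUE`, apply the Haldane-Anscombe
#'   adjustment (+0.5 to both counts, +1 to both totals) before forming the
#'   odds; useful for sparse tables. Off by default.
#' @return Numeric log disparity, or `NA` (missing sentinel) when
#'   `count_S = 0` without continuity correction.
#' @examples
#' log_disparity(12806, 30000, 13135, 30526)   # ~ -0.0140
#' log_disparity(100, 1000, 50, 1000)          # ~  0.7472
#' @export
log_disparity <- function(count_S, n_S, count_R, n_R,
                          continuity_correction = FALSE) {
  check_counts(count_S, n_S, "synthetic")
  check_counts(count_R, n_R, "real")
  if (count_R == 0) {
    synfair_stop("synfair_reference_error",
                 "subgroup absent from the real data (count_R = 0): not evaluable")
  }
  if (count_S == n_S || count_R == n_R) {
    synfair_stop("synfair_degenerate_subgroup",
                 "subgroup equals an entire dataset: odds ratio undefined")
  }
  if (continuity_correction) {
    count_S <- count_S + 0.5; n_S <- n_S + 1
    count_R <- count_R + 0.5; n_R <- n_R + 1
  }
  if (count_S == 0) {
    return(NA_real_)
  }
  log(odds(count_S / n_S) / odds(count_R / n_R))
}

check_counts <- function(count, n, which) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop(sprintf("n_%s must be >= 1", substr(which, 1, 1)), call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1 || is.na(count) ||
      count < 0 || count > n) {
    stop(sprintf("count in %s data must lie in [0, n]", which), call. = FALSE)
  }
  invisible(TRUE)
}

#' The six-level representativeness scale
#'
#' Log disparity values are binned into six levels using two symmetric
#' thresholds: `t1 = |log(0.9)|` (the "90 percent rule" separating
#' adequate representation from over-/under-representation) and
#' `t2 = |log(0.8)|` (the "80 percent rule" marking highly inequitable
#' representation). The sixth level, `missing`, is reserved for subgroups
#' present in the real data but entirely absent from the synthetic data.
#'
#' @param t1,t2 Positive thresholds with `t1 < t2`. Defaults
#'   `|log(0.9)| ~ 0.1054` and `|log(0.8)| ~ 0.2231`.
#' @return An object of class `synfair_scale` with the thresholds and the
#'   ordered level labels.
#' @export
category_scale <- function(t1 = abs(log(0.9)), t2 = abs(log(0.8))) {
  stopifnot(is.numeric(t1), is.numeric(t2), t1 > 0, t2 > t1)
  structure(list(t1 = t1, t2 = t2, levels = category_levels()),
            class = "synfair_scale")
}

#' @rdname category_scale
#' @export
category_levels <- function() {
  c("highly_over", "over", "adequate", "under", "highly_under", "missing")
}

#' Categorize a log disparity value on the six-level scale
#'
#' `|LD| < t1` is `adequate`; `t1 <= |LD| < t2` is `over` or `under`
#' according to sign; `|LD| >= t2` is `highly_over` or `highly_under`.
#' Values exactly on a threshold go to the more severe side (an audit
#' should err toward flagging). The missing sentinel `NA` maps to
#' `missing`.
#'
#' @param ld Numeric vector of log disparities (NA = missing sentinel).
#' @param scale A [category_scale()].
#' @return Character vector of category labels.
#' @examples
#' categorize(c(0, 0.15, -0.3, NA))
#' @export
categorize <- function(ld, scale = category_scale()) {
  stopifnot(inherits(scale, "synfair_scale"))
  out <- character(length(ld))
  for (i in seq_along(ld)) {
    x <- ld[i]
    out[i] <-
      if (is.na(x)) "missing"
      else if (abs(x) < scale$t1) "adequate"
      else if (abs(x) < scale$t2) { if (x > 0) "over" else "under" }
      else { if (x > 0) "highly_over" else "highly_under" }
  }
  out
}

#' Audit representation rates over the subgroup lattice
#'
#' For every enumerated subgroup this computes the 2x2 representation
#' table (in/out of subgroup x real/synthetic), the observed proportions
#' and odds, the disparity ratio and log disparity, the six-level
#' category, and a two-proportion test of the null that the real and
#' synthetic rates are equal (exact test for sparse tables), with
#' Benjamini-Hochberg adjustment applied once across the whole family.
#'
#' Non-evaluable subgroups never abort the run; they are flagged:
#' `absent_in_real` (no real rows; no metric or test possible) and
#' `degenerate` (subgroup is an entire dataset). Subgroups present in real
#' but absent from synthetic data get category `missing` with flag
#' `missing_in_synthetic`; their test is still performed.
#'
#' @param pair A [dataset_pair()].
#' @param max_order Lattice depth passed to [enumerate_subgroups()].
#' @param alpha Significance level for the BH-adjusted decision.
#' @param continuity_correction Passed to [log_disparity()].
#' @param scale A [category_scale()].
#' @param min_expected Expected-cell-count threshold below which the
#'   Fisher exact test replaces the z-test (textbook rule of 5).
#' @return A tibble with one row per subgroup: `subgroup`, `order`,
#'   counts/totals, `p_R`, `p_S`, `odds_R`, `odds_S`, `disparity_ratio`,
#'   `log_disparity`, `category`, `method`, `z`, `p_value`, `p_adjusted`,
#'   `significant`, `flag`.
#' @export
evaluate_rates <- function(pair, max_order = "all", alpha = 0.05,
                           continuity_correction = FALSE,
                           scale = category_scale(), min_expected = 5) {
  stopifnot(inherits(pair, "synfair_pair"))
  sgs <- enumerate_subgroups(pair$schema, max_order)
  n_R <- pair$real$n
  n_S <- pair$synthetic$n
  m <- length(sgs)
  res <- tibble::tibble(
    subgroup = vapply(sgs, subgroup_label, character(1)),
    order = vapply(sgs, function(s) s$order, integer(1)),
    count_R = integer(m), count_S = integer(m),
    n_R = rep(n_R, m), n_S = rep(n_S, m),
    p_R = numeric(m), p_S = numeric(m),
    odds_R = NA_real_, odds_S = NA_real_,
    disparity_ratio = NA_real_, log_disparity = NA_real_,
    category = NA_character_, method = NA_character_,
    z = NA_real_, p_value = NA_real_, p_adjusted = NA_real_,
    significant = NA, flag = ""
  )
  for (i in seq_len(m)) {
    sg <- sgs[[i]]
    cR <- sum(subgroup_mask(pair$real, sg))
    cS <- sum(subgroup_mask(pair$synthetic, sg))
    res$count_R[i] <- cR
    res$count_S[i] <- cS
    res$p_R[i] <- cR / n_R
    res$p_S[i] <- cS / n_S
    if (cR == 0) {
      res$flag[i] <- "absent_in_real"
      next
    }
    if (cR == n_R || cS == n_S) {
      res$flag[i] <- "degenerate"
    } else {
      res$odds_R[i] <- odds(cR / n_R)
      res$odds_S[i] <- odds(cS / n_S)
      ld <- log_disparity(cS, n_S, cR, n_R,
                          continuity_correction = continuity_correction)
      res$log_disparity[i] <- ld
      res$disparity_ratio[i] <- if (is.na(ld)) 0 else exp(ld)
      res$category[i] <- categorize(ld, scale)
      if (cS == 0) res$flag[i] <- "missing_in_synthetic"
    }
    tst <- proportion_test(cS, n_S, cR, n_R, min_expected = min_expected)
    res$method[i] <- tst$method
    res$z[i] <- tst$statistic
    res$p_value[i] <- tst$p_value
  }
  tested <- !is.na(res$p_value)
  if (any(tested)) {
    res$p_adjusted[tested] <- benjamini_hochberg(res$p_value[tested])
    res$significant[tested] <- res$p_adjusted[tested] < alpha
  }
  attr(res, "alpha") <- alpha
  res
}
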