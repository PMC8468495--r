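#' Two-proportion z-test for a subgroup's representation rate
#'
#' Tests the null that the subgroup occurs at the same rate in the real
#' and synthetic data. The statistic pools the proportion across both
#' samples:
#' `z = (p_S - p_R) / sqrt( p(1-p)/n_S + p(1-p)/n_R )`,
#' with pooled `p = (count_S + count_R) / (n_S + n_R)` and a two-sided
#' p-value from the standard normal. With a degenerate pooled proportion
#' (0 or 1) the two rates can only be identical, which returns `z = 0`,
#' `p = 1`; anything else raises a degenerate-test error.
#'
#' @param count_S,n_S Subgroup count and total in the synthetic data.
#' @param count_R,n_R Subgroup count and total in the real data.
#' @return List with `statistic`, `p_value`, `method = "z_test"`.
#' @examples
#' two_proportion_z(400, 1000, 500, 1000)$statistic  # ~ -4.49
#' @export
two_proportion_z <- function(count_S, n_S, count_R, n_R) {
  check_counts(count_S, n_S, "synthetic")
  check_counts(count_R, n_R, "real")
  p_S <- count_S / n_S
  p_R <- count_R / n_R
  p <- (count_S + count_R) / (n_S + n_R)
  if (p == 0 || p == 1) {
    if (p_S == p_R) {
      return(list(statistic = 0, p_value = 1, method = "z_test"))
    }
    synfair_stop("synfair_degenerate_test",
                 "pooled proportion is degenerate but rates differ")
  }
  se <- sqrt(p * (1 - p) / n_S + p * (1 - p) / n_R)
  z <- (p_S - p_R) / se
  list(statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       method = "z_test")
}

#' Fisher exact test on the representation 2x2 table
#'
#' Small-sample alternative to [two_proportion_z()]: the two-sided exact
#' p-value sums the hypergeometric probabilities of all 2x2 tables with
#' the observed margins that are at most as probable as the observed one.
#' Degenerate tables (an empty margin) give p = 1.
#'
#' @inheritParams two_proportion_z
#' @return List with `statistic` (`NA`; no normal statistic exists),
#'   `p_value`, `method = "fisher_exact"`.
#' @export
fisher_exact <- function(count_S, n_S, count_R, n_R) {
  check_counts(count_S, n_S, "synthetic")
  check_counts(count_R, n_R, "real")
  tab <- matrix(c(count_S, n_S - count_S, count_R, n_R - count_R),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  list(statistic = NA_real_, p_value = min(p, 1), method = "fisher_exact")
}

#' Pick the z-test or the exact test for one table
#'
#' Applies the textbook rule: if any of the four expected cell counts
#' under the pooled proportion falls below `min_expected` (default 5), the
#' Fisher exact test is used; otherwise the z-test.
#'
#' @inheritParams two_proportion_z
#' @param min_expected Expected-count threshold for the exact fallback.
#' @return As [two_proportion_z()] / [fisher_exact()].
#' @export
proportion_test <- function(count_S, n_S, count_R, n_R, min_expected = 5) {
  p <- (count_S + count_R) / (n_S + n_R)
  expected <- c(n_S * p, n_S * (1 - p), n_R * p, n_R * (1 - p))
  if (p == 0 || p == 1 || any(expected < min_expected)) {
    fisher_exact(count_S, n_S, count_R, n_R)
  } else {
    two_proportion_z(count_S, n_S, count_R, n_R)
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment over the family of subgroup tests: sort
#' ascending, scale p(i) by m/i, enforce monotonicity from the largest
#' down, cap at 1, return in the original order. Adjusted values are
#' always >= the raw values and preserve their rank order.
#'
#' @param p_values Non-empty numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) {
    stop("`p_values` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
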