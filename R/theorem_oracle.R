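#' Disparate impact vs odds ratio on a finite population
#'
#' The representation-rate metric rests on an equivalence: under the two
#' sampling assumptions (real and synthetic sampling indicators are
#' independent of each other, and the real-sampling indicator is
#' independent of subgroup membership), the classic disparate impact
#' ratio
#' `P(y' = 1 | g = 1) / P(y' = 1 | g = 0)`
#' equals the ratio of the subgroup's odds among synthetic rows to its
#' odds among real rows. This function verifies the equivalence on an
#' explicit finite population: the left side is computed by brute-force
#' frequency counting over the rows, the right side from the subgroup
#' frequencies among `y' = 1` (synthetic-sampled) and `y = 1`
#' (real-sampled) rows. The two agree to numerical tolerance on any
#' population that satisfies the assumptions by construction (see
#' [independent_population()]).
#'
#' @param population Data frame with binary columns `g` (subgroup
#'   membership), `y` (sampled into the real data) and `yprime` (sampled
#'   into the synthetic data).
#' @return List with `eq_di_value` (brute-force disparate impact) and
#'   `odds_ratio_value`.
#' @export
disparate_impact_oracle <- function(population) {
  stopifnot(is.data.frame(population),
            all(c("g", "y", "yprime") %in% names(population)))
  g <- population$g
  y <- population$y
  yp <- population$yprime
  stopifnot(all(g %in% 0:1), all(y %in% 0:1), all(yp %in% 0:1))
  if (sum(g == 1) == 0 || sum(g == 0) == 0 ||
      sum(yp[g == 1]) == 0 || sum(yp[g == 0]) == 0 ||
      sum(y) == 0 || sum(yp) == 0) {
    synfair_stop("synfair_degenerate_population",
                 "a conditional frequency in the disparate impact ratio is zero")
  }
  di <- mean(yp[g == 1]) / mean(yp[g == 0])
  p_g_syn <- mean(g[yp == 1])
  p_g_real <- mean(g[y == 1])
  if (p_g_syn %in% c(0, 1) || p_g_real %in% c(0, 1)) {
    synfair_stop("synfair_degenerate_population",
                 "subgroup frequency among sampled rows is degenerate")
  }
  or <- odds(p_g_syn) / odds(p_g_real)
  list(eq_di_value = di, odds_ratio_value = or)
}

#' Construct a finite population satisfying the sampling assumptions
#'
#' Builds a product-form population over `(g, y, yprime)` in which the
#' real-sampling indicator `y` is exactly independent of `(g, yprime)`
#' jointly — hence of each marginally — by replicating every `(g, yprime)`
#' configuration `u` times with `y = 1` and `v` times with `y = 0`. Cell
#' counts over the four `(g, yprime)` configurations are given directly,
#' so independence holds by construction, not just in expectation.
#'
#' @param counts_g_yprime Numeric vector of length 4: row counts for the
#'   `(g, yprime)` configurations (1,1), (1,0), (0,1), (0,0). All must be
#'   >= 1 so no conditional frequency is zero.
#' @param u,v Positive integer replication counts for `y = 1` / `y = 0`.
#' @return Data frame with columns `g`, `y`, `yprime` and
#'   `sum(counts) * (u + v)` rows.
#' @examples
#' pop <- independent_population(c(3, 1, 7, 9), u = 1, v = 4)
#' oracle <- disparate_impact_oracle(pop)
#' all.equal(oracle$eq_di_value, oracle$odds_ratio_value)
#' @export
independent_population <- function(counts_g_yprime, u = 1, v = 1) {
  stopifnot(length(counts_g_yprime) == 4, all(counts_g_yprime >= 1),
            u >= 1, v >= 1)
  cfg <- data.frame(g = c(1, 1, 0, 0), yprime = c(1, 0, 1, 0))
  base <- cfg[rep(seq_len(4), times = counts_g_yprime), , drop = FALSE]
  pop <- rbind(
    cbind(base, y = 1)[rep(seq_len(nrow(base)), each = u), , drop = FALSE],
    cbind(base, y = 0)[rep(seq_len(nrow(base)), each = v), , drop = FALSE]
  )
  rownames(pop) <- NULL
  pop[, c("g", "y", "yprime")]
}
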