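#' Schema presets for the three case-study dataset shapes
#'
#' Ready-made schemas mirroring the shapes of three published
#' real/synthetic health-data pairs:
#' \describe{
#'   \item{`schema_mimic_like()`}{an ICU mortality extract — race (5
#'     levels), gender (2), binned age (4) and 30-day mortality (2);
#'     categorical only.}
#'   \item{`schema_atus_like()`}{a time-use sleep survey — gender (2) and
#'     age (7 bins), with one temporal feature of 30 contiguous hourly
#'     columns of minutes slept, aggregated by mean.}
#'   \item{`schema_asd_like()`}{a pediatric claims extract — gender and
#'     race, with seven binary comorbid-condition diagnosis series of 10
#'     six-month periods each, aggregated by mean (per-period
#'     prevalence).}
#' }
#'
#' @return A [dataset_schema()].
#' @name schema_presets
NULL

#' @rdname schema_presets
#' @export
schema_mimic_like <- function() {
  dataset_schema(
    protected_attrs = list(
      race = c("White", "Black", "Asian", "Unknown", "Other"),
      gender = c("Male", "Female"),
      age = c("<=45", "46-65", "66-80", "81+"),
      mortality = c("alive", "dead")
    )
  )
}

#' @rdname schema_presets
#' @export
schema_atus_like <- function() {
  dataset_schema(
    protected_attrs = list(
      gender = c("Male", "Female"),
      age = c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+")
    ),
    temporal_features = list(sleep = sprintf("sleep_h%02d", 1:30)),
    aggregation_statistic = "mean"
  )
}

#' @rdname schema_presets
#' @export
schema_asd_like <- function() {
  cmcs <- c("Auditory", "DD", "Gastro", "Immune", "Psychiatric",
            "Seizure", "Sleep")
  feats <- stats::setNames(
    lapply(cmcs, function(f) sprintf("%s_t%02d", tolower(f), 1:10)), cmcs)
  dataset_schema(
    protected_attrs = list(
      gender = c("Male", "Female"),
      race = c("White", "Black", "Asian", "Other")
    ),
    temporal_features = feats,
    aggregation_statistic = "mean"
  )
}

# default marginal probabilities for each preset; chosen once as plausible
# health-survey compositions (the sleep survey's gender margin reproduces
# its published totals, 13135 M / 17391 F of 30526)
preset_margins <- function(preset) {
  switch(preset,
    mimic = list(race = c(0.70, 0.12, 0.04, 0.08, 0.06),
                 gender = c(0.55, 0.45),
                 age = c(0.20, 0.30, 0.30, 0.20),
                 mortality = c(0.85, 0.15)),
    atus = list(gender = c(13135, 17391) / 30526,
                age = c(0.15, 0.17, 0.16, 0.16, 0.15, 0.12, 0.09)),
    asd = list(gender = c(0.80, 0.20),
               race = c(0.60, 0.17, 0.08, 0.15)),
    stop(sprintf("unknown preset '%s'", preset), call. = FALSE)
  )
}

# hourly minutes-asleep template over 30 contiguous hours, in [0, 60]:
# a circadian cosine whose amplitude shrinks and phase drifts with age,
# so every cell has a distinct, non-constant, non-monotone curve
atus_curve <- function(cell, feature, T_len) {
  age_idx <- match(cell[["age"]],
                   c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74",
                     "75+"))
  gender_shift <- if (cell[["gender"]] == "Male") 0 else 0.6
  k <- seq_len(T_len)
  amp <- 26 - 1.4 * (age_idx - 1)
  base <- 30 + amp * cos(2 * pi * (k - 4 - 0.4 * age_idx - gender_shift) / 24)
  pmin(pmax(base, 0), 60)
}

# six-month prevalence curves per comorbid condition: gentle rise with a
# condition-specific wiggle; distinct across cells via small level shifts
asd_curve <- function(cell, feature, T_len) {
  f_idx <- match(feature, c("Auditory", "DD", "Gastro", "Immune",
                            "Psychiatric", "Seizure", "Sleep"))
  race_idx <- match(cell[["race"]], c("White", "Black", "Asian", "Other"))
  gender_shift <- if (cell[["gender"]] == "Male") 0.02 else -0.02
  k <- seq_len(T_len)
  base <- 0.10 + 0.02 * f_idx + 0.01 * race_idx + gender_shift +
    0.015 * k + 0.05 * sin(k / 1.5 + f_idx)
  pmin(pmax(base, 0.02), 0.90)
}

#' Monte-Carlo calibration of the subgroup tests under the null
#'
#' Draws both arms of every replicate from the same multinomial over the
#' protected-attribute cells (the null: the synthetic generator is
#' perfectly fair), applies the two-proportion z-test to each univariate
#' subgroup and Benjamini-Hochberg across the family, and reports the raw
#' per-test rejection rate at `alpha` plus the replicate-mean
#' false-discovery proportion (under the global null every BH rejection
#' is a false discovery, so the FDP of a replicate is 1 exactly when it
#' rejects anything). A calibrated test has raw rate close to `alpha` and
#' FDP at or below it.
#'
#' @param schema A [dataset_schema()].
#' @param joint Cell distribution, e.g. from [joint_from_margins()].
#' @param n_rep Number of replicates.
#' @param n_arm Rows drawn per arm per replicate.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return List with `rejection_rate`, `fdp`, `n_tests`.
#' @export
calibrate_null <- function(schema, joint, n_rep = 10000, n_arm = 2000,
                           alpha = 0.05, seed = 1) {
  stopifnot(inherits(schema, "synfair_schema"))
  sgs <- enumerate_subgroups(schema, max_order = 1)
  member <- vapply(sgs, function(sg) cell_mask(joint, sg),
                   logical(nrow(joint)))
  set.seed(seed)
  XR <- stats::rmultinom(n_rep, n_arm, joint$prob)
  XS <- stats::rmultinom(n_rep, n_arm, joint$prob)
  reject <- 0L; total <- 0L; any_bh <- 0L
  for (r in seq_len(n_rep)) {
    cR <- as.integer(crossprod(member, XR[, r]))
    cS <- as.integer(crossprod(member, XS[, r]))
    p <- vapply(seq_along(sgs), function(j) {
      two_proportion_z(cS[j], n_arm, cR[j], n_arm)$p_value
    }, numeric(1))
    reject <- reject + sum(p < alpha)
    total <- total + length(p)
    if (any(benjamini_hochberg(p) < alpha)) any_bh <- any_bh + 1L
  }
  list(rejection_rate = reject / total, fdp = any_bh / n_rep,
       n_tests = total)
}

#' One-call simulation of a preset real/synthetic pair
#'
#' Convenience wrapper tying a schema preset, its default margins and a
#' [bias_spec()] together. `omega` injects representation-rate bias (a
#' named list of odds multipliers per subgroup label); `flip_prob` /
#' `flip_subgroup` inject temporal direction distortion; `noise_sd` is
#' the additive series noise (ignored for the binary preset).
#'
#' @param preset `"mimic"`, `"atus"` or `"asd"`.
#' @param n_R,n_S Sample sizes (defaults 5000/5000).
#' @param seed Integer seed.
#' @param omega Named list of odds multipliers, e.g.
#'   `list("gender=Female" = 0.8)`.
#' @param noise_sd,flip_prob,flip_subgroup Temporal distortion settings,
#'   see [generate_temporal_pair()].
#' @return A [dataset_pair()].
#' @examples
#' pair <- simulate_pair("mimic", n_R = 500, n_S = 500, seed = 1,
#'                       omega = list("race=Black" = 0.5))
#' evaluate_rates(pair, max_order = 1)
#' @export
simulate_pair <- function(preset = c("mimic", "atus", "asd"),
                          n_R = 5000, n_S = 5000, seed = 1,
                          omega = list(), noise_sd = NULL,
                          flip_prob = 0, flip_subgroup = NULL) {
  preset <- match.arg(preset)
  schema <- switch(preset,
                   mimic = schema_mimic_like(),
                   atus = schema_atus_like(),
                   asd = schema_asd_like())
  joint <- joint_from_margins(schema, preset_margins(preset))
  temporal <- switch(preset,
    mimic = NULL,
    atus = list(curve_fn = atus_curve, noise_sd = noise_sd %||% 6,
                flip_prob = flip_prob, flip_subgroup = flip_subgroup),
    asd = list(curve_fn = asd_curve, binary = TRUE,
               flip_prob = flip_prob, flip_subgroup = flip_subgroup)
  )
  spec <- bias_spec(joint, n_R = n_R, n_S = n_S, seed = seed,
                    odds_multipliers = omega, temporal = temporal)
  if (is.null(temporal)) {
    generate_categorical_pair(schema, spec)
  } else {
    generate_temporal_pair(schema, spec)
  }
}
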