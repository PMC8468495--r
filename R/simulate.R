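#' Specify a bias-injection simulation
#'
#' Defines a joint distribution over the protected-attribute cells and the
#' distortions to inject into the synthetic arm. Rate bias is injected on
#' the *sampling odds* of target subgroups: a multiplier `omega` on a
#' subgroup multiplies its odds of occurrence in the synthetic table, so
#' `omega` is exactly the disparity ratio the rate metric estimates (and
#' `log(omega)` the log disparity). `omega = 0` deletes the subgroup from
#' the synthetic data, emulating mode collapse. Temporal bias is injected
#' by flipping the direction of the base curve's increments with a given
#' probability for rows of a target subgroup, plus additive noise.
#'
#' @param base_joint Data frame with one column per protected attribute
#'   plus a `prob` column summing to 1 over the cells.
#' @param n_R,n_S Number of rows to draw for the real / synthetic table.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param odds_multipliers Named list mapping subgroup labels (see
#'   [subgroup_label()]) to positive multipliers `omega` (0 allowed, for
#'   deletion), applied to the synthetic sampling odds in order.
#' @param temporal Optional list configuring series generation:
#'   `curve_fn(cell, feature, T)` returning the cell's base curve;
#'   `noise_sd` (additive Gaussian noise sd, default 0); `flip_prob`
#'   (per-step direction-flip probability in the synthetic arm, default
#'   0); `flip_subgroup` (label of the subgroup whose synthetic rows are
#'   flipped; `NULL` = all rows); `binary` (if `TRUE`, cell curves are
#'   prevalence curves and row values are Bernoulli draws).
#' @return An object of class `synfair_bias_spec`.
#' @export
bias_spec <- function(base_joint, n_R, n_S, seed,
                      odds_multipliers = list(), temporal = NULL) {
  stopifnot(is.data.frame(base_joint), "prob" %in% names(base_joint))
  p <- base_joint$prob
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`base_joint$prob` must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(n_R >= 1, n_S >= 1, is.numeric(seed))
  if (length(odds_multipliers) > 0) {
    if (is.null(names(odds_multipliers)) || any(names(odds_multipliers) == "")) {
      stop("`odds_multipliers` must be named by subgroup label", call. = FALSE)
    }
    if (any(unlist(odds_multipliers) < 0)) {
      stop("odds multipliers must be >= 0", call. = FALSE)
    }
  }
  if (!is.null(temporal)) {
    temporal$noise_sd <- temporal$noise_sd %||% 0
    temporal$flip_prob <- temporal$flip_prob %||% 0
    temporal$binary <- isTRUE(temporal$binary)
    stopifnot(is.function(temporal$curve_fn), temporal$noise_sd >= 0)
    if (temporal$flip_prob < 0 || temporal$flip_prob > 1) {
      stop("`flip_prob` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(base_joint = base_joint, n_R = n_R, n_S = n_S,
                 seed = as.integer(seed),
                 odds_multipliers = odds_multipliers, temporal = temporal),
            class = "synfair_bias_spec")
}

#' Product-form joint over the protected-attribute cells
#'
#' Builds the full cross of declared levels with cell probabilities equal
#' to the product of per-attribute marginal probabilities (independent
#' attributes). With `margins = NULL` every level of an attribute is
#' equally likely.
#'
#' @param schema A [dataset_schema()].
#' @param margins Optional named list mapping attribute name to a
#'   probability vector over its levels (each summing to 1).
#' @return Data frame of cells with a `prob` column.
#' @export
joint_from_margins <- function(schema, margins = NULL) {
  stopifnot(inherits(schema, "synfair_schema"))
  attrs <- names(schema$protected_attrs)
  grid <- expand.grid(rev(schema$protected_attrs), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(attrs)), drop = FALSE]
  names(grid) <- attrs
  prob <- rep(1, nrow(grid))
  for (attr in attrs) {
    lv <- schema$protected_attrs[[attr]]
    m <- if (!is.null(margins) && !is.null(margins[[attr]])) {
      margins[[attr]]
    } else {
      rep(1 / length(lv), length(lv))
    }
    if (length(m) != length(lv) || abs(sum(m) - 1) > 1e-8) {
      stop(sprintf("margin for '%s' must be a probability vector over its levels",
                   attr), call. = FALSE)
    }
    prob <- prob * m[match(grid[[attr]], lv)]
  }
  grid$prob <- prob
  grid
}

cell_mask <- function(joint, sg) {
  mask <- rep(TRUE, nrow(joint))
  for (attr in names(sg$assignment)) {
    mask <- mask & (joint[[attr]] == sg$assignment[[attr]])
  }
  mask
}

# multiply a subgroup's sampling odds by omega and renormalize;
# exact: P'(g)/(1-P'(g)) = omega * P(g)/(1-P(g))
reweight_odds <- function(joint, schema, odds_multipliers) {
  prob <- joint$prob
  for (lab in names(odds_multipliers)) {
    sg <- parse_subgroup(lab, schema)
    omega <- odds_multipliers[[lab]]
    mask <- cell_mask(joint, sg)
    q <- sum(prob[mask])
    if (q <= 0 || q >= 1) {
      stop(sprintf("cannot reweight subgroup '%s': base probability %g", lab, q),
           call. = FALSE)
    }
    q_new <- omega * q / (1 - q + omega * q)
    prob[mask] <- prob[mask] * if (q > 0) q_new / q else 0
    prob[!mask] <- prob[!mask] * (1 - q_new) / (1 - q)
  }
  if (sum(prob) <= 0) stop("reweighting produced a non-normalizable table",
                           call. = FALSE)
  prob / sum(prob)
}

#' Generate a paired categorical dataset with known injected rate bias
#'
#' The real table is an i.i.d. sample of `n_R` cells from `base_joint`;
#' the synthetic table samples `n_S` cells from the joint re-weighted so
#' each target subgroup's odds are multiplied by its `omega`. Given the
#' seed, output is fully deterministic.
#'
#' @param schema A [dataset_schema()] (protected attributes only are
#'   used).
#' @param spec A [bias_spec()].
#' @return A [dataset_pair()].
#' @export
generate_categorical_pair <- function(schema, spec) {
  stopifnot(inherits(schema, "synfair_schema"),
            inherits(spec, "synfair_bias_spec"))
  set.seed(spec$seed)
  joint <- spec$base_joint
  attrs <- names(schema$protected_attrs)
  prob_syn <- reweight_odds(joint, schema, spec$odds_multipliers)
  idx_R <- sample.int(nrow(joint), spec$n_R, replace = TRUE, prob = joint$prob)
  idx_S <- sample.int(nrow(joint), spec$n_S, replace = TRUE, prob = prob_syn)
  real <- as_tabular_dataset(joint[idx_R, attrs, drop = FALSE], schema, "real")
  synthetic <- as_tabular_dataset(joint[idx_S, attrs, drop = FALSE], schema,
                                  "synthetic")
  dataset_pair(real, synthetic, schema)
}

#' Generate a paired temporal dataset with known injected trend bias
#'
#' Each real row's series is its cell's base curve plus independent
#' Gaussian noise (or Bernoulli draws around a prevalence curve when
#' `binary`). Each synthetic row's series starts from the same base curve
#' but, for rows in the flip-target subgroup, each step's increment has
#' its direction flipped independently with probability `flip_prob`
#' before noise is added — degrading directional symmetry toward 50% and
#' correlation toward 0.5 for that subgroup only. Categorical membership
#' is drawn exactly as in [generate_categorical_pair()].
#'
#' @inheritParams generate_categorical_pair
#' @return A [dataset_pair()] including the temporal columns.
#' @export
generate_temporal_pair <- function(schema, spec) {
  stopifnot(inherits(schema, "synfair_schema"),
            inherits(spec, "synfair_bias_spec"))
  tm <- spec$temporal
  if (is.null(tm)) stop("spec has no temporal model", call. = FALSE)
  if (length(schema$temporal_features) == 0) {
    stop("schema has no temporal features", call. = FALSE)
  }
  set.seed(spec$seed)
  joint <- spec$base_joint
  attrs <- names(schema$protected_attrs)
  prob_syn <- reweight_odds(joint, schema, spec$odds_multipliers)
  idx_R <- sample.int(nrow(joint), spec$n_R, replace = TRUE, prob = joint$prob)
  idx_S <- sample.int(nrow(joint), spec$n_S, replace = TRUE, prob = prob_syn)

  flip_sg <- if (!is.null(tm$flip_subgroup)) {
    parse_subgroup(tm$flip_subgroup, schema)
  } else NULL

  build <- function(idx, synthetic) {
    df <- joint[idx, attrs, drop = FALSE]
    rownames(df) <- NULL
    flip_rows <- if (synthetic && tm$flip_prob > 0) {
      if (is.null(flip_sg)) rep(TRUE, nrow(df)) else {
        mask <- rep(TRUE, nrow(df))
        for (attr in names(flip_sg$assignment)) {
          mask <- mask & (df[[attr]] == flip_sg$assignment[[attr]])
        }
        mask
      }
    } else rep(FALSE, nrow(df))
    for (feat in names(schema$temporal_features)) {
      cols <- schema$temporal_features[[feat]]
      T_len <- length(cols)
      vals <- matrix(NA_real_, nrow(df), T_len)
      for (cell_id in sort(unique(idx))) {
        rows <- which(idx == cell_id)
        cell <- unlist(joint[cell_id, attrs, drop = FALSE])
        curve <- tm$curve_fn(cell, feat, T_len)
        stopifnot(length(curve) == T_len)
        nc <- length(rows)
        base <- matrix(curve, nc, T_len, byrow = TRUE)
        fr <- flip_rows[rows]
        if (any(fr) && T_len > 1) {
          d <- diff(curve)
          nf <- sum(fr)
          signs <- matrix(ifelse(stats::runif(nf * (T_len - 1)) < tm$flip_prob,
                                 -1, 1), nf, T_len - 1)
          steps <- sweep(signs, 2, d, `*`)
          cs <- if (T_len > 2) t(apply(steps, 1, cumsum)) else steps
          base[fr, ] <- cbind(rep(curve[1], nf), curve[1] + cs)
        }
        if (tm$binary) {
          pmat <- pmin(pmax(base, 0.01), 0.99)
          vals[rows, ] <- stats::rbinom(nc * T_len, 1, as.vector(pmat))
        } else {
          vals[rows, ] <- base +
            matrix(stats::rnorm(nc * T_len, 0, tm$noise_sd), nc, T_len)
        }
      }
      df[cols] <- as.data.frame(vals)
    }
    df
  }

  real <- as_tabular_dataset(build(idx_R, synthetic = FALSE), schema, "real")
  synthetic <- as_tabular_dataset(build(idx_S, synthetic = TRUE), schema,
                                  "synthetic")
  dataset_pair(real, synthetic, schema)
}
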