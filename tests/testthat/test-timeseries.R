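test_that("aggregation collapses subgroup rows per time point", {
  sch <- tiny_temporal_schema(3)
  df <- data.frame(gender = c("Male", "Male", "Female"),
                   hr_1 = c(1, 3, 9), hr_2 = c(2, 2, 9), hr_3 = c(3, 1, 9))
  ds <- as_tabular_dataset(df, sch, "real")
  sg <- subgroup(c(gender = "Male"), sch)

  # mean of rows [1,2,3] and [3,2,1] -> [2,2,2]
  expect_equal(unname(aggregate_series(ds, sg, sch, "mean")$hr), c(2, 2, 2))
  expect_equal(unname(aggregate_series(ds, sg, sch, "sum")$hr), c(4, 4, 4))

  # two identical rows, mean -> the row's own values
  df2 <- df[c(3, 3), ]
  ds2 <- as_tabular_dataset(df2, sch, "real")
  expect_equal(unname(aggregate_series(
    ds2, subgroup(c(gender = "Female"), sch), sch, "mean")$hr), c(9, 9, 9))

  # count statistic counts nonzero cells (binary diagnosis semantics)
  df3 <- data.frame(gender = c("Male", "Male"),
                    hr_1 = c(1, 0), hr_2 = c(1, 1), hr_3 = c(0, 0))
  ds3 <- as_tabular_dataset(df3, sch, "real")
  expect_equal(unname(aggregate_series(ds3, sg, sch, "count")$hr), c(1, 2, 0))

  # complement aggregation and the empty-subgroup error
  expect_equal(unname(aggregate_series(ds, sg, sch, "mean",
                                       complement = TRUE)$hr), c(9, 9, 9))
  expect_error(aggregate_series(ds2, sg, sch, "mean"),
               class = "synfair_empty_subgroup")
})

test_that("mapped correlation reproduces hand-computed values", {
  expect_equal(pcc_mapped(c(1, 2, 3), c(1, 2, 3)), 1)       # b = a
  expect_equal(pcc_mapped(c(1, 2, 3), c(3, 2, 1)), 0)       # anti-correlated
  expect_equal(pcc_mapped(c(1, 2, 3), c(1, 3, 2)), 0.75)    # r = 0.5
  expect_equal(pcc_mapped(c(1, 2, 3), c(1, 3, 2)),
               pcc_oracle(c(1, 2, 3), c(1, 3, 2)))
  expect_error(pcc_mapped(c(1, 1, 1), c(1, 2, 3)),
               class = "synfair_undefined_resemblance")
  expect_error(pcc_mapped(c(1, 2, 3), c(2, 2, 2)), "synthetic")
})

test_that("mapped correlation is symmetric and affine-invariant", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(pcc_mapped(a, b), pcc_mapped(b, a))
    expect_equal(pcc_mapped(2.5 * a + 3, b), pcc_mapped(a, b))
    expect_equal(pcc_mapped(a, 0.1 * b - 7), pcc_mapped(a, b))
  }
})

test_that("directional symmetry counts sign agreements with ties agreeing", {
  expect_equal(directional_symmetry(1:5, 1:5), 100)  # identical monotone
  # signs (+,+,-) vs (+,-,-): 2 of 3 agree
  expect_equal(directional_symmetry(c(1, 2, 3, 2), c(1, 3, 2, 1)), 200 / 3)
  # a zero step counts as agreement (the >= 0 tie rule)
  expect_equal(directional_symmetry(c(1, 1), c(1, 2)), 100)
  expect_error(directional_symmetry(1, 1), "at least 2")
})

test_that("directional symmetry is symmetric and shift/scale invariant", {
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(directional_symmetry(a, b), directional_symmetry(b, a))
    expect_equal(directional_symmetry(a + 11, b), directional_symmetry(a, b))
    expect_equal(directional_symmetry(3 * a, 0.2 * b),
                 directional_symmetry(a, b))
  }
})

test_that("time-series log disparity thresholds match the shared scale", {
  expect_equal(ts_log_disparity(0.8, 0.8), 0)
  expect_equal(ts_log_disparity(0.90, 0.95), log(0.90 / 0.95))
  expect_equal(categorize(ts_log_disparity(0.90, 0.95)), "adequate")
  expect_equal(ts_log_disparity(0.70, 0.95), -0.305382, tolerance = 1e-5)
  expect_equal(categorize(ts_log_disparity(0.70, 0.95)), "highly_under")
  expect_equal(ts_log_disparity(0.95, 0.70), -ts_log_disparity(0.70, 0.95))
  expect_error(ts_log_disparity(0, 0.5), class = "synfair_undefined_disparity")
  # scale factors cancel: DS percentages and mapped correlations give the
  # same disparity as their rescaled versions
  expect_equal(ts_log_disparity(90, 95), ts_log_disparity(0.90, 0.95))
})

test_that("an identity temporal pair has zero disparity everywhere", {
  pair <- simulate_pair("atus", n_R = 200, n_S = 200, seed = 2)
  ident <- dataset_pair(pair$real,
                        as_tabular_dataset(pair$real$data, pair$schema,
                                           "synthetic"),
                        pair$schema)
  for (metric in c("pcc", "ds")) {
    res <- evaluate_timeseries(ident, metric = metric)
    ok <- res$flag == ""
    expect_true(all(abs(res$ts_log_disparity[ok]) < 1e-12))
    expect_true(all(res$category[ok] == "adequate"))
  }
})

test_that("multivariate series yield per-feature rows plus a mean summary", {
  pair <- simulate_pair("asd", n_R = 400, n_S = 400, seed = 9)
  sgs <- enumerate_subgroups(pair$schema, 1)
  res <- evaluate_timeseries(pair, subgroups = sgs, metric = "pcc")
  feats <- names(pair$schema$temporal_features)
  expect_length(feats, 7)
  one <- res[res$subgroup == "gender=Male", ]
  expect_setequal(one$feature, c(feats, "(mean)"))
  mean_row <- one[one$feature == "(mean)", ]
  per <- one[one$feature != "(mean)", ]
  expect_equal(mean_row$res_g1, mean(per$res_g1))
  expect_equal(mean_row$ts_log_disparity,
               log(mean(per$res_g1) / mean(per$res_g0)))
})

test_that("concatenated mode joins features in schema order", {
  pair <- simulate_pair("asd", n_R = 300, n_S = 300, seed = 10)
  sg <- subgroup(c(gender = "Female"), pair$schema)
  res <- evaluate_timeseries(pair, subgroups = list(sg), metric = "pcc",
                             mode = "concatenated")
  expect_equal(res$feature, "concatenated")
  # oracle: build the concatenated series by hand and compare
  g1r <- unlist(aggregate_series(pair$real, sg, pair$schema, "mean"),
                use.names = FALSE)
  g1s <- unlist(aggregate_series(pair$synthetic, sg, pair$schema, "mean"),
                use.names = FALSE)
  expect_length(g1r, 7 * 10)
  expect_equal(res$res_g1, pcc_mapped(g1r, g1s))
})

test_that("the two resemblance metrics can disagree in category", {
  # same macro-trend (high correlation) but alternating micro-jitter that
  # flips most step directions
  a <- as.numeric(1:10)
  b <- a + 0.8 * (-1)^(1:10)
  pcc_ld <- ts_log_disparity(pcc_mapped(a, b), 1)
  ds_ld <- ts_log_disparity(directional_symmetry(a, b), 100)
  expect_equal(categorize(pcc_ld), "adequate")
  expect_true(categorize(ds_ld) %in% c("under", "highly_under"))
})

test_that("a subgroup absent from the synthetic arm is reported missing", {
  sch <- tiny_temporal_schema(4)
  real_df <- data.frame(gender = rep(c("Male", "Female"), each = 4))
  syn_df <- data.frame(gender = rep("Male", 6))
  set.seed(3)
  for (col in sch$temporal_features$hr) {
    real_df[[col]] <- rnorm(8); syn_df[[col]] <- rnorm(6)
  }
  pair <- dataset_pair(as_tabular_dataset(real_df, sch, "real"),
                       as_tabular_dataset(syn_df, sch, "synthetic"), sch)
  res <- evaluate_timeseries(pair)
  fem <- res[res$subgroup == "gender=Female", ]
  expect_equal(fem$category, "missing")
  expect_equal(fem$flag, "missing_in_synthetic")
  # the run is not aborted: the other subgroup is still evaluated
  expect_true(any(res$subgroup == "gender=Male" & res$flag != "absent_in_real"))
})
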