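test_that("odds has its fixed points and rejects p = 1", {
  expect_equal(odds(0.5), 1)
  expect_equal(odds(0), 0)
  expect_equal(odds(13135 / 30526), 13135 / 17391)  # ~ 0.755276
  expect_error(odds(1), class = "synfair_degenerate_subgroup")
  expect_error(odds(-0.1), "proportion")
})

test_that("log disparity reproduces hand-computed odds ratios", {
  # survey worked example from the published gender totals
  expect_equal(log_disparity(12806, 30000, 13135, 30526),
               log((12806 / 17194) / (13135 / 17391)))
  expect_equal(log_disparity(12806, 30000, 13135, 30526), -0.013974,
               tolerance = 1e-4)
  # identical counts and totals -> exactly 0
  expect_identical(log_disparity(250, 1000, 250, 1000), 0)
  # direct arithmetic: ln((0.1/0.9)/(0.05/0.95))
  expect_equal(log_disparity(100, 1000, 50, 1000),
               log((0.1 / 0.9) / (0.05 / 0.95)))
  expect_equal(log_disparity(100, 1000, 50, 1000), 0.747214,
               tolerance = 1e-6)
})

test_that("log disparity edge cases: missing sentinel and hard errors", {
  expect_true(is.na(log_disparity(0, 1000, 50, 1000)))  # mode collapse
  expect_error(log_disparity(10, 1000, 0, 1000),
               class = "synfair_reference_error")
  expect_error(log_disparity(1000, 1000, 50, 1000),
               class = "synfair_degenerate_subgroup")
  expect_error(log_disparity(10, 1000, 1000, 1000),
               class = "synfair_degenerate_subgroup")
})

test_that("continuity correction keeps sparse tables finite", {
  expect_true(is.finite(log_disparity(0, 100, 3, 100,
                                      continuity_correction = TRUE)))
  # correction barely moves a well-filled table
  plain <- log_disparity(400, 1000, 500, 1000)
  cc <- log_disparity(400, 1000, 500, 1000, continuity_correction = TRUE)
  expect_equal(cc, plain, tolerance = 0.01)
})

test_that("categorization uses six levels with ties to the severe side", {
  expect_setequal(category_levels(),
                  c("highly_over", "over", "adequate", "under",
                    "highly_under", "missing"))
  expect_length(category_levels(), 6)

  sc <- category_scale()
  expect_equal(sc$t1, abs(log(0.9)))
  expect_equal(sc$t2, abs(log(0.8)))

  expect_equal(categorize(0), "adequate")
  expect_equal(categorize(0.15), "over")      # log(1/0.9) <= 0.15 < log(1/0.8)
  expect_equal(categorize(-0.15), "under")
  expect_equal(categorize(0.3), "highly_over")
  expect_equal(categorize(-0.3), "highly_under")
  expect_equal(categorize(NA_real_), "missing")

  # boundary behavior: exactly t1 -> flagged, exactly t2 -> highly
  expect_equal(categorize(sc$t1), "over")
  expect_equal(categorize(-sc$t1), "under")
  expect_equal(categorize(sc$t2), "highly_over")
  expect_equal(categorize(-sc$t2), "highly_under")
  expect_equal(categorize(sc$t1 * (1 - 1e-9)), "adequate")
  expect_equal(categorize(sc$t2 * (1 - 1e-9)), "over")
})

test_that("binary-attribute log disparities are exactly antisymmetric", {
  set.seed(21)
  for (i in 1:20) {
    n_R <- sample(100:5000, 1); n_S <- sample(100:5000, 1)
    cR <- sample(seq_len(n_R - 1), 1); cS <- sample(seq_len(n_S - 1), 1)
    ld_a <- log_disparity(cS, n_S, cR, n_R)
    ld_b <- log_disparity(n_S - cS, n_S, n_R - cR, n_R)
    expect_equal(ld_a, -ld_b)
  }
})

test_that("log disparity is monotone in count_S and scale-invariant", {
  lds <- vapply(10:90, function(cS) log_disparity(cS, 100, 50, 100),
                numeric(1))
  expect_true(all(diff(lds) > 0))
  for (k in c(2, 5, 17)) {
    expect_equal(log_disparity(30 * k, 100 * k, 40 * k, 120 * k),
                 log_disparity(30, 100, 40, 120))
  }
})

test_that("disparate impact equals the odds ratio on product-form populations", {
  # worked example: P(g=1|y'=1)=0.3, P(g=1|y=1)=0.2 -> both (0.3/0.7)/(0.2/0.8)
  pop <- independent_population(c(3, 1, 7, 9), u = 1, v = 4)
  expect_equal(mean(pop$g[pop$yprime == 1]), 0.3)
  expect_equal(mean(pop$g[pop$y == 1]), 0.2)
  o <- disparate_impact_oracle(pop)
  expect_equal(o$eq_di_value, (0.3 / 0.7) / (0.2 / 0.8))
  expect_equal(o$odds_ratio_value, o$eq_di_value, tolerance = 1e-12)

  # no association between g and y' -> both ratios are 1
  pop0 <- independent_population(c(4, 6, 8, 12), u = 2, v = 3)
  o0 <- disparate_impact_oracle(pop0)
  expect_equal(o0$eq_di_value, 1)
  expect_equal(o0$odds_ratio_value, 1)
})

test_that("the equivalence holds on randomized product-form populations", {
  set.seed(97)
  for (i in 1:100) {
    counts <- sample(1:20, 4, replace = TRUE)
    u <- sample(1:5, 1); v <- sample(1:5, 1)
    pop <- independent_population(counts, u, v)
    expect_lte(nrow(pop), 1e4)
    o <- disparate_impact_oracle(pop)
    expect_lt(abs(o$eq_di_value - o$odds_ratio_value), 1e-12)
  }
})

test_that("an identity pair is adequate everywhere with zero disparity", {
  sch <- tiny_schema()
  set.seed(5)
  df <- data.frame(gender = sample(c("Male", "Female"), 200, TRUE),
                   age = sample(c("young", "old"), 200, TRUE))
  res <- evaluate_rates(identity_pair(df, sch), max_order = "all")
  evaluable <- res$flag == ""
  expect_true(any(evaluable))
  expect_true(all(res$log_disparity[evaluable] == 0))
  expect_true(all(res$category[evaluable] == "adequate"))
  expect_true(all(res$p_value[evaluable] == 1))
  expect_true(all(!res$significant[evaluable]))
})

test_that("a subgroup absent only from the synthetic data is missing", {
  sch <- tiny_schema()
  real_df <- tiny_table(5)
  syn_df <- real_df[real_df$gender != "Female" | real_df$age != "old", ]
  pair <- dataset_pair(as_tabular_dataset(real_df, sch, "real"),
                       as_tabular_dataset(syn_df, sch, "synthetic"), sch)
  res <- evaluate_rates(pair, max_order = "all")
  row <- res[res$subgroup == "gender=Female&age=old", ]
  expect_equal(row$category, "missing")
  expect_equal(row$flag, "missing_in_synthetic")
  # a subgroup absent from the real data is flagged, not categorized
  syn_only <- rbind(real_df, data.frame(gender = "Male", age = "old"))
  pair2 <- dataset_pair(
    as_tabular_dataset(real_df[!(real_df$gender == "Male" &
                                   real_df$age == "old"), ], sch, "real"),
    as_tabular_dataset(syn_only, sch, "synthetic"), sch)
  res2 <- evaluate_rates(pair2, max_order = "all")
  row2 <- res2[res2$subgroup == "gender=Male&age=old", ]
  expect_equal(row2$flag, "absent_in_real")
  expect_true(is.na(row2$category))
})
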