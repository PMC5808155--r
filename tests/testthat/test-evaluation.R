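test_that("residuals are predicted minus observed over all measured cells", {
  p <- fig_lacc_pair()
  rec <- simulate_record(p, dilution6_design(2.5, 2.5), "mean", 0)
  res <- model_residuals(rec, surface_model("mean", p))
  expect_identical(nrow(res), 36L)
  expect_lt(max(abs(res$residual)), 1e-12)
  # sign convention: observed below prediction gives positive residual
  rec$responses[3, 3] <- rec$responses[3, 3] - 0.1
  res2 <- model_residuals(rec, surface_model("mean", p))
  expect_equal(sort(res2$residual, decreasing = TRUE)[1], 0.1)
  # missing cells are skipped
  rec$responses[2, 2] <- NA
  expect_identical(nrow(model_residuals(rec, surface_model("mean", p))), 35L)
})

test_that("bias and mse follow their definitions and decomposition", {
  p <- fig_lacc_pair()
  rec <- simulate_record(p, dose_design(c(0, 1), c(0, 1)), "mean", 0)
  m <- surface_model("mean", p)
  pred <- surface_matrix(m, c(0, 1), c(0, 1))
  rec$responses <- pred - matrix(c(0.1, -0.1, 0.2, 0.2), 2, 2)
  ev <- evaluate_record(rec, m)
  expect_equal(ev$bias, mean(c(0.1, -0.1, 0.2, 0.2)))
  expect_equal(ev$mse, mean(c(0.1, -0.1, 0.2, 0.2)^2))
  expect_gte(ev$mse, ev$bias^2)
  rec$responses <- pred - matrix(0.2, 2, 2)
  ev2 <- evaluate_record(rec, m)
  expect_equal(ev2$bias, 0.2)
  expect_equal(ev2$mse, 0.04)
})

test_that("mse dominates squared bias on noisy simulated records", {
  set.seed(3)
  for (i in 1:10) {
    p <- make_pair("both", random = TRUE)
    rec <- simulate_record(p, linear8_design(4 * p$curve1$e, 4 * p$curve2$e),
                           "gi", 0.05)
    ev <- evaluate_record(rec, surface_model("mean", p))
    expect_gte(ev$mse, ev$bias^2)
  }
})

test_that("a model evaluated against its own noiseless surface is exact", {
  set.seed(29)
  for (kind in c("gi", "mean", "2to1")) {
    p <- make_pair("both", random = TRUE)
    rec <- simulate_record(p, linear8_design(4 * p$curve1$e, 4 * p$curve2$e),
                           kind, 0)
    ev <- evaluate_record(rec, surface_model(kind, p))
    expect_lt(ev$mse, (2e-9)^2)
    expect_lt(abs(ev$bias), 2e-9)
  }
})

test_that("the outlier rule excludes gross cells and counts them", {
  p <- fig_lacc_pair()
  rec <- simulate_record(p, dilution6_design(2.5, 2.5), "mean", 0.01,
                         seed = 8)
  rec$responses[4, 4] <- rec$responses[4, 4] + 2   # plate artifact
  m <- surface_model("mean", p)
  ev_all <- evaluate_record(rec, m)
  ev_rob <- evaluate_record(rec, m, mad_mult = 5)
  expect_identical(ev_rob$n_outliers, 1L)
  expect_identical(ev_rob$n_points + ev_rob$n_outliers, ev_all$n_points)
  expect_lt(ev_rob$mse, ev_all$mse)
})

test_that("the generating model wins the paired comparison", {
  recs <- simulate_population(30, scenario = "both", truth_kind = "mean",
                              noise_sd = 0.02, seed = 101)
  cmp <- compare_models(recs, models = c("gi", "mean"),
                        alternative = "greater")
  expect_gt(cmp$n, 20)
  expect_lt(cmp$p_mse, 0.01)
  expect_lt(median(cmp$per_record$mse_mean), median(cmp$per_record$mse_gi))
})

test_that("consistent-pair populations make the models indistinguishable", {
  recs <- simulate_population(10, scenario = "lacc", truth_kind = "gi",
                              noise_sd = 0, seed = 7)
  cmp <- compare_models(recs, models = c("gi", "mean"))
  # fitted pairs recover proportional curves; surfaces coincide to solver tol
  d <- abs(cmp$per_record$mse_gi - cmp$per_record$mse_mean)
  expect_lt(max(d), 1e-12)
  expect_error(compare_models(list()), "no records")
})
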