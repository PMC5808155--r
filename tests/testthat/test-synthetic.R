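test_that("standard designs match their screening layouts", {
  d6 <- dilution6_design(2.5, 125)
  expect_equal(d6$doses1, c(0, 2.5 / 256, 2.5 / 64, 2.5 / 16, 2.5 / 4, 2.5))
  expect_equal(d6$doses2, c(0, 125 / 256, 125 / 64, 125 / 16, 125 / 4, 125))
  l8 <- linear8_design(4, 8)
  expect_identical(length(l8$doses1), 8L)
  expect_equal(l8$doses1, seq(0, 4, length.out = 8))
  expect_equal(diff(l8$doses2), rep(8 / 7, 7))
  expect_error(dose_design(c(0.1, 1), c(0, 1)), "start at exactly 0")
  expect_error(dose_design(c(0, 1, 1), c(0, 1)), "strictly increasing")
})

test_that("fixture pairs carry the canonical illustration parameters", {
  p <- make_pair("lacc")
  expect_equal(c(p$curve1$e, p$curve2$e, p$curve1$s, p$curve1$y_inf),
               c(1, 2, 2, 0))
  pb <- make_pair("both")
  expect_equal(c(pb$curve1$s, pb$curve2$s, pb$curve1$y_inf, pb$curve2$y_inf),
               c(1, 2, 0.3, 0))
})

test_that("random scenarios enforce their constraints", {
  set.seed(99)
  for (i in 1:20) {
    pl <- make_pair("lacc", random = TRUE)
    expect_true(check_lacc(pl)$proportional)
    ps <- make_pair("slopes", random = TRUE)
    expect_gte(abs(ps$curve1$s - ps$curve2$s), 0.2)
    expect_identical(ps$curve1$y_inf, ps$curve2$y_inf)
    pm <- make_pair("max_effect", random = TRUE)
    expect_gte(abs(pm$curve1$y_inf - pm$curve2$y_inf), 0.1)
    pb <- make_pair("both", random = TRUE)
    expect_gte(abs(pb$curve1$s - pb$curve2$s), 0.2)
    expect_gte(abs(pb$curve1$y_inf - pb$curve2$y_inf), 0.1)
  }
})

test_that("noiseless records reproduce the conditional curves exactly", {
  p <- make_pair("both")
  rec <- simulate_record(p, linear8_design(4, 4), "gi", 0)
  expect_equal(rec$responses[, 1],
               hill_response(p$curve1, rec$design$doses1),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(rec$responses[1, ],
               hill_response(p$curve2, rec$design$doses2),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("simulation is deterministic given a seed", {
  p <- make_pair("both")
  r1 <- simulate_record(p, linear8_design(4, 4), "mean", 0.05, seed = 42)
  r2 <- simulate_record(p, linear8_design(4, 4), "mean", 0.05, seed = 42)
  expect_identical(r1$responses, r2$responses)
  pop1 <- simulate_population(3, "slopes", "mean", 0.02, seed = 9)
  pop2 <- simulate_population(3, "slopes", "mean", 0.02, seed = 9)
  expect_identical(lapply(pop1, `[[`, "responses"),
                   lapply(pop2, `[[`, "responses"))
  pop3 <- simulate_population(3, "slopes", "mean", 0.02, seed = 10)
  expect_false(identical(pop1[[1]]$responses, pop3[[1]]$responses))
})

test_that("fitting a noiseless record recovers the generating pair", {
  set.seed(55)
  p <- make_pair("lacc", random = TRUE)
  rec <- simulate_record(p, linear8_design(4 * p$curve1$e, 4 * p$curve2$e),
                         "gi", 0)
  cs <- conditional_series(rec)
  fit <- fit_pair(cs$cond1, cs$cond2)
  rel <- function(a, b) abs(a - b) / abs(b)
  expect_lt(rel(fit$pair$curve1$e, p$curve1$e), 1e-4)
  expect_lt(rel(fit$pair$curve2$e, p$curve2$e), 1e-4)
  expect_lt(rel(fit$pair$curve1$s, p$curve1$s), 1e-4)
})

test_that("systematic slope doubling drives the population test", {
  # records whose second compound is always twice as steep as the first
  set.seed(2024)
  recs <- lapply(1:50, function(i) {
    s1 <- runif(1, 0.5, 2)
    p <- curve_pair(hill_curve(1, 0, exp(runif(1, log(0.25), log(4))), s1),
                    hill_curve(1, 0, exp(runif(1, log(0.25), log(4))),
                               2 * s1))
    simulate_record(p, linear8_design(4 * p$curve1$e, 4 * p$curve2$e),
                    "mean", 0.02, id = sprintf("dbl-%02d", i))
  })
  fits <- lapply(recs, function(r) {
    cs <- conditional_series(r)
    fit_pair(cs$cond1, cs$cond2)
  })
  res <- population_lacc_test(fits)
  expect_lt(res$p_slope, 0.001)
})
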