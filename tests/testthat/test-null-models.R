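test_that("implicit model matches closed forms for a consistent pair", {
  p <- fig_lacc_pair()
  expect_equal(general_isobole(p, 1, 2), 0.2, tolerance = 5e-9)
  expect_equal(explicit_2to1(p, 1, 2), 0.2, tolerance = 1e-12)
  expect_equal(explicit_1to2(p, 1, 2), 0.2, tolerance = 1e-12)
  expect_equal(explicit_mean(p, 1, 2), 0.2, tolerance = 1e-12)
  expect_equal(explicit_mean(p, 1, 2, "geometric"), 0.2, tolerance = 1e-12)
})

test_that("axis doses reproduce the conditional curves exactly", {
  p <- fig_both_pair()
  for (kind in c("gi", "2to1", "1to2", "mean", "geomean")) {
    m <- surface_model(kind, p)
    x <- c(0.3, 1, 2.7)
    expect_equal(evaluate_surface(m, x, 0), hill_response(p$curve1, x),
                 tolerance = 1e-9)
    expect_equal(evaluate_surface(m, 0, x), hill_response(p$curve2, x),
                 tolerance = 1e-9)
    expect_equal(evaluate_surface(m, 0, 0), 1)
  }
})

test_that("unequal maximal effects trigger the fallback rules", {
  p <- fig_maxeff_pair()    # y_inf1 = 0.3, y_inf2 = 0
  x2 <- hill_inverse(p$curve2, 0.1)   # f2(x2) = 0.1 < 0.3
  expect_equal(general_isobole(p, 5, x2), 0.1, tolerance = 1e-9)
  expect_equal(explicit_2to1(p, 5, x2), 0.1, tolerance = 1e-12)
  # explicit mean keeps its 1->2 component alive (differs from implicit)
  x1 <- hill_inverse(p$curve1, 0.5)
  m <- explicit_mean(p, x1, x2)
  expected <- 0.5 * (0.1 + hill_response(p$curve2,
                                         hill_inverse(p$curve2, 0.5) + x2))
  expect_equal(m, expected, tolerance = 1e-12)
  expect_equal(m, 0.0954545454545, tolerance = 1e-9)  # brute-force oracle
})

test_that("sham combination: a compound with itself adds doses", {
  set.seed(31)
  for (i in 1:100) {
    crv <- random_curve()
    p <- curve_pair(crv, crv)
    x1 <- runif(10, 0, 4 * crv$e); x2 <- runif(10, 0, 4 * crv$e)
    g <- expand.grid(x1 = x1, x2 = x2)
    expect_lt(max(abs(general_isobole(p, g$x1, g$x2) -
                      hill_response(crv, g$x1 + g$x2))), 2e-9)
  }
})

test_that("all four models coincide when the consistency condition holds", {
  set.seed(13)
  for (i in 1:100) {
    p <- random_lacc_pair()
    d1 <- sort(runif(10, 0, 4 * p$curve1$e))
    d2 <- sort(runif(10, 0, 4 * p$curve2$e))
    g <- expand.grid(x1 = d1, x2 = d2)
    vals <- cbind(general_isobole(p, g$x1, g$x2),
                  explicit_2to1(p, g$x1, g$x2),
                  explicit_1to2(p, g$x1, g$x2),
                  explicit_mean(p, g$x1, g$x2))
    spread <- apply(vals, 1, function(v) diff(range(v)))
    expect_lt(max(spread), 5e-9)
  }
})

test_that("models diverge when the consistency condition is violated", {
  p <- fig_both_pair()
  g <- seq(0, 4, length.out = 20)
  gg <- expand.grid(x1 = g, x2 = g)
  expect_gt(max(abs(general_isobole(p, gg$x1, gg$x2) -
                    explicit_mean(p, gg$x1, gg$x2))), 0.01)
})

test_that("bisection agrees with an independent dense-scan oracle", {
  set.seed(17)
  for (i in 1:5) {
    p <- curve_pair(random_curve(), random_curve())
    x1 <- runif(1, 0.1, 3); x2 <- runif(1, 0.1, 3)
    y_scan <- gi_scan_oracle(p, x1, x2, n_scan = 1e5)
    expect_equal(general_isobole(p, x1, x2), y_scan, tolerance = 1e-4)
  }
})

test_that("surfaces are non-increasing in each dose and mean is bracketed", {
  set.seed(19)
  for (i in 1:10) {
    p <- curve_pair(random_curve(), random_curve())
    d1 <- sort(runif(10, 0, 4 * p$curve1$e))
    d2 <- sort(runif(10, 0, 4 * p$curve2$e))
    for (kind in c("gi", "2to1", "1to2", "mean", "geomean")) {
      m <- surface_matrix(surface_model(kind, p), d1, d2)
      expect_true(all(apply(m, 2, diff) <= 1e-9))
      expect_true(all(apply(m, 1, diff) <= 1e-9))
    }
    g <- expand.grid(x1 = d1, x2 = d2)
    a <- explicit_2to1(p, g$x1, g$x2)
    b <- explicit_1to2(p, g$x1, g$x2)
    mean_s <- explicit_mean(p, g$x1, g$x2)
    expect_true(all(mean_s >= pmin(a, b) & mean_s <= pmax(a, b)))
  }
})

test_that("surface_matrix lays out doses1 as rows and doses2 as columns", {
  p <- fig_lacc_pair()
  m <- surface_matrix(surface_model("mean", p), c(0, 1), c(0, 1, 2))
  expect_identical(dim(m), c(2L, 3L))
  expect_equal(m[1, 1], 1)
  expect_equal(m[2, 1], hill_response(p$curve1, 1))
  expect_equal(m[1, 3], hill_response(p$curve2, 2))
  expect_equal(surface_matrix(surface_model("gi", p), 0, 0)[1, 1], 1)
  expect_error(surface_matrix(surface_model("gi", p), c(1, 0), c(0, 1)),
               "ascending")
})
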