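test_that("closed forms agree with adaptive quadrature over random parameters", {
  set.seed(11)
  for (i in 1:50) {
    k <- exp(runif(1, log(0.5), log(12)))
    lam <- exp(runif(1, log(0.5), log(20)))
    expect_equal(quad(function(t) dwhole(t, k, lam)), 1, tolerance = 1e-8)
    expect_equal(quad(function(t) dbiased(t, k, lam)), 1, tolerance = 1e-8)
    expect_equal(quad(function(v) dforward(v, k, lam)), 1, tolerance = 1e-8)
    ew <- quad(function(t) t * dwhole(t, k, lam))
    ev <- quad(function(v) v * dforward(v, k, lam))
    expect_equal(whole_mean(k, lam), ew, tolerance = 1e-8)
    expect_equal(forward_mean(k, lam), ev, tolerance = 1e-8)
    expect_equal(mean_ratio(k), ew / ev, tolerance = 1e-8)
    expect_equal(forward_mean(k, lam) * mean_ratio(k), whole_mean(k, lam),
                 tolerance = 1e-10)
  }
})

test_that("memoryless and degenerate limits hold", {
  # k = 1: exponential; forward law equals the whole law, ratio 1
  expect_equal(whole_mean(1, 7), 7)
  expect_equal(forward_mean(1, 3), 3)
  expect_equal(mean_ratio(1), 1, tolerance = 1e-12)
  v <- seq(0, 30, by = 0.01)
  expect_lt(max(abs(dforward(v, 1, 4) - dwhole(v, 1, 4))), 1e-12)
  # exact Weibull values
  expect_equal(dwhole(6, 1, 6), exp(-1) / 6)
  expect_equal(whole_mean(2, 1), sqrt(pi) / 2)
  # v = 0: forward density is 1 / E[T]
  expect_equal(dforward(0, 3.3, 5), 1 / whole_mean(3.3, 5))
  # k large: whole time degenerates at the scale, forward -> uniform(0, scale)
  expect_equal(forward_mean(500, 8), 4, tolerance = 1e-2)
  expect_equal(mean_ratio(1e4), 2, tolerance = 1e-3)
  # exponential length-biased mean is 2 * scale
  expect_equal(quad(function(t) t * dbiased(t, 1, 1)), 2, tolerance = 1e-8)
})

test_that("forward density is monotone non-increasing and the ratio increases in shape", {
  for (k in c(0.4, 1, 2.3, 4.5, 9)) {
    d <- dforward(seq(0, 40, by = 0.05), k, 5.5)
    expect_true(all(diff(d) <= 1e-13))
  }
  ks <- exp(seq(log(0.2), log(50), length.out = 200))
  r <- mean_ratio(ks)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 2))
})

test_that("samplers match the analytic moments and the rejection oracle", {
  set.seed(21)
  x <- rweibull(1e6, 2, 5)
  expect_equal(mean(x), whole_mean(2, 5), tolerance = 4 * sd(x) / sqrt(1e6))
  y <- rbiased(1e5, 2, 5)
  m_quad <- quad(function(t) t * dbiased(t, 2, 5))
  expect_equal(mean(y), m_quad, tolerance = 4 * sd(y) / sqrt(1e5))
  # the package's direct Gamma-transform draw vs an independent rejection draw
  z <- rbiased_reject(1e4, 2, 5)
  expect_gt(suppressWarnings(ks.test(y[1:1e4], z)$p.value), 0.01)
  # forward draws have the analytic mean
  v <- rforward(1e5, 4.5, 6)
  expect_equal(mean(v), forward_mean(4.5, 6), tolerance = 4 * sd(v) / sqrt(1e5))
})

test_that("cumulative forward distribution matches integrated density", {
  for (par in list(c(1.7, 3), c(4.5, 9))) {
    for (v in c(0.5, 2, 7)) {
      expect_equal(pforward(v, par[1], par[2]),
                   quad(function(u) dforward(u, par[1], par[2]), 0, v),
                   tolerance = 1e-8)
    }
  }
})

test_that("mean-ratio delta interval is well formed and its derivative is exact", {
  for (k in c(0.7, 1.5, 4.15, 8)) {
    h <- 1e-5 * k
    num <- (mean_ratio(k + h) - mean_ratio(k - h)) / (2 * h)
    expect_equal(mean_ratio_deriv(k), num, tolerance = 1e-6)
  }
  ci <- mean_ratio_ci(4.15, 0.25)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  expect_true(ci$lower >= 0 && ci$upper <= 2)
  deg <- mean_ratio_ci(2.5, 0)
  expect_equal(deg$lower, deg$estimate)
  expect_equal(deg$upper, deg$estimate)
})

test_that("parameter domain is enforced", {
  expect_error(dwhole(1, -1, 2), "shape")
  expect_error(dforward(1, 2, 0), "scale")
  expect_error(mean_ratio(-3), "positive")
  expect_error(mean_ratio_ci(2, 0.1, level = 1.2), "level")
  expect_error(mean_ratio_ci(2, -0.1), "non-negative")
})
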