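test_that("closed-form t density matches stats::dt and integrates to one", {
  xs <- seq(-8, 8, by = 0.25)
  for (nu in c(1, 2.5, 30, 69.25, 500)) {
    expect_equal(t_density(xs, nu), dt(xs, nu), tolerance = 1e-12)
    expect_equal(t_density(-xs, nu), t_density(xs, nu), tolerance = 1e-15)
  }
  expect_equal(t_density(0, 1), 1 / pi, tolerance = 1e-14)
  q <- integrate(function(u) t_density(u, 7.3), -Inf, Inf, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("alpha is an even, decreasing tail probability with the right limits", {
  expect_equal(alpha_of_x(0, 10), 1)
  expect_equal(alpha_of_x(1.96, 1e6), 0.05, tolerance = 1e-3)
  expect_equal(alpha_of_x(-2.4, 17), alpha_of_x(2.4, 17))
  xs <- seq(0.1, 6, by = 0.1)
  expect_true(all(diff(alpha_of_x(xs, 12)) < 0))
})

test_that("beta has the stated limits and grows with the threshold", {
  expect_equal(beta_of_x(0, 20, 2.5), 0)
  expect_equal(beta_of_x(50, 20, 2.5), 1, tolerance = 1e-9)
  xs <- seq(0.1, 6, by = 0.1)
  expect_true(all(diff(beta_of_x(xs, 12, 1.8)) > 0))
})

test_that("alpha + beta = 1 identically when delta = 0", {
  for (nu in c(3, 10, 69.25, 200)) {
    xs <- seq(0, 8, by = 0.2)
    expect_equal(alpha_of_x(xs, nu) + beta_of_x(xs, nu, 0),
                 rep(1, length(xs)), tolerance = 1e-12)
  }
})

test_that("weighted error interpolates between its boundary limits", {
  g <- test_geometry(replica1_arms())
  er0 <- error_rates(0, g$nu, g$delta, g$prior, g$c_ratio)
  expect_equal(er0$epsilon, 1 - g$prior, tolerance = 1e-9)
  erInf <- error_rates(60, g$nu, g$delta, g$prior, g$c_ratio)
  expect_equal(erInf$epsilon, g$c_ratio * g$prior, tolerance = 1e-9)
  # with delta = 0, epsilon(x) = C pr + (1 - pr - C pr) alpha(x)
  er <- error_rates(1.7, 30, 0, prior = 0.5, c_ratio = 0.25)
  expect_equal(er$epsilon, 0.125 + 0.375 * er$alpha, tolerance = 1e-12)
  expect_equal(er$epsilon, 0.25 * 0.5 * er$beta + 0.5 * er$alpha, tolerance = 1e-15)
})

test_that("log-space stationarity residual equals the raw power form", {
  grid <- expand.grid(x = c(0.2, 1, 2.5, 5, 9),
                      nu = c(3, 30, 120, 400),
                      delta = c(0.5, 1.5, 3))
  got <- stationarity_residual(grid$x, grid$nu, grid$delta, k = 0)
  ref <- mapply(power_form_ratio, grid$x, grid$nu, grid$delta)
  expect_equal(got, ref, tolerance = 1e-10)
  # even in x
  expect_equal(stationarity_residual(-2.2, 40, 1.5, 0.125),
               stationarity_residual(2.2, 40, 1.5, 0.125), tolerance = 1e-14)
})

test_that("delta = 0 degenerates the residual to the constant 1/2 - k", {
  xs <- c(0.3, 1, 2, 7)
  expect_equal(stationarity_residual(xs, 25, 0, 0.125),
               rep(0.375, 4), tolerance = 1e-12)
})

test_that("replica-1 geometry has its stationary point near x = 2.17", {
  g <- test_geometry(replica1_arms(), effect_size = 0.5, prior = 0.5, c_ratio = 0.25)
  expect_equal(g$delta, 1.4910, tolerance = 1e-4)
  expect_equal(g$k, 0.125)
  # independent bisection on the power form
  f <- function(x) power_form_ratio(x, g$nu, g$delta) - g$k
  expect_gt(f(2.0), 0)
  expect_lt(f(2.4), 0)
  root <- bisect_root(f, 2.0, 2.4)
  expect_equal(root, 2.1694, tolerance = 1e-3)
})

test_that("geometry helpers agree where equal variances hold", {
  g <- equal_variance_geometry(50, effect_size = 0.5)
  expect_equal(g$nu, 98)
  expect_equal(g$delta, 2.5)
  expect_equal(equal_variance_geometry(2, effect_size = 1)$delta, 1)
  expect_equal(equal_variance_geometry(2, effect_size = 1)$nu, 2)
  expect_error(equal_variance_geometry(1), ">= 2")

  gm <- test_geometry(arm_summaries(50, 0, 1.3, 50, 0.4, 1.3))
  expect_equal(gm$nu, g$nu, tolerance = 1e-12)
  expect_equal(gm$delta, g$delta, tolerance = 1e-12)

  # k depends only on the weights
  expect_equal(test_geometry(replica2_arms(), prior = 0.5, c_ratio = 0.25)$k, 0.125)
  expect_equal(test_geometry(replica2_arms(), effect_size = 1e-12)$delta, 0,
               tolerance = 1e-10)
})
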