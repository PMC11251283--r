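test_that("ml recovers the exponential at xi = 1", {
  z <- seq(-20, 20, by = 0.25)
  expect_equal(ml(1, z), exp(z), tolerance = 1e-13)
  expect_identical(ml(1, 0), 1)
})

test_that("ml satisfies E_xi(0) = 1 for all orders", {
  for (xi in c(0.05, 0.25, 0.5, 0.75, 0.95, 1)) {
    expect_identical(ml(xi, 0), 1)
  }
})

test_that("ml at xi = 1/2 matches the scaled-complementary-error-function identity", {
  # E_{1/2}(-x) = exp(x^2) erfc(x) = erfcx(x)
  expect_equal(ml(0.5, -1), exp(1) * pracma::erfc(1), tolerance = 1e-12)
  x <- c(1.5, 2, 5, 10, 20, 26)   # pracma::erfcx overflows past ~26.6
  expect_equal(ml(0.5, -x), pracma::erfcx(x), tolerance = 1e-10)
})

test_that("ml is completely monotone and positive on the negative axis", {
  g <- seq(0, 100, by = 0.5)
  for (xi in c(0.3, 0.5, 0.7, 0.9, 0.95, 1)) {
    v <- ml(xi, -g)
    expect_true(all(v > 0))
    expect_true(all(diff(v) < 0))
    expect_identical(v[1], 1)
  }
})

test_that("ml matches the large-argument algebraic decay", {
  # E_xi(-x) = 1/(x Gamma(1-xi)) - 1/(x^2 Gamma(1-2xi)) + O(x^-3)
  for (xi in c(0.3, 0.6, 0.9)) {
    x <- 1e4
    lead <- 1 / (x * gamma(1 - xi))
    corr <- -1 / (x^2 * gamma(1 - 2 * xi))
    expect_equal(ml(xi, -x), lead + corr, tolerance = 1e-6)
  }
})

test_that("ml rejects out-of-range inputs", {
  expect_error(ml(0, 1), "xi")
  expect_error(ml(1.2, 1), "xi")
  expect_error(ml(1, NaN), "finite")
  expect_error(ml(1, 2e4), "1e4")
  expect_error(ml(1, 1, tol = 0), "tol")
  expect_error(ml(1, 1, max_terms = 10), "max_terms")
})

test_that("ab_normalization has the right endpoints and positivity", {
  expect_identical(ab_normalization(1), 1)
  expect_equal(ab_normalization(0.5), 1 - 0.5 + 0.5 / gamma(0.5),
               tolerance = 1e-15)
  for (xi in seq(0.05, 1, by = 0.05)) expect_gt(ab_normalization(xi), 0)
  expect_error(ab_normalization(0), "xi")
})

test_that("positivity bound is exact exponential decay in the classical limit", {
  sc <- scenario_paper()
  s <- supnorms(1, 1, 2000, 2, 2, 1)
  t <- seq(0, 50, by = 1)
  b <- positivity_bound("Z", t, sc$initial, sc$parameters,
                        fractional_orders(1, 1), s)
  # classical limit: Z(t) >= Z0 exp(-a t), the envelope collapses to it
  expect_equal(b$bound, sc$initial[["Z"]] * exp(-sc$parameters[["a"]] * t),
               tolerance = 1e-12)
})

test_that("positivity bound is a valid decreasing envelope under fractional orders", {
  sc <- scenario_paper()
  s <- supnorms(1, 1, 2000, 2, 2, 1)
  t <- seq(0, 100, by = 0.5)
  ord <- fractional_orders(0.95, 0.95)
  for (comp in c("T", "C", "D", "IL2", "IL12", "Z")) {
    b <- positivity_bound(comp, t, sc$initial, sc$parameters, ord, s)
    expect_true(all(is.finite(b$bound)))
    expect_true(all(diff(b$bound) <= 0))
    expect_true(all(b$bound >= 0))
    expect_equal(b$bound[1], sc$initial[[comp]], tolerance = 1e-14)
  }
})

test_that("positivity bound raises a domain error when the denominator closes", {
  # AB(xi) - (1 - xi) * rate <= 0 for a large enough rate
  p <- endemic_parameters()
  x0 <- state_vector(1, 1, 1, 1, 1, 1)
  s <- supnorms(1, 1, 1, 1, 1, 1)
  q <- unclass(p); q["a"] <- 50   # rate for Z is a
  q <- do.call(model_parameters, as.list(q))
  expect_error(
    positivity_bound("Z", 1, x0, q, fractional_orders(0.5, 0.95), s),
    "undefined")
})

test_that("classical trajectory stays above its positivity envelope", {
  # In the xi = eta = 1 limit the envelope is an exact exponential lower
  # bound, so the adaptive reference solution must dominate it to solver
  # accuracy. C is excluded: its defining rate subtracts the gain terms
  # (kappa - rho||D|| - phi||T||), so that envelope is not a certified
  # lower bound; for the other five the rate over-counts the losses.
  sc <- scenario_paper()
  cfg <- solver_config(dt = 0.1, t_end = 50)
  traj <- simulate_classical(sc$parameters, sc$initial, cfg)
  s <- supnorms_from_trajectory(traj)
  for (comp in c("T", "D", "IL2", "IL12", "Z")) {
    b <- positivity_bound(comp, traj$times, sc$initial, sc$parameters,
                          fractional_orders(1, 1), s)
    expect_true(all(traj$states[, comp] >= b$bound - 1e-8), label = comp)
  }
})

test_that("fractional trajectory respects its envelope up to discretization error", {
  sc <- scenario_paper()
  traj <- simulate_ffm(sc$parameters, sc$initial, sc$orders, sc$solver)
  s <- supnorms_from_trajectory(traj)
  for (comp in c("T", "D", "IL2", "IL12", "Z")) {
    b <- positivity_bound(comp, traj$times[-1], sc$initial, sc$parameters,
                          sc$orders, s)
    # the continuous-time bound holds up to the scheme's local error,
    # budgeted at 1% of the starting value of the compartment
    slack <- 0.01 * sc$initial[[comp]]
    expect_true(all(traj$states[-1, comp] >= b$bound - slack),
                label = comp)
  }
})
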