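test_that("OU conditional matches univariate closed forms and limits", {
  p <- ou_params(0, matrix(0.5), matrix(1))
  z <- ou_conditional(p, 2, 0)
  expect_equal(z$mean, 2)
  expect_equal(z$cov, matrix(0))

  z1 <- ou_conditional(p, 2, 1)
  expect_equal(z1$mean, 2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(z1$cov[1, 1], 1 - exp(-1), tolerance = 1e-12)

  # full relaxation: theta = I, dt = 50
  set.seed(5)
  p2 <- ou_params(c(60, 20), diag(2), diag(c(8, 6)))
  z2 <- ou_conditional(p2, c(0, 100), 50)
  statp <- ou_stationary(p2)
  expect_lt(max(abs(z2$mean - statp$mean)), 1e-10)
  expect_lt(max(abs(z2$cov - statp$cov)), 1e-10)

  expect_error(ou_conditional(ou_params(0, matrix(-1), matrix(1)), 0, 1),
               "unstable")
})

test_that("scalar OU conditional variance grows monotonically with dt", {
  p <- ou_params(0, matrix(0.7), matrix(1.3))
  v <- vapply(seq(0, 6, by = 0.25),
              function(dt) ou_conditional(p, 1, dt)$cov[1, 1], 0)
  expect_true(all(diff(v) >= 0))
})

test_that("OU stationary covariance solves the Lyapunov equation", {
  expect_equal(ou_stationary(ou_params(0, matrix(0.5), matrix(1)))$cov[1, 1], 1)
  p <- ou_params(c(1, 2), diag(c(0.5, 2)), diag(c(3, 4)))
  expect_equal(ou_stationary(p)$cov, diag(c(9 / 1, 16 / 4)), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:25) {
    q <- random_stable_ou(2)
    S <- ou_stationary(q)$cov
    resid <- q$theta %*% S + S %*% t(q$theta) - q$sigma %*% t(q$sigma)
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("VAR conditional compounds steps correctly", {
  p <- var_params(1, matrix(0.5), matrix(0.75))
  z1 <- var_conditional(p, 4, 1)
  expect_equal(z1$mean, 1 + 0.5 * 4)
  expect_equal(z1$cov[1, 1], 0.75)
  z2 <- var_conditional(p, 4, 2)
  expect_equal(z2$mean, 0.25 * 4 + 1.5)
  expect_equal(z2$cov[1, 1], 0.75 * 1.25)
  p0 <- var_params(c(1, 2), matrix(0, 2, 2), diag(2))
  for (k in c(1, 3))
    expect_equal(var_conditional(p0, c(9, 9), k)$mean, c(1, 2))
  expect_error(var_conditional(p, 4, 0), "steps")
})

test_that("VAR stationary distribution: closed forms and instability error", {
  p0 <- var_params(c(1, 2), matrix(0, 2, 2), diag(c(2, 3)))
  s0 <- var_stationary(p0)
  expect_equal(s0$mean, c(1, 2))
  expect_equal(s0$cov, diag(c(2, 3)))
  p <- var_params(1, matrix(0.5), matrix(0.75))
  s <- var_stationary(p)
  expect_equal(s$mean, 2)
  expect_equal(s$cov[1, 1], 1)
  expect_error(var_stationary(var_params(0, matrix(1), matrix(1))), "unstable")
  # discrete Lyapunov self-consistency on random stable draws
  set.seed(43)
  for (i in 1:25) {
    q <- ou_to_var(random_stable_ou(2), 0.8)
    S <- var_stationary(q)$cov
    resid <- S - q$transition %*% S %*% t(q$transition) - q$innovation_cov
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("OU -> VAR mapping reproduces the equal-spacing equivalence", {
  v <- ou_to_var(ou_params(3, matrix(log(2)), matrix(1)), 1)
  expect_equal(v$transition[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(v$intercept, 1.5, tolerance = 1e-12)
  set.seed(44)
  for (i in 1:10) {
    p <- random_stable_ou(2)
    v1 <- ou_to_var(p, 0.7)
    expect_equal(var_stationary(v1)$mean, p$mu, tolerance = 1e-8)
    expect_equal(var_stationary(v1)$cov, ou_stationary(p)$cov, tolerance = 1e-8)
    # A(2 dt) = A(dt)^2
    v2 <- ou_to_var(p, 1.4)
    expect_equal(v2$transition, v1$transition %*% v1$transition,
                 tolerance = 1e-10)
  }
})

test_that("gaussian_nll matches standard normal values", {
  expect_equal(gaussian_nll(0, list(mean = 0, cov = matrix(1))),
               0.5 * log(2 * pi), tolerance = 1e-9)
  C <- matrix(c(2, 0.3, 0.3, 1.5), 2)
  expect_equal(gaussian_nll(c(5, 7), list(mean = c(5, 7), cov = C)),
               0.5 * (2 * log(2 * pi) + log(det(C))), tolerance = 1e-9)
  expect_equal(gaussian_nll(c(3, 4), list(mean = c(0, 0), cov = diag(2))),
               log(2 * pi) + 12.5, tolerance = 1e-7)
})

test_that("parameter sets survive a JSON round trip", {
  set.seed(45)
  p <- random_stable_ou(2)
  q <- params_from_json(params_to_json(p))
  expect_equal(q$theta, p$theta)
  expect_equal(q$sigma, p$sigma)
  v <- ou_to_var(p, 1)
  v2 <- params_from_json(params_to_json(v))
  expect_equal(v2$transition, v$transition)
  s <- stationary_params(c(1, 2), diag(2))
  expect_equal(params_from_json(params_to_json(s))$cov, s$cov)
})
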