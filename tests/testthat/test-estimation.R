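test_that("series NLL matches a term-by-term reference sum", {
  set.seed(301)
  p <- random_stable_ou(2)
  s <- toy_series(c(10, 11.3, 12.1), c(1, 1, 1),
                  cbind(c(48, 55, 51), c(22, 18, 25)))
  plan <- build_transition_plan(s)
  expect_equal(series_nll("ou", p, s, plan),
               reference_series_nll("ou", p, s, plan), tolerance = 1e-8)
  v <- ou_to_var(p, 1)
  expect_equal(series_nll("var", v, s, plan),
               reference_series_nll("var", v, s, plan), tolerance = 1e-8)
  st <- stationary_params(c(50, 20), diag(c(25, 16)))
  expect_equal(series_nll("stationary", st, s, plan),
               reference_series_nll("stationary", st, s, plan),
               tolerance = 1e-10)
})

test_that("NLL is additive over independent series", {
  set.seed(302)
  st <- generate_study(study_config(n_series = 2, seed = 302))
  p <- st$truth$ou
  nlls <- vapply(st$series, function(s) series_nll("ou", p, s), 0)
  pooled <- sum(vapply(st$series, function(s)
    series_nll("ou", p, s, build_transition_plan(s)), 0))
  expect_equal(sum(nlls), pooled)
})

test_that("unstable parameters give an infinite objective, not an error", {
  s <- toy_series(c(10, 11, 12), c(1, 1, 1), cbind(1:3, 4:6))
  bad_ou <- structure(list(mu = c(0, 0),
                           theta = matrix(c(-1, 0, 0, 1), 2),
                           sigma = diag(2), d = 2), class = "ou_params")
  expect_identical(series_nll("ou", bad_ou, s), Inf)
  bad_var <- structure(list(intercept = c(0, 0),
                            transition = diag(c(1.2, 0.5)),
                            innovation_cov = diag(2), d = 2),
                       class = "var_params")
  expect_identical(series_nll("var", bad_var, s), Inf)
})

test_that("OU and the mapped VAR agree on equal unit spacing", {
  set.seed(303)
  for (i in 1:5) {
    p <- random_stable_ou(2)
    s <- equal_spaced_series(p, 40)
    plan <- build_transition_plan(s)
    expect_equal(series_nll("ou", p, s, plan),
                 series_nll("var", ou_to_var(p, 1), s, plan),
                 tolerance = 1e-8)
  }
})

test_that("closed-form VAR estimates: hand case and exact recovery", {
  # 3-point toy: transitions (0,1), (1,1.5), (1.5,1.75) -> a = 0.5, c = 1
  s <- toy_series(0:3, rep(1, 4), cbind(c(0, 1, 1.5, 1.75)))
  plan <- build_transition_plan(s)
  v <- var_closed_form(s, plan)
  expect_equal(v$transition[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(v$intercept, 1, tolerance = 1e-12)

  # exact linear recursion -> OLS recovers it to machine precision
  A <- matrix(c(0.6, 0.1, -0.2, 0.5), 2, byrow = TRUE)
  cc <- c(10, 5)
  x <- matrix(0, 30, 2)
  x[1, ] <- c(30, 20)
  for (i in 2:30) x[i, ] <- cc + A %*% x[i - 1, ]
  s2 <- toy_series(seq_len(30), rep(1, 30), x)
  v2 <- var_closed_form(s2)
  expect_equal(v2$transition, A, tolerance = 1e-8)
  expect_equal(v2$intercept, cc, tolerance = 1e-7)
  expect_lt(max(abs(v2$innovation_cov)), 1e-12)
})

test_that("closed-form VAR is consistent on white noise", {
  set.seed(304)
  x <- rnorm(8000)
  s <- toy_series(seq_along(x), rep(1, length(x)), cbind(x))
  v <- var_closed_form(s)
  expect_lt(abs(v$transition[1, 1]), 0.05)
  expect_equal(v$innovation_cov[1, 1], 1, tolerance = 0.05)
})

test_that("differential evolution is reproducible under a fixed seed", {
  set.seed(305)
  st <- generate_study(study_config(n_series = 1, seed = 305))
  s <- st$series[[1]]
  de <- de_config(np = 15, iters = 40, seed = 99)
  f1 <- fit_mle("ou", s, de = de)
  f2 <- fit_mle("ou", s, de = de)
  expect_identical(f1$params$theta, f2$params$theta)
  expect_identical(f1$train_nll, f2$train_nll)
})

test_that("the DE optimum is no worse than the generating parameters", {
  set.seed(306)
  st <- generate_study(study_config(n_series = 1, seed = 306))
  s <- st$series[[1]]
  f <- fit_mle("ou", s, de = de_config_fast(seed = 7))
  expect_lte(f$train_nll, series_nll("ou", st$truth$ou, s) + 1e-6)
})

test_that("univariate OU parameters are recovered from a long series", {
  # theta = 1, mu = 50, sigma = 5, N = 1000 equal unit steps
  p <- ou_params(50, matrix(1), matrix(5))
  set.seed(307)
  s <- equal_spaced_series(p, 1000)
  f <- fit_mle("ou", s, de = de_config(np = 30, iters = 300, seed = 307))
  expect_lt(abs(f$params$theta[1, 1] - 1), 0.2)
  expect_lt(abs(f$params$mu - 50), 0.5)
})

test_that("the DE-fitted VAR matches the closed-form OLS solution", {
  set.seed(308)
  p <- random_stable_ou(2)
  s <- equal_spaced_series(p, 300)
  plan <- build_transition_plan(s)
  # exclude the stationary item so OLS is the exact MLE of the objective
  plan$retained[plan$kind == "stationary"] <- FALSE
  ols <- var_closed_form(s, plan)
  nll_ols <- series_nll("var", ols, s, plan)
  f <- fit_mle("var", s, plan, de = de_config(np = 30, iters = 400, seed = 308))
  expect_lt(abs(f$train_nll - nll_ols), 1e-3)
})

test_that("fitting fails loudly on under-determined input", {
  s <- toy_series(c(10, 11), c(1, 1), cbind(c(1, 2), c(3, 4)))
  expect_error(fit_mle("ou", s), "under-determined")
})
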