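test_that("zero measurement error reduces the marginal NLL to the plain NLL", {
  set.seed(201)
  st <- generate_study(study_config(n_series = 2, seed = 201))
  for (s in st$series) {
    plan <- build_transition_plan(s)
    p <- st$truth$ou
    expect_equal(kalman_marginal_nll(p, noise_params(c(0, 0)), s, plan),
                 series_nll("ou", p, s, plan), tolerance = 1e-8)
    v <- ou_to_var(p, 1)
    expect_equal(kalman_marginal_nll(v, noise_params(c(0, 0)), s, plan),
                 series_nll("var", v, s, plan), tolerance = 1e-8)
  }
})

test_that("marginal NLL equals the brute-force joint Gaussian NLL", {
  set.seed(202)
  ts <- c(10, 11.3, 12.1)
  day <- c(1L, 1L, 1L)
  for (i in 1:5) {
    p <- random_stable_ou(2)
    path <- simulate_latent(p, ts, day)
    nz <- noise_params(c(2.5, 1.2))
    s <- observe(path, nz)
    plan <- build_transition_plan(s)
    expect_equal(kalman_marginal_nll(p, nz, s, plan),
                 joint_nll_oracle("ou", p, nz, s), tolerance = 1e-8)
    v <- ou_to_var(p, 0.9)
    expect_equal(kalman_marginal_nll(v, nz, s, plan),
                 joint_nll_oracle("var", v, nz, s), tolerance = 1e-8)
  }
})

test_that("C++ Kalman chain agrees with the R reference filter", {
  set.seed(203)
  st <- generate_study(study_config(n_series = 1, seed = 203))
  s <- st$series[[1]]
  plan <- build_transition_plan(s)
  p <- st$truth$ou
  nz <- noise_params(c(5, 3))
  ref <- affectdyn:::kalman_filter_pass("ou", p, nz, s, plan)
  expect_equal(kalman_marginal_nll(p, nz, s, plan), ref$nll, tolerance = 1e-8)
})

test_that("marginal NLL splits additively at day boundaries", {
  set.seed(204)
  st <- generate_study(study_config(n_series = 1, seed = 204))
  s <- st$series[[1]]
  p <- st$truth$ou
  nz <- noise_params(c(3, 3))
  whole <- kalman_marginal_nll(p, nz, s, build_transition_plan(s))
  cut <- max(which(s$day_index <= 3))
  first <- truncate_series(s, cut)
  rest <- esm_series(s$series_id, s$timestamps[-seq_len(cut)],
                     s$day_index[-seq_len(cut)],
                     s$ratings[-seq_len(cut), , drop = FALSE],
                     s$missing_mask[-seq_len(cut), , drop = FALSE])
  parts <- kalman_marginal_nll(p, nz, first, build_transition_plan(first)) +
    kalman_marginal_nll(p, nz, rest, build_transition_plan(rest))
  expect_equal(whole, parts, tolerance = 1e-8)
})

test_that("stationary-item predictive covariance is Sigma_y plus noise", {
  set.seed(205)
  p <- random_stable_ou(2)
  nz <- noise_params(c(4, 9))
  s <- toy_series(c(10, 11), c(1, 1), cbind(c(50, 51), c(20, 21)))
  item <- data.frame(kind = "stationary", source = NA, target = 1,
                     dt = NA, steps = NA, retained = TRUE)
  pred <- kalman_predict_next(p, nz, s, build_transition_plan(s)[0, ], item)
  statp <- ou_stationary(p)
  expect_equal(pred$mean, statp$mean)
  expect_equal(pred$cov, statp$cov + diag(c(4, 9)), tolerance = 1e-10)
})

test_that("one-step prediction matches a hand-run scalar Kalman recursion", {
  p <- ou_params(0, matrix(1), matrix(sqrt(2)))  # stationary variance 1
  r <- 0.5
  s <- toy_series(c(0, 1), c(1, 1), cbind(c(0.8, -0.3)))
  plan <- build_transition_plan(s)
  pred <- kalman_predict_next(p, noise_params(r), s, plan,
                              data.frame(kind = "transition", source = 2,
                                         target = 3, dt = 2, steps = 1,
                                         retained = TRUE))
  # hand recursion: prior (0, 1); two updates; propagate over dt = 2
  m <- 0; P <- 1
  for (x in c(0.8, -0.3)) {
    if (x != 0.8) { e <- exp(-1); m <- e * m; P <- e^2 * P + (1 - e^2) }
    K <- P / (P + r)
    m <- m + K * (x - m)
    P <- (1 - K) * P
  }
  e2 <- exp(-2)
  expect_equal(pred$mean, e2 * m, tolerance = 1e-10)
  expect_equal(pred$cov[1, 1], e2^2 * P + (1 - e2^2) + r, tolerance = 1e-10)
})

test_that("raising one error variance raises only that predictive variance", {
  set.seed(206)
  p <- random_stable_ou(2)
  s <- toy_series(c(10, 11.5), c(1, 1), cbind(c(48, 52), c(18, 22)))
  plan <- build_transition_plan(s)
  item <- data.frame(kind = "transition", source = 2, target = 3,
                     dt = 1.1, steps = 1, retained = TRUE)
  v1 <- kalman_predict_next(p, noise_params(c(1, 1)), s, plan, item)$cov
  v2 <- kalman_predict_next(p, noise_params(c(4, 1)), s, plan, item)$cov
  expect_gt(v2[1, 1], v1[1, 1])
})

test_that("vanishing noise drives the filtered mean to the observation", {
  set.seed(207)
  p <- random_stable_ou(2)
  s <- toy_series(c(10, 11), c(1, 1), cbind(c(70, 40), c(30, 10)))
  plan <- build_transition_plan(s)
  st <- affectdyn:::kalman_filter_pass("ou", p, noise_params(c(1e-8, 1e-8)), s, plan)
  expect_equal(st$m, unname(s$ratings[2, ]), tolerance = 1e-6)
})
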