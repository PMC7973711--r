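test_that("stratified schedule stays in-window with the nominal mean gap", {
  cfg <- study_config(n_series = 1, days = 1000, seed = 501)
  set.seed(501)
  sched <- sample_schedule(cfg)
  expect_length(sched$timestamps, 10000)
  within <- sched$timestamps - 24 * (sched$day_index - 1)
  expect_true(all(within >= 10 & within <= 22))
  expect_true(all(tapply(sched$timestamps, sched$day_index, function(x)
    all(diff(x) > 0))))
  gaps <- unlist(tapply(sched$timestamps, sched$day_index, diff))
  expect_lt(abs(mean(gaps) - 1.2), 0.1)  # 72 minutes on average

  cfg1 <- study_config(n_series = 1, beeps_per_day = 1, seed = 502)
  set.seed(502)
  s1 <- sample_schedule(cfg1)
  expect_length(s1$timestamps, cfg1$days)
})

test_that("noiseless latent dynamics relax deterministically toward mu", {
  p <- ou_params(c(60, 20), diag(c(1, 0.8)), matrix(0, 2, 2))
  set.seed(503)
  path <- simulate_latent(p, c(10, 11, 12, 13), rep(1L, 4))
  y <- path$latent
  d1 <- abs(y[1, ] - p$mu)
  for (i in 2:4) {
    d2 <- abs(y[i, ] - p$mu)
    expect_true(all(d2 <= d1 + 1e-12))
    d1 <- d2
  }
  # exact conditional-mean recursion when sigma = 0
  expect_equal(y[2, ], as.numeric(ou_conditional(p, y[1, ], 1)$mean),
               tolerance = 1e-10)
})

test_that("long-run beep moments match the stationary distribution", {
  p <- study_config(n_series = 1)$ou
  statp <- ou_stationary(p)
  set.seed(504)
  cfg <- study_config(n_series = 120, missing_rate = 0, seed = 504)
  st <- generate_study(cfg)
  pooled <- do.call(rbind, lapply(st$series, function(s) s$ratings))
  n <- nrow(pooled)
  se_mean <- sqrt(diag(statp$cov) / n) * 6  # beeps correlate; generous SE
  expect_true(all(abs(colMeans(pooled) - statp$mean) < pmax(se_mean, 0.5)))
  expect_equal(stats::cov(pooled), statp$cov, tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- generate_study(study_config(n_series = 2, event_rate = 1, seed = 505))
  b <- generate_study(study_config(n_series = 2, event_rate = 1, seed = 505))
  expect_identical(a$series[[1]]$ratings, b$series[[1]]$ratings)
  expect_identical(a$truth$paths[[2]]$event_beeps, b$truth$paths[[2]]$event_beeps)
  c2 <- generate_study(study_config(n_series = 2, event_rate = 1, seed = 506))
  expect_false(identical(a$series[[1]]$ratings, c2$series[[1]]$ratings))
  expect_identical(dim(a$series[[1]]$ratings), dim(c2$series[[1]]$ratings))
})

test_that("observation adds calibrated noise, missingness and clipping", {
  p <- study_config(n_series = 1)$ou
  set.seed(507)
  ts <- seq(0, by = 1.2, length.out = 4000)
  path <- simulate_latent(p, ts, rep(seq_len(400), each = 10))

  s0 <- observe(path, noise_params(c(0, 0)), missing_rate = 0)
  expect_identical(s0$ratings[, 1], path$latent[, 1])
  expect_false(any(s0$missing_mask))

  nz <- noise_params(c(25, 9))
  s1 <- observe(path, nz, missing_rate = 0)
  err <- s1$ratings - path$latent
  expect_equal(unname(apply(err, 2, stats::var)), nz$error_var,
               tolerance = 0.1)

  s2 <- observe(path, noise_params(c(0, 0)), missing_rate = 0.13)
  frac <- mean(!s2$missing_mask[, 1])
  expect_lt(abs(frac - 0.87), 3 * sqrt(0.13 * 0.87 / 4000))

  s3 <- observe(path, noise_params(c(1e4, 1e4)), clip_to_scale = TRUE)
  expect_true(all(s3$ratings[!s3$missing_mask] >= 0 &
                    s3$ratings[!s3$missing_mask] <= 100))
})

test_that("a generated study has the advertised shape and JSON-safe truth", {
  st <- generate_study(study_config(n_series = 5, seed = 508))
  expect_length(st$series, 5)
  expect_true(all(vapply(st$series, function(s) nrow(s$ratings) == 70, TRUE)))
  rt <- params_from_json(params_to_json(st$truth$ou))
  expect_equal(rt$theta, st$truth$ou$theta)
})
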