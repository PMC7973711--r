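# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately avoid the package's own likelihood kernels: matrix
# exponentials come from Matrix::expm, joint densities from dense Cholesky.

# stable OU draw: symmetric-PD + antisymmetric split guarantees eigenvalues
# with positive real part while allowing rotation (complex pairs)
random_stable_ou <- function(d = 2) {
  B <- matrix(rnorm(d * d, sd = 0.6), d, d)
  S <- B %*% t(B) + 0.3 * diag(d)
  K0 <- matrix(rnorm(d * d, sd = 0.5), d, d)
  K <- (K0 - t(K0)) / 2
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- rnorm(d * (d + 1) / 2, sd = 2)
  diag(L) <- abs(diag(L)) + 0.5
  ou_params(rnorm(d, 50, 10), S + K, L)
}

# single-day equally spaced noise-free observation of an OU path
equal_spaced_series <- function(ou, n, dt = 1, id = "eq") {
  ts <- (seq_len(n) - 1) * dt
  path <- simulate_latent(ou, ts, rep(1L, n))
  observe(path, noise_params(rep(0, ou$d)), series_id = id)
}

# hand-built bivariate series over explicit timestamps/days (no missing)
toy_series <- function(ts, day, x, id = "toy") {
  esm_series(id, ts, day, as.matrix(x))
}

mexp <- function(M) as.matrix(Matrix::expm(M))

mpow <- function(A, k) {
  out <- diag(nrow(A))
  for (j in seq_len(k)) out <- out %*% A
  out
}

# Brute-force joint multivariate-normal NLL of all non-missing beeps:
# days are independent blocks; within a day the joint covariance is
# assembled from the stationary covariance and the lag cross-covariances
# Cov(x_i, x_j) = Sigma_y * t(E(t_j - t_i)), with E the OU propagator
# e^{-theta dt} or the VAR power A^steps; measurement error adds a diagonal.
joint_nll_oracle <- function(family, params, noise, series) {
  d <- params$d
  if (family == "ou") {
    statp <- ou_stationary(params)
    Efun <- function(i, j, obs) mexp(-params$theta *
                                       (series$timestamps[obs[j]] - series$timestamps[obs[i]]))
  } else {
    statp <- var_stationary(params)
    Efun <- function(i, j, obs) mpow(params$transition, obs[j] - obs[i])
  }
  R <- diag(noise$error_var, d)
  total <- 0
  miss <- apply(series$missing_mask, 1, any)
  for (dd in unique(series$day_index)) {
    obs <- which(series$day_index == dd & !miss)
    if (!length(obs)) next
    m <- length(obs)
    Sig <- matrix(0, m * d, m * d)
    for (i in seq_len(m)) for (j in i:m) {
      blk <- if (i == j) statp$cov + R else statp$cov %*% t(Efun(i, j, obs))
      ri <- (i - 1) * d + seq_len(d)
      rj <- (j - 1) * d + seq_len(d)
      Sig[ri, rj] <- blk
      Sig[rj, ri] <- t(blk)
    }
    x <- as.numeric(t(series$ratings[obs, , drop = FALSE]))
    mu <- rep(statp$mean, m)
    ch <- chol((Sig + t(Sig)) / 2)
    z <- backsolve(ch, x - mu, transpose = TRUE)
    total <- total + 0.5 * (m * d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  total
}

# term-by-term R reference of the plain (error-free) series NLL
reference_series_nll <- function(family, params, series, plan) {
  statp <- switch(family, ou = ou_stationary(params),
                  var = var_stationary(params), stationary = params)
  tot <- 0
  for (k in seq_len(nrow(plan))) {
    if (!plan$retained[k]) next
    x <- series$ratings[plan$target[k], ]
    pred <- if (family == "stationary" || plan$kind[k] == "stationary") statp
    else if (family == "ou")
      ou_conditional(params, series$ratings[plan$source[k], ], plan$dt[k])
    else var_conditional(params, series$ratings[plan$source[k], ], plan$steps[k])
    tot <- tot + gaussian_nll(x, pred)
  }
  tot
}
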