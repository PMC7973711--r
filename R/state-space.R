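#' Measurement-error variances
#'
#' Per-dimension variances of independent Gaussian measurement error added
#' on top of the latent process (units: squared rating units). The error
#' covariance is diagonal: one variance per affect dimension.
#'
#' @param error_var Numeric length-d vector, entries `>= 0`.
#' @return A `noise_params` object.
#' @export
noise_params <- function(error_var) {
  error_var <- as.numeric(error_var)
  if (any(error_var < 0)) stop("error variances must be non-negative")
  structure(list(error_var = error_var, d = length(error_var)),
            class = "noise_params")
}

#' Kalman-filter marginal min-log-likelihood
#'
#' Marginal NLL of an observed series under a latent OU or VAR(1) process
#' plus diagonal Gaussian measurement error, computed by the linear Kalman
#' filter: at every stationary item (first beep of a day) the filter is
#' re-initialized from the latent stationary prior, so the predictive
#' covariance there is `Sigma_y + diag(error_var)`; at transition items the
#' latent state is propagated over the actual elapsed time (OU) or the
#' pseudo-step count (VAR) and then updated with the observation
#' (Joseph-form covariance update). Items whose `retained` flag is `FALSE`
#' update the filter without contributing to the sum, so a removed
#' transition's end point still conditions what follows.
#'
#' @param model An [ou_params] or [var_params].
#' @param noise A [noise_params].
#' @param series An [esm_series].
#' @param plan A plan from [build_transition_plan()].
#' @return The marginal min-log-likelihood (scalar).
#' @export
kalman_marginal_nll <- function(model, noise, series, plan = NULL) {
  if (is.null(plan)) plan <- build_transition_plan(series)
  family <- if (inherits(model, "ou_params")) "ou" else "var"
  series_nll(family, model, series, plan, noise = noise)
}

# one latent propagation step; dt is hours (ou) or integer steps (var)
latent_propagate <- function(family, model, m, P, dt) {
  if (family == "ou") {
    E <- expm_neg(model$theta, dt)
    SigY <- ou_stationary(model)$cov
    Q <- SigY - E %*% SigY %*% t(E)
  } else {
    pred0 <- var_conditional(model, rep(0, model$d), as.integer(dt))
    # reuse the compounded matrices: mean map is x -> A^k x + csum c
    E <- attr_compound_A(model, as.integer(dt))
    Q <- pred0$cov
  }
  mu <- if (family == "ou") model$mu else var_stationary(model)$mean
  list(m = as.numeric(mu + E %*% (m - mu)),
       P = sym(E %*% P %*% t(E) + Q))
}

attr_compound_A <- function(model, steps) {
  Ak <- diag(model$d)
  for (j in seq_len(steps)) Ak <- Ak %*% model$transition
  Ak
}

# Reference R implementation of the filtered pass; returns the filter state
# after consuming every item of `plan` (used by prediction and in tests as
# the slow-path check against the C++ chain).
kalman_filter_pass <- function(family, model, noise, series, plan) {
  d <- model$d
  statp <- if (family == "ou") ou_stationary(model) else var_stationary(model)
  R <- diag(noise$error_var, d)
  m <- statp$mean
  P <- statp$cov
  nll <- 0
  for (k in seq_len(nrow(plan))) {
    if (plan$kind[k] == "stationary") {
      m <- statp$mean
      P <- statp$cov
    } else {
      dt <- if (family == "ou") plan$dt[k] else plan$steps[k]
      st <- latent_propagate(family, model, m, P, dt)
      m <- st$m
      P <- st$P
    }
    S <- sym(P + R)
    x <- series$ratings[plan$target[k], ]
    if (plan$retained[k])
      nll <- nll + gaussian_nll(x, list(mean = m, cov = S))
    Sj <- S
    diag(Sj) <- diag(Sj) + 1e-12 * (mean(diag(Sj)) + 1)
    K <- P %*% solve(Sj)
    m <- as.numeric(m + K %*% (x - m))
    IK <- diag(d) - K
    P <- sym(IK %*% P %*% t(IK) + K %*% R %*% t(K))
  }
  list(m = m, P = P, nll = nll, stationary = statp, R = R)
}

#' One-step-ahead predictive distribution from the Kalman filter
#'
#' Runs the filter over the items of `plan` (the series prefix) and returns
#' the predictive distribution of the next observation described by
#' `next_item`: latent propagation plus `diag(error_var)` for a transition,
#' or `Sigma_y + diag(error_var)` when the next observation opens a new
#' day. With `error_var = 0` this reduces to the error-free conditional.
#'
#' @param model An [ou_params] or [var_params].
#' @param noise A [noise_params].
#' @param series An [esm_series] containing the prefix observations.
#' @param plan Plan rows covering the prefix (may have zero rows for an
#'   empty filter history only when the next item is stationary).
#' @param next_item A one-row plan data frame describing the upcoming
#'   observation (`kind`, `source`, `dt`, `steps`).
#' @return A list with predictive `mean` and `cov`.
#' @export
kalman_predict_next <- function(model, noise, series, plan, next_item) {
  family <- if (inherits(model, "ou_params")) "ou" else "var"
  if (next_item$kind[1] == "stationary") {
    statp <- if (family == "ou") ou_stationary(model) else var_stationary(model)
    return(gaussian_prediction(statp$mean,
                               statp$cov + diag(noise$error_var, model$d)))
  }
  if (nrow(plan) < 1) stop("empty prefix before a transition item")
  st <- kalman_filter_pass(family, model, noise, series, plan)
  dt <- if (family == "ou") next_item$dt[1] else next_item$steps[1]
  pr <- latent_propagate(family, model, st$m, st$P, dt)
  gaussian_prediction(pr$m, pr$P + st$R)
}
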