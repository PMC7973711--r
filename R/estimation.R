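#' Differential evolution configuration
#'
#' DE/rand/1/bin with a fixed iteration budget: `np` agents, binomial
#' crossover probability `cr`, and the mutation weight `F` redrawn from
#' `U(0, 2)` for every mutation. The defaults (`np = 50`, `cr = 0.6`,
#' 3000 iterations) are the full estimation budget; walk-forward experiments
#' use a reduced budget via [de_config_fast()].
#'
#' @param np Population size (`>= 4`).
#' @param cr Crossover probability in `[0, 1]`.
#' @param iters Number of generations (`>= 1`).
#' @param seed Integer seed for the optimizer's random draws.
#' @param trace_every Record the best objective every this many generations.
#' @return A `de_config` list.
#' @export
de_config <- function(np = 50, cr = 0.6, iters = 3000, seed = 1,
                      trace_every = 100) {
  stopifnot(np >= 4, cr >= 0, cr <= 1, iters >= 1)
  structure(list(np = as.integer(np), cr = cr, iters = as.integer(iters),
                 seed = as.integer(seed), trace_every = as.integer(trace_every)),
            class = "de_config")
}

#' @rdname de_config
#' @export
de_config_fast <- function(np = 30, iters = 300, seed = 1)
  de_config(np = np, cr = 0.6, iters = iters, seed = seed, trace_every = 50)

#' Min-log-likelihood of a series under a fitted or fixed model
#'
#' Sums, over the retained items of the scoring plan, the negative log
#' density of each non-missing beep: the first beep of a day under the
#' model's stationary distribution, later beeps under the conditional
#' distribution given the previous non-missing beep (actual elapsed hours
#' for the OU family, pseudo-steps for the VAR family, i.i.d. stationary
#' scoring for the stationary family). With `noise` set, the whole sum is
#' the Kalman-filter marginal NLL instead (see [kalman_marginal_nll()]).
#' Unstable parameters yield `+Inf` rather than an error so that optimizers
#' can treat stability as a rejection constraint.
#'
#' @param family `"ou"`, `"var"` or `"stationary"`.
#' @param params Matching parameter object ([ou_params], [var_params] or
#'   [stationary_params]).
#' @param series An [esm_series].
#' @param plan A plan from [build_transition_plan()] (any timescale; the
#'   family picks its own time encoding).
#' @param noise Optional [noise_params] for the measurement-error variants.
#' @return The min-log-likelihood (scalar; `+Inf` when unstable).
#' @export
series_nll <- function(family = c("ou", "var", "stationary"), params, series,
                       plan = NULL, noise = NULL) {
  family <- match.arg(family)
  if (is.null(plan)) plan <- build_transition_plan(series)
  ev <- if (is.null(noise)) numeric(0) else noise$error_var
  if (family == "ou") {
    payload <- plan_payload(series, plan, "continuous")
    cpp_nll_ou(params$mu, params$theta, params$sigma, ev, payload)
  } else if (family == "var") {
    payload <- plan_payload(series, plan, "unit_step")
    cpp_nll_var(params$intercept, params$transition, params$innovation_cov,
                ev, payload)
  } else {
    if (!is.null(noise))
      stop("measurement error is not identifiable in the stationary family")
    payload <- plan_payload(series, plan, "continuous")
    cpp_nll_stationary(params$mean, params$cov, payload)
  }
}

# pooled (list-of-series) helpers --------------------------------------------

as_series_list <- function(series, plan) {
  if (inherits(series, "esm_series")) {
    series <- list(series)
    plan <- if (is.null(plan)) NULL else list(plan)
  }
  if (is.null(plan)) plan <- lapply(series, build_transition_plan)
  list(series = series, plan = plan)
}

# search bounds from the pooled observed ratings, per design:
# mu within the observed range widened by 50%, theta entries in [-10, 10]
# per hour, sigma lower triangle bounded by 3x the per-dimension SD
# (diagonal >= 0), error variances within the per-dimension variance
fit_bounds <- function(series_list, d, noise) {
  X <- do.call(rbind, lapply(series_list, function(s) {
    x <- s$ratings
    x[s$missing_mask] <- NA
    x
  }))
  lo <- hi <- NULL
  mu_lo <- mu_hi <- sd_d <- numeric(d)
  for (j in seq_len(d)) {
    v <- X[, j]
    v <- v[!is.na(v)]
    r <- diff(range(v))
    if (r <= 0) r <- max(abs(v), 1)
    mu_lo[j] <- min(v) - 0.5 * r
    mu_hi[j] <- max(v) + 0.5 * r
    sd_d[j] <- stats::sd(v)
    if (!is.finite(sd_d[j]) || sd_d[j] <= 0) sd_d[j] <- 1
  }
  B_theta <- 10
  lower <- c(mu_lo, rep(-B_theta, d * d))
  upper <- c(mu_hi, rep(B_theta, d * d))
  for (i in seq_len(d)) for (j in seq_len(i)) {
    b <- 3 * sd_d[i]
    lower <- c(lower, if (i == j) 0 else -b)
    upper <- c(upper, b)
  }
  if (noise) {
    lower <- c(lower, rep(0, d))
    upper <- c(upper, sd_d^2)
  }
  list(lower = lower, upper = upper)
}

# principal matrix logarithm via the eigendecomposition; NULL when no real
# principal log exists (zero or negative-real eigenvalue) or A is defective
logm_principal <- function(A) {
  out <- tryCatch({
    eg <- eigen(A)
    if (any(Mod(eg$values) < 1e-10)) return(NULL)
    if (any(Re(eg$values) < 0 & abs(Im(eg$values)) < 1e-12)) return(NULL)
    Re(eg$vectors %*% diag(log(eg$values), nrow(A)) %*% solve(eg$vectors))
  }, error = function(e) NULL)
  out
}

# Moment-based warm start for the DE population: OLS VAR(1) over the pooled
# single-step transitions, mapped to OU drift by the principal matrix log at
# the mean spacing; mu and Sigma_y from pooled sample moments; sigma from the
# Lyapunov relation sigma sigma' = theta Sigma_y + Sigma_y theta'. Returns
# numeric(0) when any step is unavailable (DE then starts fully random).
ou_moment_seed <- function(series_list, plan_list, timescale, noise, bounds) {
  d <- n_dims(series_list[[1]])
  Xp <- Xn <- NULL
  dts <- numeric(0)
  rows <- NULL
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    p <- plan_list[[i]]
    tr <- p[p$kind == "transition" & p$steps == 1 & p$retained, , drop = FALSE]
    if (nrow(tr)) {
      Xp <- rbind(Xp, s$ratings[tr$source, , drop = FALSE])
      Xn <- rbind(Xn, s$ratings[tr$target, , drop = FALSE])
      dts <- c(dts, tr$dt)
    }
    rows <- rbind(rows, s$ratings[p$target[p$retained], , drop = FALSE])
  }
  if (is.null(Xp) || nrow(Xp) < d + 2) return(numeric(0))
  dtbar <- if (timescale == "continuous") mean(dts) else 1
  seed <- tryCatch({
    mu0 <- colMeans(rows)
    SigY <- unname(stats::cov(rows))
    theta0 <- NULL
    Z <- cbind(1, Xp)
    coefs <- tryCatch(solve(crossprod(Z), crossprod(Z, Xn)),
                      error = function(e) NULL)
    if (!is.null(coefs)) {
      A <- unname(t(coefs[-1, , drop = FALSE]))
      L <- logm_principal(A)
      if (!is.null(L)) {
        cand <- -L / dtbar
        if (all(Re(eigen(cand, only.values = TRUE)$values) > 1e-6)) {
          theta0 <- cand
          mu_ols <- tryCatch(solve(diag(d) - A, unname(coefs[1, ])),
                             error = function(e) NULL)
          if (!is.null(mu_ols) && all(is.finite(mu_ols))) mu0 <- mu_ols
          resid <- Xn - Z %*% coefs
          Se <- unname(crossprod(resid) / nrow(resid))
          Sd <- tryCatch({
            K <- diag(d * d) - kronecker(A, A)
            sym(matrix(solve(K, as.numeric(Se)), d, d))
          }, error = function(e) NULL)
          if (!is.null(Sd) && all(eigen(Sd, symmetric = TRUE,
                                        only.values = TRUE)$values > 0))
            SigY <- Sd
        }
      }
    }
    # fallback: moderate diagonal relaxation, moments from the sample
    if (is.null(theta0)) theta0 <- diag(d) / dtbar
    Q <- sym(theta0 %*% SigY + SigY %*% t(theta0))
    eg <- eigen(Q, symmetric = TRUE)
    Q <- eg$vectors %*% diag(pmax(eg$values, 1e-6), d) %*% t(eg$vectors)
    sigma0 <- t(chol(sym(Q)))
    par <- c(mu0, as.numeric(t(theta0)))
    for (i in seq_len(d)) for (j in seq_len(i)) par <- c(par, sigma0[i, j])
    if (noise) par <- c(par, 0.05 * diag(SigY))
    pmin(pmax(unname(par), bounds$lower), bounds$upper)
  }, error = function(e) numeric(0))
  seed
}

decode_ou_par <- function(par, d, noise) {
  mu <- par[seq_len(d)]
  pos <- d
  theta <- matrix(par[pos + seq_len(d * d)], d, d, byrow = TRUE)
  pos <- pos + d * d
  sigma <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    pos <- pos + 1
    sigma[i, j] <- par[pos]
  }
  ev <- if (noise) par[pos + seq_len(d)] else NULL
  list(params = ou_params(mu, theta, sigma),
       noise = if (noise) noise_params(ev) else NULL)
}

#' Maximum-likelihood fit by differential evolution
#'
#' Minimizes the (marginal) min-log-likelihood over the family's parameter
#' space with DE/rand/1/bin; stability is enforced by assigning unstable
#' candidates an infinite objective. The VAR(1) family is fitted on the same
#' exponential-propagation machinery with the time intervals set to the
#' pseudo-step counts (so missed beeps compound automatically) and the
#' optimum mapped to `(c, A, Sigma_eps)` via the equal-spacing equivalence
#' at unit step. The stationary family has its exact MLE in closed form
#' (sample mean, 1/n covariance of the retained beeps), which is returned
#' directly.
#'
#' @param family `"ou"`, `"var"` or `"stationary"`.
#' @param series An [esm_series] or list of them (pooled fit).
#' @param plan Matching plan or list of plans (built if `NULL`).
#' @param de A [de_config].
#' @param noise Logical; fit the measurement-error variant (OU/VAR only).
#' @return A `fit_result` list: `family`, `noise` flag, `params` (family
#'   parameter object), `noise_params`, `ou_equivalent` (for the VAR
#'   family, the OU parameters it was fitted through), `train_nll`,
#'   `trace`, `de`.
#' @export
fit_mle <- function(family = c("ou", "var", "stationary"), series, plan = NULL,
                    de = de_config(), noise = FALSE) {
  family <- match.arg(family)
  sp <- as_series_list(series, plan)
  d <- n_dims(sp$series[[1]])
  n_retained <- sum(vapply(sp$plan, function(p) sum(p$retained), 0))
  if (n_retained < d + 2)
    stop("under-determined fit: fewer than d + 2 retained items")

  if (family == "stationary") {
    if (noise) stop("measurement error is not identifiable in the stationary family")
    rows <- do.call(rbind, Map(function(s, p) {
      s$ratings[p$target[p$retained], , drop = FALSE]
    }, sp$series, sp$plan))
    mu <- colMeans(rows)
    cen <- sweep(rows, 2, mu)
    Sig <- crossprod(cen) / nrow(rows)
    params <- stationary_params(mu, Sig)
    nll <- sum(mapply(function(s, p) series_nll("stationary", params, s, p),
                      sp$series, sp$plan))
    return(structure(list(family = family, noise = FALSE, params = params,
                          noise_params = NULL, ou_equivalent = NULL,
                          train_nll = nll, trace = nll, de = de),
                     class = "fit_result"))
  }

  timescale <- if (family == "ou") "continuous" else "unit_step"
  payloads <- Map(function(s, p) plan_payload(s, p, timescale),
                  sp$series, sp$plan)
  b <- fit_bounds(sp$series, d, noise)
  warm <- ou_moment_seed(sp$series, sp$plan, timescale, noise, b)
  set.seed(de$seed)
  res <- cpp_de_fit(unname(payloads), b$lower, b$upper, d, noise, de$np,
                    de$cr, de$iters, de$trace_every, warm)
  dec <- decode_ou_par(res$par, d, noise)
  if (family == "ou") {
    params <- dec$params
    ou_eq <- NULL
  } else {
    params <- ou_to_var(dec$params, 1)
    ou_eq <- dec$params
  }
  structure(list(family = family, noise = noise, params = params,
                 noise_params = dec$noise, ou_equivalent = ou_eq,
                 train_nll = res$value, trace = res$trace, de = de),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> family =", x$family,
      if (x$noise) "(+ measurement error)" else "",
      " train NLL =", format(x$train_nll, digits = 6), "\n")
  invisible(x)
}

#' Closed-form VAR(1) estimates
#'
#' Ordinary least squares of each beep on the previous beep over the
#' single-step transitions of the plan (stationary items and multi-step
#' pseudo-transitions are excluded); the innovation covariance is the
#' residual covariance with MLE normalization `1/n`. No stability
#' constraint is imposed, so the estimate can be explosive on short series;
#' it serves as an independent check on the DE optimizer.
#'
#' @param series An [esm_series].
#' @param plan A plan from [build_transition_plan()].
#' @return A [var_params] (its stability can be checked with
#'   [var_is_stable()]).
#' @export
var_closed_form <- function(series, plan = NULL) {
  if (is.null(plan)) plan <- build_transition_plan(series)
  tr <- plan[plan$kind == "transition" & plan$steps == 1 & plan$retained, ]
  d <- n_dims(series)
  if (nrow(tr) < d + 2) stop("too few single-step transitions for OLS")
  Xprev <- series$ratings[tr$source, , drop = FALSE]
  Xnext <- series$ratings[tr$target, , drop = FALSE]
  Z <- cbind(1, Xprev)
  coefs <- tryCatch(solve(crossprod(Z), crossprod(Z, Xnext)),
                    error = function(e) stop("singular design in var_closed_form"))
  intercept <- coefs[1, ]
  A <- t(coefs[-1, , drop = FALSE])
  resid <- Xnext - Z %*% coefs
  var_params(intercept, A, crossprod(resid) / nrow(resid))
}
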