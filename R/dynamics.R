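#' Ornstein-Uhlenbeck process parameters
#'
#' Parameters of the multivariate OU diffusion
#' `dy(t) = theta (mu - y(t)) dt + sigma dW(t)`: the attractor `mu`, the
#' drift matrix `theta` (stable when all eigenvalues have strictly positive
#' real part) and the lower-triangular diffusion factor `sigma` with
#' non-negative diagonal (the Wiener increments have covariance
#' `sigma %*% t(sigma)`; the triangular form with signed diagonal fixed
#' resolves the reflection non-identifiability of `sigma sigma^T`).
#'
#' @param mu Numeric length-d center.
#' @param theta d x d drift matrix.
#' @param sigma d x d lower-triangular diffusion matrix, diagonal `>= 0`.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(mu, theta, sigma) {
  mu <- as.numeric(mu)
  theta <- unname(as.matrix(theta))
  sigma <- unname(as.matrix(sigma))
  d <- length(mu)
  stopifnot(all(dim(theta) == d), all(dim(sigma) == d))
  if (any(abs(sigma[upper.tri(sigma)]) > 1e-12))
    stop("sigma must be lower triangular")
  if (any(diag(sigma) < 0))
    stop("sigma diagonal must be non-negative")
  structure(list(mu = mu, theta = theta, sigma = sigma, d = d),
            class = "ou_params")
}

#' VAR(1) model parameters
#'
#' Parameters of the lag-1 vector autoregression
#' `x_i = c + A x_{i-1} + eps_i` with Gaussian innovations of covariance
#' `innovation_cov`; stable when all eigenvalues of `A` lie strictly inside
#' the unit circle.
#'
#' @param intercept Numeric length-d intercept `c`.
#' @param transition d x d transition matrix `A`.
#' @param innovation_cov d x d symmetric PSD innovation covariance.
#' @return An object of class `var_params`.
#' @export
var_params <- function(intercept, transition, innovation_cov) {
  intercept <- as.numeric(intercept)
  transition <- unname(as.matrix(transition))
  innovation_cov <- unname(as.matrix(innovation_cov))
  d <- length(intercept)
  stopifnot(all(dim(transition) == d), all(dim(innovation_cov) == d))
  if (max(abs(innovation_cov - t(innovation_cov))) > 1e-8)
    stop("innovation_cov must be symmetric")
  structure(list(intercept = intercept, transition = transition,
                 innovation_cov = sym(innovation_cov), d = d),
            class = "var_params")
}

#' Stationary Gaussian parameters
#'
#' @param mean Numeric length-d mean.
#' @param cov d x d symmetric positive-definite covariance.
#' @return An object of class `stationary_params`.
#' @export
stationary_params <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- unname(as.matrix(cov))
  d <- length(mean)
  stopifnot(all(dim(cov) == d))
  if (max(abs(cov - t(cov))) > 1e-8) stop("cov must be symmetric")
  structure(list(mean = mean, cov = sym(cov), d = d),
            class = "stationary_params")
}

gaussian_prediction <- function(mean, cov) {
  list(mean = as.numeric(mean), cov = sym(as.matrix(cov)))
}

sym <- function(m) (m + t(m)) / 2

#' @rdname ou_params
#' @param p An `ou_params` object.
#' @export
ou_is_stable <- function(p) all(Re(eigen(p$theta, only.values = TRUE)$values) > 0)

#' @rdname var_params
#' @param p A `var_params` object.
#' @export
var_is_stable <- function(p) all(Mod(eigen(p$transition, only.values = TRUE)$values) < 1)

# e^{-theta dt}; closed forms for d = 1 and 2 (the 2x2 traceless split is
# exact for oscillatory drift too), Matrix::expm otherwise
expm_neg <- function(theta, dt) {
  d <- nrow(theta)
  if (d == 1L) return(matrix(exp(-theta[1, 1] * dt), 1, 1))
  if (d == 2L) {
    M <- -theta * dt
    s <- 0.5 * (M[1, 1] + M[2, 2])
    B <- M - s * diag(2)
    disc <- B[1, 1]^2 + B[1, 2] * B[2, 1]
    if (disc > 1e-24) {
      q <- sqrt(disc)
      E <- cosh(q) * diag(2) + sinh(q) / q * B
    } else if (disc < -1e-24) {
      q <- sqrt(-disc)
      E <- cos(q) * diag(2) + sin(q) / q * B
    } else {
      E <- diag(2) + B
    }
    return(exp(s) * E)
  }
  as.matrix(Matrix::expm(-theta * dt))
}

#' OU conditional distribution after an elapsed time
#'
#' Distribution of `y(t + dt)` given `y(t) = y_prev`:
#' mean `(I - e^{-theta dt}) mu + e^{-theta dt} y_prev` and covariance
#' `Sigma_y - e^{-theta dt} Sigma_y e^{-theta' dt}` with `Sigma_y` the
#' stationary covariance. At `dt = 0` this degenerates to a point mass; as
#' `dt -> Inf` it relaxes to the stationary distribution.
#'
#' @param p An [ou_params].
#' @param y_prev Length-d previous state.
#' @param dt Elapsed time in hours, `>= 0`.
#' @return A list with `mean` and `cov` (symmetrized).
#' @export
ou_conditional <- function(p, y_prev, dt) {
  if (!ou_is_stable(p)) stop("unstable OU drift matrix")
  stopifnot(dt >= 0)
  E <- expm_neg(p$theta, dt)
  SigY <- ou_stationary(p)$cov
  gaussian_prediction(p$mu + E %*% (as.numeric(y_prev) - p$mu),
                      SigY - E %*% SigY %*% t(E))
}

#' Stationary distribution of a stable OU process
#'
#' Solves the continuous Lyapunov equation
#' `theta Sigma_y + Sigma_y theta' = sigma sigma'` for the stationary
#' covariance.
#'
#' @param p An [ou_params].
#' @return A [stationary_params] with mean `mu` and covariance `Sigma_y`.
#' @export
ou_stationary <- function(p) {
  if (!ou_is_stable(p)) stop("unstable OU drift matrix")
  d <- p$d
  Q <- p$sigma %*% t(p$sigma)
  K <- kronecker(diag(d), p$theta) + kronecker(p$theta, diag(d))
  SigY <- matrix(solve(K, as.numeric(Q)), d, d)
  stationary_params(p$mu, sym(SigY))
}

#' VAR(1) conditional distribution after a number of steps
#'
#' Compounds the one-step recursion: mean
#' `A^k x_prev + (I + A + ... + A^{k-1}) c` and covariance
#' `sum_{j<k} A^j Sigma_eps A^j'`. Pseudo-step counts above 1 encode beeps
#' that were missed in between.
#'
#' @param p A [var_params].
#' @param x_prev Length-d previous observation.
#' @param steps Positive integer number of unit steps.
#' @return A list with `mean` and `cov`.
#' @export
var_conditional <- function(p, x_prev, steps) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  d <- p$d
  Ak <- diag(d)
  csum <- matrix(0, d, d)
  cov <- matrix(0, d, d)
  for (j in seq_len(steps)) {
    csum <- csum + Ak
    cov <- cov + Ak %*% p$innovation_cov %*% t(Ak)
    Ak <- Ak %*% p$transition
  }
  gaussian_prediction(Ak %*% as.numeric(x_prev) + csum %*% p$intercept, cov)
}

#' Stationary distribution of a stable VAR(1) model
#'
#' Mean `(I - A)^{-1} c`; covariance solves the discrete Lyapunov equation
#' `Sigma = A Sigma A' + Sigma_eps`.
#'
#' @param p A [var_params].
#' @return A [stationary_params].
#' @export
var_stationary <- function(p) {
  if (!var_is_stable(p)) stop("unstable VAR(1) process")
  d <- p$d
  mu <- solve(diag(d) - p$transition, p$intercept)
  K <- diag(d * d) - kronecker(p$transition, p$transition)
  Sig <- matrix(solve(K, as.numeric(p$innovation_cov)), d, d)
  stationary_params(mu, sym(Sig))
}

#' Map OU parameters to the equivalent VAR(1) at a fixed spacing
#'
#' For equally spaced observations `dt` apart, the OU process observed at
#' the beeps is exactly a VAR(1) with `A = e^{-theta dt}`,
#' `c = (I - A) mu`, and `Sigma_eps = Sigma_y - A Sigma_y A'`.
#'
#' @param p An [ou_params].
#' @param dt Spacing in hours, `> 0`.
#' @return A [var_params].
#' @export
ou_to_var <- function(p, dt) {
  if (!ou_is_stable(p)) stop("unstable OU drift matrix")
  stopifnot(dt > 0)
  A <- expm_neg(p$theta, dt)
  SigY <- ou_stationary(p)$cov
  var_params((diag(p$d) - A) %*% p$mu, A, SigY - A %*% SigY %*% t(A))
}

#' Gaussian negative log density
#'
#' `0.5 * (d log(2 pi) + log det(cov) + (x - mean)' cov^{-1} (x - mean))`,
#' with a relative jitter of `1e-10 * mean(diag(cov))` added to the diagonal
#' so that near-degenerate conditional covariances (`dt -> 0`) remain
#' invertible.
#'
#' @param x Length-d observation.
#' @param pred A list with `mean` and `cov` (as returned by the conditional
#'   and stationary operations).
#' @return The negative log density (scalar).
#' @export
gaussian_nll <- function(x, pred) {
  C <- sym(as.matrix(pred$cov))
  d <- nrow(C)
  jit <- 1e-10 * mean(diag(C))
  if (!is.finite(jit) || jit <= 0) jit <- 1e-12
  diag(C) <- diag(C) + jit
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) stop("singular covariance in gaussian_nll")
  e <- as.numeric(x) - pred$mean
  z <- backsolve(ch, e, transpose = TRUE)
  0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Count free parameters of a model family
#'
#' `mu` (d) plus drift/transition (d^2) plus the lower-triangular
#' diffusion or innovation factor (d(d+1)/2) for the dynamical families;
#' `mu` plus covariance factor for the stationary family; measurement-error
#' variants add d error variances.
#'
#' @param family `"ou"`, `"var"` or `"stationary"`.
#' @param d Dimension.
#' @param noise Logical, measurement-error variant?
#' @return Integer parameter count.
#' @export
param_count <- function(family = c("ou", "var", "stationary"), d, noise = FALSE) {
  family <- match.arg(family)
  k <- if (family == "stationary") d + d * (d + 1) / 2
       else d + d^2 + d * (d + 1) / 2
  as.integer(k + if (noise) d else 0L)
}

#' Serialize model parameters to JSON
#'
#' Matrices are written row-major with explicit dimension so that parameter
#' sets round-trip across tools.
#'
#' @param p An [ou_params], [var_params] or [stationary_params].
#' @param dim_names Optional dimension names stored alongside.
#' @return A JSON string.
#' @export
params_to_json <- function(p, dim_names = NULL) {
  fam <- class(p)[1]
  payload <- switch(fam,
    ou_params = list(family = "ou", d = p$d, mu = p$mu,
                     theta = as.numeric(t(p$theta)),
                     sigma = as.numeric(t(p$sigma))),
    var_params = list(family = "var", d = p$d, intercept = p$intercept,
                      transition = as.numeric(t(p$transition)),
                      innovation_cov = as.numeric(t(p$innovation_cov))),
    stationary_params = list(family = "stationary", d = p$d, mean = p$mean,
                             cov = as.numeric(t(p$cov))),
    stop("unknown parameter class"))
  if (!is.null(dim_names)) payload$dim_names <- dim_names
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @param json A JSON string produced by [params_to_json()].
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  d <- obj$d
  m <- function(v) matrix(v, d, d, byrow = TRUE)
  switch(obj$family,
         ou = ou_params(obj$mu, m(obj$theta), m(obj$sigma)),
         var = var_params(obj$intercept, m(obj$transition), m(obj$innovation_cov)),
         stationary = stationary_params(obj$mean, m(obj$cov)),
         stop("unknown family in JSON"))
}
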