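#' Synthetic ESM study configuration
#'
#' Defines the conditions of a simulated experience-sampling study: 7 days
#' of 10 beeps between 10:00 and 22:00 sampled by a stratified random
#' interval scheme (one beep uniform in each of 10 equal 72-minute strata,
#' so beeps arrive every 72 minutes on average), latent bivariate OU affect
#' dynamics on a 0-100 rating scale, optional diagonal Gaussian measurement
#' error, optional event-driven latent jumps that subsequently relax under
#' the OU dynamics, and beep-level missingness matching the ~87% compliance
#' typical of ESM protocols.
#'
#' @param n_series Number of series (participants) to generate.
#' @param days Days per series (default 7).
#' @param beeps_per_day Beeps per day (default 10).
#' @param day_window Daily sampling window in hours (default `c(10, 22)`).
#' @param ou Latent [ou_params]; the default is a stable bivariate PA/NA
#'   process with cross-coupling
#'   (`theta = [[1, 0.3], [-0.2, 0.8]]` per hour, `mu = (60, 20)`,
#'   `sigma = diag(8, 6)` rating units per sqrt hour).
#' @param noise [noise_params] of the measurement error (default: none).
#' @param event_rate Expected number of external-event jumps per series
#'   (Poisson; default 0).
#' @param event_scale Length-d SDs of the Gaussian latent jumps; default
#'   `4 * diag(sigma)`, i.e. jumps well outside the typical hourly
#'   fluctuation.
#' @param missing_rate Per-beep missingness probability (default 0.13).
#' @param clip_to_scale Clip observed ratings to `[0, 100]`? Off by default
#'   because clipping breaks the Gaussian assumptions model-recovery tests
#'   rely on; switch on for realism demonstrations.
#' @param seed Integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_series,
                         days = 7,
                         beeps_per_day = 10,
                         day_window = c(10, 22),
                         ou = ou_params(c(60, 20),
                                        matrix(c(1.0, 0.3, -0.2, 0.8), 2, 2,
                                               byrow = TRUE),
                                        diag(c(8, 6))),
                         noise = noise_params(rep(0, length(ou$mu))),
                         event_rate = 0,
                         event_scale = 4 * diag(ou$sigma),
                         missing_rate = 0.13,
                         clip_to_scale = FALSE,
                         seed = 1) {
  stopifnot(n_series >= 1, days >= 1, beeps_per_day >= 1,
            length(day_window) == 2, day_window[2] > day_window[1],
            missing_rate >= 0, missing_rate < 1, event_rate >= 0)
  if (!ou_is_stable(ou)) stop("latent OU parameters must be stable")
  structure(list(n_series = as.integer(n_series), days = as.integer(days),
                 beeps_per_day = as.integer(beeps_per_day),
                 day_window = as.numeric(day_window), ou = ou, noise = noise,
                 event_rate = event_rate, event_scale = as.numeric(event_scale),
                 missing_rate = missing_rate, clip_to_scale = clip_to_scale,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Sample a stratified random beep schedule
#'
#' Each day's window is split into `beeps_per_day` equal strata and one
#' beep is drawn uniformly within each stratum, giving strictly increasing
#' within-day times with the nominal mean inter-beep interval
#' (72 minutes at the defaults). Uses the current RNG state.
#'
#' @param config A [study_config].
#' @return A list with `timestamps` (hours since study start) and
#'   `day_index`.
#' @export
sample_schedule <- function(config) {
  nb <- config$beeps_per_day
  w <- config$day_window
  width <- (w[2] - w[1]) / nb
  ts <- numeric(0)
  day <- integer(0)
  for (dd in seq_len(config$days)) {
    offsets <- w[1] + (seq_len(nb) - 1) * width + stats::runif(nb) * width
    ts <- c(ts, 24 * (dd - 1) + offsets)
    day <- c(day, rep(dd, nb))
  }
  list(timestamps = ts, day_index = day)
}

#' Simulate a latent OU path over a beep schedule
#'
#' The first beep of each day is drawn from the stationary distribution
#' (the process is assumed to relax completely overnight, mirroring the
#' scoring convention); each later beep is drawn exactly from the OU
#' conditional at the actual elapsed time. Each external event adds an
#' independent Gaussian jump (per-dimension SDs `event_scale`) to the
#' latent state at a uniformly chosen beep; the jumped state then relaxes
#' under the same dynamics.
#'
#' @param ou Latent [ou_params].
#' @param timestamps,day_index Schedule from [sample_schedule()].
#' @param n_events Number of events to inject.
#' @param event_scale Length-d jump SDs.
#' @return A `latent_path` list: `timestamps`, `day_index`, `latent`
#'   (N x d), `event_beeps`, `event_jumps`.
#' @export
simulate_latent <- function(ou, timestamps, day_index, n_events = 0,
                            event_scale = NULL) {
  if (!ou_is_stable(ou)) stop("latent OU parameters must be stable")
  d <- ou$d
  n <- length(timestamps)
  statp <- ou_stationary(ou)
  L_stat <- chol_psd(statp$cov)
  y <- matrix(NA_real_, n, d)
  event_beeps <- if (n_events > 0) sample.int(n, n_events, replace = TRUE) else integer(0)
  event_jumps <- matrix(0, length(event_beeps), d)
  state <- NULL
  for (i in seq_len(n)) {
    new_day <- i == 1 || day_index[i] != day_index[i - 1]
    if (new_day) {
      state <- statp$mean + as.numeric(L_stat %*% stats::rnorm(d))
    } else {
      pred <- ou_conditional(ou, state, timestamps[i] - timestamps[i - 1])
      state <- pred$mean + as.numeric(chol_psd(pred$cov) %*% stats::rnorm(d))
    }
    hits <- which(event_beeps == i)
    for (h in hits) {
      jump <- stats::rnorm(d) * event_scale
      event_jumps[h, ] <- jump
      state <- state + jump
    }
    y[i, ] <- state
  }
  list(timestamps = timestamps, day_index = day_index, latent = y,
       event_beeps = event_beeps, event_jumps = event_jumps)
}

chol_psd <- function(C) {
  C <- sym(C)
  out <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (is.null(out)) {
    eg <- eigen(C, symmetric = TRUE)
    out <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(C))
  }
  out
}

#' Observe a latent path
#'
#' Adds independent Gaussian measurement error per dimension, marks beeps
#' missing independently at `missing_rate` (non-compliance), and optionally
#' clips the observed ratings to the 0-100 scale.
#'
#' @param path A `latent_path` from [simulate_latent()].
#' @param noise A [noise_params].
#' @param missing_rate Per-beep missingness probability.
#' @param clip_to_scale Clip to `[0, 100]`?
#' @param series_id Identifier for the resulting series.
#' @param dim_names Dimension names (default `PA`, `NA` for d = 2).
#' @return An [esm_series].
#' @export
observe <- function(path, noise, missing_rate = 0, clip_to_scale = FALSE,
                    series_id = "sim", dim_names = NULL) {
  y <- path$latent
  n <- nrow(y)
  d <- ncol(y)
  if (is.null(dim_names))
    dim_names <- if (d == 2) c("PA", "NA") else paste0("V", seq_len(d))
  err <- matrix(stats::rnorm(n * d), n, d) %*% diag(sqrt(noise$error_var), d)
  x <- y + err
  if (clip_to_scale) x <- pmin(pmax(x, 0), 100)
  miss_beep <- stats::runif(n) < missing_rate
  mask <- matrix(miss_beep, n, d)
  x[mask] <- NA
  esm_series(series_id, path$timestamps, path$day_index, x,
             missing_mask = mask, dim_names = dim_names)
}

#' Generate a full synthetic ESM study
#'
#' Composes [sample_schedule()], [simulate_latent()] and [observe()] per
#' series under the configured seed, and returns the ground truth (latent
#' paths, event times and magnitudes, generating parameters) alongside the
#' observed series for recovery tests.
#'
#' @param config A [study_config].
#' @return A list with `series` (list of [esm_series]) and `truth`
#'   (generating `ou`/`noise` parameters and one entry of latent path +
#'   events per series).
#' @export
generate_study <- function(config) {
  set.seed(config$seed)
  series <- vector("list", config$n_series)
  paths <- vector("list", config$n_series)
  for (i in seq_len(config$n_series)) {
    sched <- sample_schedule(config)
    n_events <- stats::rpois(1, config$event_rate)
    path <- simulate_latent(config$ou, sched$timestamps, sched$day_index,
                            n_events, config$event_scale)
    series[[i]] <- observe(path, config$noise, config$missing_rate,
                           config$clip_to_scale,
                           series_id = sprintf("sim%03d", i))
    paths[[i]] <- path
  }
  names(series) <- vapply(series, function(s) s$series_id, "")
  list(series = series,
       truth = list(ou = config$ou, noise = config$noise,
                    event_rate = config$event_rate,
                    event_scale = config$event_scale, paths = paths))
}
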