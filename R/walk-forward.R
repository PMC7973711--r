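#' Truncate a series to its first m beeps
#'
#' @param series An [esm_series].
#' @param m Number of leading beeps to keep (missing beeps count).
#' @return An [esm_series] with `m` beeps.
#' @export
truncate_series <- function(series, m) {
  stopifnot(m >= 1, m <= n_beeps(series))
  idx <- seq_len(m)
  esm_series(series$series_id, series$timestamps[idx], series$day_index[idx],
             series$ratings[idx, , drop = FALSE],
             series$missing_mask[idx, , drop = FALSE], series$dim_names)
}

# predictive item for beep i_test: the row of the plan built on the series
# truncated just after the test beep
test_item <- function(series, i_test) {
  trunc <- truncate_series(series, i_test)
  plan <- build_transition_plan(trunc)
  plan[plan$target == i_test, , drop = FALSE]
}

# one-step predictive NLL of beep i_test under a fitted model
score_test_point <- function(fit, series, i_test) {
  item <- test_item(series, i_test)
  if (nrow(item) != 1) stop("test beep is missing")
  x <- series$ratings[i_test, ]
  if (fit$noise) {
    trunc <- truncate_series(series, i_test)
    prefix <- build_transition_plan(truncate_series(series, max(1, i_test - 1)))
    pred <- kalman_predict_next(fit$params, fit$noise_params, trunc, prefix, item)
    return(gaussian_nll(x, pred))
  }
  pred <- if (item$kind == "stationary") {
    switch(fit$family,
           ou = ou_stationary(fit$params),
           var = var_stationary(fit$params),
           stationary = fit$params)
  } else {
    switch(fit$family,
           ou = ou_conditional(fit$params, series$ratings[item$source, ], item$dt),
           var = var_conditional(fit$params, series$ratings[item$source, ], item$steps),
           stationary = fit$params)
  }
  if (fit$family == "stationary")
    pred <- list(mean = pred$mean, cov = pred$cov)
  gaussian_nll(x, pred)
}

#' Walk-forward out-of-sample cross-validation of one series
#'
#' For each fold `n = 1..folds`: train on the first `N - n` beeps (beeps,
#' not transitions — missed beeps count toward `N`), remove large
#' deviations from the training transitions at cutoff `C` (speeds,
#' normalization SDs, median and MAD are all computed on the training
#' portion only, so nothing leaks from the test point), fit the family by
#' differential evolution (per-fold refit with a fold-specific seed), and
#' score the `(N - n + 1)`-th beep under the fitted one-step predictive
#' density — the conditional given the last training observation at its
#' actual elapsed time / pseudo-steps, the stationary density when the test
#' beep opens a new day, or the Kalman predictive when measurement error is
#' on. A missing test beep drops its fold.
#'
#' @param series An [esm_series].
#' @param family `"ou"`, `"var"` or `"stationary"`.
#' @param de A [de_config]; `de$seed + fold` seeds each fold's fit.
#' @param cutoff MAD cutoff `C` (`Inf` = no removal).
#' @param noise Logical: fit the measurement-error variant.
#' @param folds Number of folds (default 10).
#' @return A `cv_record` list: `series_id`, `family`, `cutoff`,
#'   `fold_nll` (length `folds`, `NA` for dropped folds), `mean_pred_nll`,
#'   `n_folds_valid`, `removed_fraction` (mean share of training
#'   transitions removed).
#' @export
walk_forward_cv <- function(series, family = c("ou", "var", "stationary"),
                            de = de_config_fast(), cutoff = Inf,
                            noise = FALSE, folds = 10) {
  family <- match.arg(family)
  N <- n_beeps(series)
  d <- n_dims(series)
  if (N - folds < d + 2)
    stop("series too short for ", folds, "-fold walk-forward CV")
  fold_nll <- rep(NA_real_, folds)
  removed <- rep(NA_real_, folds)
  for (n in seq_len(folds)) {
    i_test <- N - n + 1
    if (fully_missing(series)[i_test]) next
    train <- truncate_series(series, N - n)
    plan <- build_transition_plan(train)
    flt <- filter_plan(train, plan, cutoff)
    removed[n] <- flt$removed_fraction
    de_fold <- de
    de_fold$seed <- de$seed + n
    fit <- fit_mle(family, train, flt$plan, de_fold, noise)
    fold_nll[n] <- score_test_point(fit, series, i_test)
  }
  cv_record(series$series_id, family, cutoff, fold_nll, removed)
}

cv_record <- function(series_id, family, cutoff, fold_nll, removed) {
  valid <- !is.na(fold_nll)
  structure(list(series_id = series_id, family = family, cutoff = cutoff,
                 fold_nll = fold_nll,
                 mean_pred_nll = mean(fold_nll[valid]),
                 n_folds_valid = sum(valid),
                 removed_fraction = mean(removed, na.rm = TRUE)),
            class = "cv_record")
}

#' Run walk-forward CV for a whole study
#'
#' Batch driver over series, model families and a cutoff grid. Per series
#' and fold, the training plan and speed statistics are computed once and
#' shared; fits are cached across cutoffs that remove the same transition
#' set (lowering `C` often flags no additional transition, in which case
#' the training likelihood — and hence the fit — is identical).
#'
#' @param series A list of [esm_series].
#' @param families Character vector of families to fit.
#' @param cutoffs Numeric vector of MAD cutoffs (may include `Inf`).
#' @param de A [de_config] (use [de_config_fast()] for grids).
#' @param noise Logical: measurement-error variants for the OU and VAR
#'   families (the stationary family is always plain).
#' @param folds Folds per series.
#' @param progress Print one line per series?
#' @return A data frame with one row per (series, family, cutoff):
#'   `series_id`, `family`, `cutoff`, `mean_pred_nll`, `n_folds_valid`,
#'   `removed_fraction`.
#' @export
run_cv_study <- function(series, families = c("ou", "var", "stationary"),
                         cutoffs = Inf, de = de_config_fast(), noise = FALSE,
                         folds = 10, progress = FALSE) {
  rows <- list()
  for (s in series) {
    N <- n_beeps(s)
    acc <- list()
    for (fam in families)
      for (C in cutoffs)
        acc[[paste(fam, C)]] <- list(nll = rep(NA_real_, folds),
                                     rem = rep(NA_real_, folds))
    for (n in seq_len(folds)) {
      i_test <- N - n + 1
      if (fully_missing(s)[i_test]) next
      train <- truncate_series(s, N - n)
      plan <- build_transition_plan(train)
      sp <- compute_speeds(train, plan)
      fit_cache <- new.env(parent = emptyenv())
      for (C in cutoffs) {
        mask <- mad_mask(sp, C)
        plan_C <- apply_filter(plan, mask)
        key_C <- paste(which(!mask), collapse = ",")
        for (fam in families) {
          fam_noise <- noise && fam != "stationary"
          key <- paste(fam, fam_noise, key_C, sep = "|")
          fit <- fit_cache[[key]]
          if (is.null(fit)) {
            de_fold <- de
            de_fold$seed <- de$seed + n
            fit <- fit_mle(fam, train, plan_C, de_fold, fam_noise)
            fit_cache[[key]] <- fit
          }
          a <- acc[[paste(fam, C)]]
          a$nll[n] <- score_test_point(fit, s, i_test)
          a$rem[n] <- mean(!mask)
          acc[[paste(fam, C)]] <- a
        }
      }
    }
    for (fam in families) for (C in cutoffs) {
      a <- acc[[paste(fam, C)]]
      rec <- cv_record(s$series_id, fam, C, a$nll, a$rem)
      rows[[length(rows) + 1]] <- data.frame(
        series_id = rec$series_id, family = rec$family, cutoff = rec$cutoff,
        mean_pred_nll = rec$mean_pred_nll, n_folds_valid = rec$n_folds_valid,
        removed_fraction = rec$removed_fraction, stringsAsFactors = FALSE)
    }
    if (progress)
      message("cv done: ", s$series_id)
  }
  do.call(rbind, rows)
}
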