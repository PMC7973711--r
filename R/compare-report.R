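#' Fraction of series one model predicts better than another
#'
#' Pairs the two record sets by `series_id` and reports the fraction of
#' series where model A has the strictly lower mean predicted
#' min-log-likelihood. Exact ties (absolute difference below `1e-12`) are
#' excluded from both numerator and denominator; when every pair ties the
#' result is `NaN` with a warning.
#'
#' @param records_a,records_b Data frames with columns `series_id` and
#'   `mean_pred_nll` (e.g. subsets of [run_cv_study()] output).
#' @return The win fraction of A over B (scalar in `[0, 1]`, or `NaN`).
#' @export
win_fraction <- function(records_a, records_b) {
  if (nrow(records_a) != nrow(records_b) ||
      !setequal(records_a$series_id, records_b$series_id) ||
      anyDuplicated(records_a$series_id) || anyDuplicated(records_b$series_id))
    stop("records are not paired one-to-one by series_id")
  b <- records_b[match(records_a$series_id, records_b$series_id), ]
  diff <- records_a$mean_pred_nll - b$mean_pred_nll
  tie <- abs(diff) < 1e-12
  if (all(tie)) {
    warning("all series tie; win fraction undefined")
    return(NaN)
  }
  mean(diff[!tie] < 0)
}

#' Akaike information criterion from a min-log-likelihood
#'
#' `AIC = 2k + 2 * NLL` with `k` the number of free parameters (see
#' [param_count()]).
#'
#' @param train_nll Min-log-likelihood at the optimum.
#' @param k Number of free parameters, `>= 0`.
#' @return The AIC value.
#' @export
aic <- function(train_nll, k) {
  stopifnot(k >= 0)
  2 * k + 2 * train_nll
}

#' Win-percentage curves over a cutoff grid
#'
#' Aggregates walk-forward CV records into one row per cutoff: the win
#' fraction of OU over VAR, of each dynamical model over the stationary
#' model, the OU-over-VAR fraction restricted to the series where at least
#' one dynamical model beats the stationary model at that cutoff, the mean
#' fraction of training transitions removed, and the number of series.
#'
#' @param records Output of [run_cv_study()] covering the families
#'   `ou`, `var`, `stationary` on every cutoff of the grid.
#' @param cutoffs Cutoff grid; defaults to the distinct cutoffs present,
#'   sorted from `Inf` downwards.
#' @return A `comparison_curve` data frame with columns `cutoff`,
#'   `ou_vs_var`, `ou_vs_stationary`, `var_vs_stationary`,
#'   `ou_vs_var_dynamic`, `removed_fraction`, `n_series`.
#' @export
build_curve <- function(records, cutoffs = NULL) {
  if (is.null(cutoffs))
    cutoffs <- sort(unique(records$cutoff), decreasing = TRUE)
  rows <- lapply(cutoffs, function(C) {
    at <- records[records$cutoff == C, ]
    get_fam <- function(fam) at[at$family == fam, ]
    ou <- get_fam("ou")
    va <- get_fam("var")
    st <- get_fam("stationary")
    if (!nrow(ou) || !nrow(va) || !nrow(st))
      stop("missing family records at cutoff ", C)
    ids <- sort(unique(at$series_id))
    for (f in list(ou, va, st))
      if (!setequal(f$series_id, ids))
        stop("incomplete series coverage at cutoff ", C, ": ",
             paste(setdiff(ids, f$series_id), collapse = ", "))
    stm <- st[match(ids, st$series_id), "mean_pred_nll"]
    oum <- ou[match(ids, ou$series_id), "mean_pred_nll"]
    vam <- va[match(ids, va$series_id), "mean_pred_nll"]
    dyn <- ids[oum < stm | vam < stm]
    ou_vs_var_dyn <- if (length(dyn) >= 1)
      win_fraction(ou[ou$series_id %in% dyn, ], va[va$series_id %in% dyn, ])
    else NaN
    data.frame(cutoff = C,
               ou_vs_var = win_fraction(ou, va),
               ou_vs_stationary = win_fraction(ou, st),
               var_vs_stationary = win_fraction(va, st),
               ou_vs_var_dynamic = ou_vs_var_dyn,
               removed_fraction = mean(at$removed_fraction),
               n_series = length(ids))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_curve", "data.frame")
  out
}

#' Write and read a comparison curve as CSV
#'
#' `Inf` cutoffs survive the round trip (written as `Inf`).
#'
#' @param curve A `comparison_curve` from [build_curve()].
#' @param path File path.
#' @return `path` (write) / the curve (read).
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  class(out) <- c("comparison_curve", "data.frame")
  out
}
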