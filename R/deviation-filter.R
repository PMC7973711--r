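#' Normalized change speeds of a series
#'
#' For every transition item of the plan, the speed
#' `v = (1/dt) * sqrt(sum_j ((x_next_j - x_prev_j) / s_j)^2)` — the
#' Euclidean displacement of the SD-normalized ratings divided by the
#' elapsed time in hours. Normalizing by the per-dimension sample standard
#' deviation `s_j` makes the speed invariant to rescaling any dimension.
#' Overnight gaps are stationary items, not transitions, and get no speed.
#'
#' @param series An [esm_series].
#' @param plan A plan from [build_transition_plan()]; must contain at least
#'   one transition item.
#' @param sd_scope Optional numeric vector of per-dimension SDs to normalize
#'   by (e.g. computed on a training subset); defaults to the sample SD of
#'   the non-missing observations of `series`.
#' @return A `speed_series` list: `speeds`, `median_speed`, `mad` (unscaled
#'   median absolute deviation), `transition_rows` (row numbers of the plan).
#' @export
compute_speeds <- function(series, plan = NULL, sd_scope = NULL) {
  if (is.null(plan)) plan <- build_transition_plan(series)
  tr_rows <- which(plan$kind == "transition")
  if (!length(tr_rows)) stop("plan has no transition items")
  if (is.null(sd_scope)) {
    x <- series$ratings
    x[series$missing_mask] <- NA
    sd_scope <- apply(x, 2, stats::sd, na.rm = TRUE)
  }
  if (any(!is.finite(sd_scope) | sd_scope <= 0))
    stop("degenerate (constant) dimension: sample SD is zero")
  sp <- vapply(tr_rows, function(k) {
    dx <- (series$ratings[plan$target[k], ] - series$ratings[plan$source[k], ]) / sd_scope
    sqrt(sum(dx^2)) / plan$dt[k]
  }, 0)
  med <- stats::median(sp)
  structure(list(speeds = sp, median_speed = med,
                 mad = stats::median(abs(sp - med)),
                 transition_rows = tr_rows),
            class = "speed_series")
}

#' Retention mask from the median + C * MAD rule
#'
#' A transition is removed when its speed exceeds
#' `median(speeds) + C * MAD(speeds)` (strict `>`), with the MAD unscaled
#' (no normal-consistency factor). `C = Inf` retains everything; when the
#' MAD is zero nothing exceeds the threshold and everything is retained.
#'
#' @param speeds A `speed_series` from [compute_speeds()] or a bare numeric
#'   vector of speeds.
#' @param C Positive cutoff, or `Inf` for no removal.
#' @return Logical vector, `TRUE` for retained transitions.
#' @export
mad_mask <- function(speeds, C) {
  if (inherits(speeds, "speed_series")) speeds <- speeds$speeds
  stopifnot(length(speeds) >= 1, C > 0)
  if (is.infinite(C)) return(rep(TRUE, length(speeds)))
  med <- stats::median(speeds)
  speeds <= med + C * stats::median(abs(speeds - med))
}

#' Apply a retention mask to a plan
#'
#' Flags the masked-out transitions as not retained: they drop out of every
#' likelihood sum, but the flagged transition's end point remains the source
#' of the following transition (the chain is not re-linked), and stationary
#' items are untouched.
#'
#' @param plan A plan from [build_transition_plan()].
#' @param retained_mask Logical vector aligned with the plan's transition
#'   items in order.
#' @return The plan with updated `retained` flags.
#' @export
apply_filter <- function(plan, retained_mask) {
  tr_rows <- which(plan$kind == "transition")
  if (length(retained_mask) != length(tr_rows))
    stop("retention mask is not aligned with the plan's transitions")
  plan$retained[tr_rows] <- plan$retained[tr_rows] & retained_mask
  plan
}

#' Filter a plan at a MAD cutoff
#'
#' Convenience wrapper: computes speeds, thresholds at `C`, applies the
#' mask, and reports the removed fraction.
#'
#' @inheritParams compute_speeds
#' @param C Positive cutoff or `Inf`.
#' @return A list with the filtered `plan`, the `speed_series`, and
#'   `removed_fraction` (share of transitions flagged).
#' @export
filter_plan <- function(series, plan, C, sd_scope = NULL) {
  if (is.infinite(C)) {
    return(list(plan = plan, speeds = NULL, removed_fraction = 0))
  }
  sp <- compute_speeds(series, plan, sd_scope)
  mask <- mad_mask(sp, C)
  list(plan = apply_filter(plan, mask), speeds = sp,
       removed_fraction = mean(!mask))
}
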