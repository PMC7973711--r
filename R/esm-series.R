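#' ESM time series
#'
#' Container for one person's timestamped multivariate experience-sampling
#' series: strictly increasing timestamps in hours since the start of the
#' study, a day index per beep, an N x d matrix of affect ratings on the
#' original 0-100 scale (or standardized), and a missing-value mask.
#'
#' @param series_id Character scalar identifying the series.
#' @param timestamps Numeric vector of measurement times in hours, strictly
#'   increasing.
#' @param day_index Integer vector, non-decreasing, one entry per beep.
#' @param ratings Numeric N x d matrix of ratings; entries under a `TRUE`
#'   missing mask are ignored (conventionally `NA`).
#' @param missing_mask Logical N x d matrix, `TRUE` where the rating is
#'   missing. Defaults to `is.na(ratings)`.
#' @param dim_names Character vector of d dimension names.
#' @return An object of class `esm_series`.
#' @export
esm_series <- function(series_id, timestamps, day_index, ratings,
                       missing_mask = NULL, dim_names = NULL) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  d <- ncol(ratings)
  if (is.null(missing_mask)) missing_mask <- is.na(ratings)
  missing_mask <- as.matrix(missing_mask)
  if (is.null(dim_names)) {
    dim_names <- colnames(ratings)
    if (is.null(dim_names)) dim_names <- paste0("V", seq_len(d))
  }
  if (length(timestamps) != n || length(day_index) != n)
    stop("timestamps, day_index and ratings disagree in length for series '",
         series_id, "'")
  if (n >= 2 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing in series '", series_id, "'")
  if (n >= 2 && any(diff(day_index) < 0))
    stop("day_index must be non-decreasing in series '", series_id, "'")
  if (!all(dim(missing_mask) == c(n, d)))
    stop("missing_mask dimensions disagree with ratings in series '",
         series_id, "'")
  if (any(!is.finite(ratings[!missing_mask])))
    stop("non-finite rating where missing_mask is FALSE in series '",
         series_id, "'")
  colnames(ratings) <- dim_names
  dimnames(missing_mask) <- list(NULL, dim_names)
  structure(
    list(series_id = as.character(series_id),
         timestamps = as.numeric(timestamps),
         day_index = as.integer(day_index),
         ratings = ratings,
         missing_mask = missing_mask,
         dim_names = dim_names),
    class = "esm_series")
}

#' @export
print.esm_series <- function(x, ...) {
  cat("<esm_series> ", x$series_id, ": ", nrow(x$ratings), " beeps x ",
      length(x$dim_names), " dims (", paste(x$dim_names, collapse = ", "),
      "), days ", min(x$day_index), "-", max(x$day_index), ", ",
      sum(fully_missing(x)), " fully-missing beeps\n", sep = "")
  invisible(x)
}

n_beeps <- function(series) nrow(series$ratings)

n_dims <- function(series) ncol(series$ratings)

# a beep with any missing dimension is treated as fully missing: the model
# likelihoods are joint over all d dimensions
fully_missing <- function(series) apply(series$missing_mask, 1L, any)

#' Read ESM series from a delimited text file
#'
#' Expects a CSV with a header and one row per beep. Timestamps are accepted
#' either as decimal hours (numeric column) or as ISO 8601 datetimes, which
#' are converted to hours since 00:00 of the series' first day. The day
#' index is taken from an explicit day column when mapped, else derived from
#' the calendar date (or `floor(hours / 24) + 1` for numeric time). Missing
#' ratings are empty cells or `NA`.
#'
#' @param path Path to the CSV file.
#' @param schema Named list mapping roles to column names:
#'   `series_id`, `time`, `day` (optional), `items` (character vector of
#'   rating columns). Defaults to `series_id`, `t_hours`/`datetime`, `day`,
#'   and all remaining columns as items.
#' @return A named list of [esm_series], one per distinct series id.
#' @export
read_esm_csv <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(schema)) schema <- list()
  id_col <- schema$series_id %||% "series_id"
  time_col <- schema$time %||%
    (if ("t_hours" %in% names(df)) "t_hours" else "datetime")
  day_col <- schema$day %||% (if ("day" %in% names(df)) "day" else NULL)
  if (!id_col %in% names(df))
    stop("column '", id_col, "' not found in ", path)
  if (!time_col %in% names(df))
    stop("time column '", time_col, "' not found in ", path)
  item_cols <- schema$items %||%
    setdiff(names(df), c(id_col, time_col, day_col))
  unknown <- setdiff(item_cols, names(df))
  if (length(unknown))
    stop("unknown rating columns: ", paste(unknown, collapse = ", "))
  if (!length(item_cols)) stop("no rating columns identified")

  split_idx <- split(seq_len(nrow(df)), df[[id_col]])
  out <- lapply(names(split_idx), function(id) {
    rows <- df[split_idx[[id]], , drop = FALSE]
    tv <- rows[[time_col]]
    if (is.numeric(tv)) {
      hours <- as.numeric(tv)
      day <- if (!is.null(day_col)) as.integer(rows[[day_col]]) else
        as.integer(floor(hours / 24) + 1)
    } else {
      tt <- as.POSIXct(tv, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                      "%Y-%m-%d %H:%M"))
      if (any(is.na(tt)))
        stop("unparseable datetime in series '", id, "'")
      origin <- as.POSIXct(format(min(tt), "%Y-%m-%d"), tz = "UTC")
      hours <- as.numeric(difftime(tt, origin, units = "hours"))
      day <- if (!is.null(day_col)) as.integer(rows[[day_col]]) else
        as.integer(floor(hours / 24) + 1)
    }
    ord <- order(hours)
    hours <- hours[ord]
    day <- day[ord]
    if (anyDuplicated(hours) || any(diff(hours) <= 0))
      stop("non-monotone or duplicated timestamps in series '", id, "'")
    ratings <- as.matrix(rows[ord, item_cols, drop = FALSE])
    storage.mode(ratings) <- "double"
    esm_series(id, hours, day, ratings, dim_names = item_cols)
  })
  names(out) <- names(split_idx)
  out
}

#' Write ESM series to CSV
#'
#' Inverse of [read_esm_csv()] for the decimal-hours dialect; missing
#' ratings become empty cells.
#'
#' @param series A single [esm_series] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esm_csv <- function(series, path) {
  if (inherits(series, "esm_series")) series <- list(series)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)   # shortest round-trip-safe decimal
    out[is.na(v)] <- ""
    out
  }
  rows <- lapply(series, function(s) {
    ratings <- s$ratings
    ratings[s$missing_mask] <- NA
    df <- data.frame(series_id = s$series_id, t_hours = fmt(s$timestamps),
                     day = s$day_index, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (j in seq_along(s$dim_names)) df[[s$dim_names[j]]] <- fmt(ratings[, j])
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Aggregate raw emotion items into PA and NA scores
#'
#' Per beep, the positive-affect (PA) score is the mean over the observed
#' positive items and likewise negative affect (NA) over the negative items;
#' if every item of a group is missing at a beep the aggregate is missing.
#'
#' @param series An [esm_series] with the raw item columns.
#' @param positive_items,negative_items Character vectors of item names.
#' @return An [esm_series] with `d = 2` and `dim_names = c("PA","NA")`.
#' @export
aggregate_pa_na <- function(series, positive_items, negative_items) {
  if (!length(positive_items) || !length(negative_items))
    stop("item groups must be non-empty")
  missing_items <- setdiff(c(positive_items, negative_items), series$dim_names)
  if (length(missing_items))
    stop("items not present: ", paste(missing_items, collapse = ", "))
  group_mean <- function(items) {
    vals <- series$ratings[, items, drop = FALSE]
    vals[series$missing_mask[, items, drop = FALSE]] <- NA
    rowMeans(vals, na.rm = TRUE)
  }
  pa <- group_mean(positive_items)
  na_ <- group_mean(negative_items)
  ratings <- cbind(PA = pa, "NA" = na_)
  ratings[is.nan(ratings)] <- NA
  esm_series(series$series_id, series$timestamps, series$day_index, ratings,
             dim_names = c("PA", "NA"))
}

#' Build the scoring plan for a series
#'
#' Segments a series into the items its likelihood sums over: the first
#' non-missing beep of each day is scored under the stationary distribution
#' (both models are assumed to relax completely overnight); every later
#' non-missing beep is a transition from the previous non-missing beep of
#' the same day, carrying both the actual elapsed time in hours (used by the
#' continuous-time OU model) and a pseudo-step count
#' `1 + number of fully-missing beeps skipped` (used by the discrete-time
#' VAR(1) model, e.g. step 2 when one beep in between was missed). Beeps
#' with any missing dimension count as fully missing.
#'
#' @param series An [esm_series].
#' @param model_timescale `"continuous"` or `"unit_step"`; recorded as an
#'   attribute (the plan itself carries both time encodings).
#' @return A `transition_plan` data frame with columns `kind`
#'   (`"stationary"`/`"transition"`), `source`, `target` (row indices into
#'   the series), `dt` (hours), `steps` (pseudo-steps) and `retained`.
#' @export
build_transition_plan <- function(series,
                                  model_timescale = c("continuous", "unit_step")) {
  model_timescale <- match.arg(model_timescale)
  obs <- which(!fully_missing(series))
  if (length(obs)) {
    day <- series$day_index[obs]
    first_of_day <- c(TRUE, day[-1] != day[-length(day)])
    source <- c(NA_integer_, obs[-length(obs)])
    source[first_of_day] <- NA_integer_
    dt <- series$timestamps[obs] - series$timestamps[source]
    plan <- data.frame(
      kind = ifelse(first_of_day, "stationary", "transition"),
      source = source, target = obs, dt = dt,
      steps = as.integer(obs - source), retained = TRUE,
      stringsAsFactors = FALSE)
  } else {
    plan <- data.frame(kind = character(), source = integer(),
                       target = integer(), dt = numeric(), steps = integer(),
                       retained = logical())
  }
  structure(plan, class = c("transition_plan", "data.frame"),
            timescale = model_timescale, series_id = series$series_id,
            n_obs = n_beeps(series))
}

# marshal a (series, plan) pair for the C++ chain evaluators;
# elapsed is hours for continuous propagation, pseudo-steps for unit-step
plan_payload <- function(series, plan, timescale = c("continuous", "unit_step")) {
  timescale <- match.arg(timescale)
  elapsed <- if (timescale == "continuous") plan$dt else as.numeric(plan$steps)
  elapsed[is.na(elapsed)] <- 0
  list(X = series$ratings,
       kind = as.integer(plan$kind == "transition"),
       src = ifelse(is.na(plan$source), 0L, as.integer(plan$source)),
       tgt = as.integer(plan$target),
       elapsed = elapsed,
       retained = as.integer(plan$retained))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
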