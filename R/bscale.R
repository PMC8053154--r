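#' Map cough counts onto the B-scale
#'
#' Applies `B = alpha * log(1 + beta * C)`. The mapping is strictly
#' increasing in the count, sends zero counts to zero, and compresses large
#' counts so that, for patients whose daily-count standard deviation grows
#' linearly with their mean, day-to-day variability on the B-scale is
#' approximately the same for low- and high-count patients.
#'
#' @param counts Numeric vector of non-negative daily cough counts;
#'   `NA` marks missing days and is propagated.
#' @param params [bscale_params()].
#' @return Numeric vector of B-scale values.
#' @export
#' @examples
#' bscale(c(0, 25, 100))
bscale <- function(counts, params = bscale_params()) {
  stopifnot(inherits(params, "bscale_params"))
  if (!is.numeric(counts)) abort("`counts` must be numeric.")
  if (any(counts < 0, na.rm = TRUE))
    abort("cough counts must be non-negative.")
  params$alpha * log(1 + params$beta * counts, base = params$log_base)
}

#' Invert the B-scale mapping
#'
#' Returns the count corresponding to a B-scale value,
#' `C = (base^(B / alpha) - 1) / beta`.
#'
#' @param b Numeric vector of B-scale values (`NA` propagated).
#' @inheritParams bscale
#' @return Numeric vector of (not necessarily integer) counts.
#' @export
bscale_inverse <- function(b, params = bscale_params()) {
  stopifnot(inherits(params, "bscale_params"))
  (params$log_base^(b / params$alpha) - 1) / params$beta
}

#' Aggregate cough event timestamps into noon-to-noon daily counts
#'
#' Counts are totalled over 24-h windows running from noon to noon; the
#' window beginning at noon on calendar day `d` is labelled day `d`. Days
#' with no monitoring coverage are reported as missing (`NA`), never as
#' zero: an uncovered day carries no information about cough frequency.
#'
#' @param timestamps Cough event times, `POSIXct` or strings parseable by
#'   [as.POSIXct()].
#' @param start_date `Date` (or string) of study day 0; day `k`'s window is
#'   `[start_date + k, 12:00, start_date + k + 1, 12:00)`.
#' @param n_days Number of monitoring days (windows) in the horizon.
#' @param covered Optional logical vector of length `n_days` (or integer
#'   vector of covered day indices): days not covered by the monitor are
#'   set to `NA`. Default: all days covered.
#' @param tz Time zone used to interpret the timestamps.
#' @return A tibble with columns `day` (0-based) and `cough_count`
#'   (integer, `NA` on uncovered days). The number of events falling
#'   outside the horizon is attached as attribute `n_dropped`, with a
#'   warning when positive.
#' @export
#' @examples
#' aggregate_daily(c("2024-01-01 11:59:00", "2024-01-01 12:01:00"),
#'                 start_date = "2024-01-01", n_days = 2)
aggregate_daily <- function(timestamps, start_date, n_days, covered = NULL,
                            tz = "UTC") {
  n_days <- check_count(n_days, "n_days", min = 1L)
  start <- as.Date(start_date)
  if (is.na(start)) abort("`start_date` must be a valid date.")
  ts <- as.POSIXct(timestamps, tz = tz)
  if (anyNA(ts) && !anyNA(timestamps)) abort("unparseable timestamps.")
  origin <- as.POSIXct(paste(start, "12:00:00"), tz = tz)
  day <- floor(as.numeric(difftime(ts, origin, units = "days")))
  in_horizon <- !is.na(day) & day >= 0 & day < n_days
  n_dropped <- sum(!in_horizon)
  if (n_dropped > 0)
    warn(sprintf("%d event(s) outside the %d-day horizon were dropped.",
                 n_dropped, n_days))
  counts <- tabulate(day[in_horizon] + 1L, nbins = n_days)
  if (!is.null(covered)) {
    if (is.numeric(covered)) covered <- seq_len(n_days) %in% (covered + 1L)
    if (!is.logical(covered) || length(covered) != n_days)
      abort("`covered` must be a logical vector of length `n_days` or day indices.")
    counts[!covered] <- NA_integer_
  }
  out <- tibble(day = seq_len(n_days) - 1L, cough_count = as.integer(counts))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Estimate an individual baseline level
#'
#' A robust location estimate (median by default) of a patient's B-scale
#' values (or questionnaire scores) over eligible days. Days flagged in
#' `exclude` -- typically exacerbation-associated windows -- and missing
#' days contribute nothing.
#'
#' @param x Numeric vector of daily values (`NA` = missing).
#' @param exclude Optional logical vector, `TRUE` for days to exclude.
#' @param min_days Minimum number of eligible days required.
#' @param method `"median"` (default) or `"mean"`.
#' @param patient Optional patient label used in error messages.
#' @return The baseline level (single number).
#' @export
estimate_baseline <- function(x, exclude = NULL, min_days = 7L,
                              method = c("median", "mean"), patient = NULL) {
  method <- match.arg(method)
  min_days <- check_count(min_days, "min_days")
  if (is.null(exclude)) exclude <- rep(FALSE, length(x))
  if (length(exclude) != length(x))
    abort("`exclude` must match `x` in length.")
  eligible <- !is.na(x) & !exclude
  if (sum(eligible) < min_days)
    abort(sprintf(
      "insufficient baseline%s: %d eligible day(s), need at least %d.",
      if (is.null(patient)) "" else paste0(" for patient ", patient),
      sum(eligible), min_days))
  if (method == "median") median(x[eligible]) else mean(x[eligible])
}

#' Express a series as deviation from baseline
#'
#' @param x Numeric vector (missing preserved).
#' @param baseline Finite baseline level.
#' @return `x - baseline`.
#' @export
normalize_to_baseline <- function(x, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline))
    abort("`baseline` must be a single finite number.")
  x - baseline
}

#' Add B-scale values to a cohort's daily records
#'
#' @param records Daily-record tibble with `patient_id`, `day` and
#'   `cough_count` columns (see [simulate_cohort()] for the schema).
#' @param params [bscale_params()].
#' @return `records` with an added numeric column `b`.
#' @export
add_bscale <- function(records, params = bscale_params()) {
  check_records(records, c("patient_id", "day", "cough_count"))
  mutate(records, b = bscale(.data$cough_count, params))
}

#' Add per-patient baselines and deviations
#'
#' Estimates each patient's baseline of `col` over days outside any
#' exacerbation-associated window (episode span extended by `pre` days
#' before onset and `post` days after end) and adds the deviation
#' `col - baseline`. Patients with too few eligible days are dropped with
#' a warning naming them; alert generation needs a baseline to deviate
#' from.
#'
#' @param records Daily-record tibble, already containing column `col`.
#' @param events Tibble of exacerbation events (possibly empty) with
#'   `patient_id`, `onset`, `end` columns; `NULL` means no exclusions.
#' @param col Name of the value column (default `"b"`).
#' @param pre,post Exclusion margins around episodes, in days.
#' @param min_days,method,... Passed to [estimate_baseline()].
#' @return `records` with added columns `baseline` and `deviation`,
#'   restricted to patients for whom a baseline could be estimated.
#' @export
add_deviation <- function(records, events = NULL, col = "b",
                          pre = 8L, post = 8L, min_days = 7L,
                          method = c("median", "mean")) {
  check_records(records, c("patient_id", "day", col))
  method <- match.arg(method)
  per_patient <- function(df) {
    pid <- df$patient_id[1]
    excl <- rep(FALSE, nrow(df))
    if (!is.null(events)) {
      ev <- events[events$patient_id == pid, , drop = FALSE]
      for (i in seq_len(nrow(ev)))
        excl <- excl | (df$day >= ev$onset[i] - pre & df$day <= ev$end[i] + post)
    }
    base <- tryCatch(
      estimate_baseline(df[[col]], exclude = excl, min_days = min_days,
                        method = method, patient = pid),
      error = function(e) NA_real_)
    df$baseline <- base
    df$deviation <- df[[col]] - base
    df
  }
  out <- records |>
    split(records$patient_id) |>
    purrr::map(per_patient) |>
    bind_rows()
  out <- arrange(out, .data$patient_id, .data$day)
  dropped <- unique(out$patient_id[is.na(out$baseline)])
  if (length(dropped)) {
    warn(sprintf("no baseline for patient(s) %s (too few eligible days); dropped.",
                 paste(dropped, collapse = ", ")))
    out <- out[!out$patient_id %in% dropped, , drop = FALSE]
  }
  out
}
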