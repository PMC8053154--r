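#' Correlation between self-reported increased cough and measured counts
#'
#' For each patient, the Pearson (point-biserial) correlation between the
#' binary "increased cough today" questionnaire item and (i) the change in
#' cough count from the previous day, `C(t) - C(t-1)` over consecutive
#' observed day pairs, and (ii) the same day's count on the B-scale,
#' `B(t)`. Coefficients are pooled per patient and then summarised across
#' patients (mean and SD of the per-patient coefficients). Patients with
#' fewer than `min_days` usable paired days, or with zero variance in
#' either variable (for example, a patient who reports increased cough
#' every day), are excluded and counted.
#'
#' @param records Daily-record tibble with `patient_id`, `day`,
#'   `cough_count`, a `b` column ([add_bscale()]) and the questionnaire
#'   item columns.
#' @param item Name of the binary increased-cough item (default `"q1"`;
#'   which item asks about cough is a property of the questionnaire, not
#'   of this package).
#' @param min_days Minimum paired days per patient (default 10).
#' @return An object of class `report_correlation`: a list with
#'   `patients` (per-patient tibble: `patient_id`, `n_change`, `r_change`,
#'   `n_bscale`, `r_bscale`, `excluded`, `reason`) and `summary` (one-row
#'   tibble: `mean_r_change`, `sd_r_change`, `mean_r_bscale`,
#'   `sd_r_bscale`, `n_included`, `n_excluded`). With every patient
#'   excluded the summary values are `NA` (undefined, not zero).
#' @export
cough_report_correlation <- function(records, item = "q1", min_days = 10L) {
  check_records(records, c("patient_id", "day", "cough_count", "b", item))
  min_days <- check_count(min_days, "min_days", min = 2L)
  per_patient <- function(df) {
    df <- df[order(df$day), , drop = FALSE]
    y <- df[[item]]
    prev <- df$cough_count[match(df$day - 1L, df$day)]
    change <- df$cough_count - prev
    ok_ch <- !is.na(y) & !is.na(change)
    ok_b <- !is.na(y) & !is.na(df$b)
    r_of <- function(yy, xx) {
      if (sd(yy) == 0 || sd(xx) == 0) return(NA_real_)
      cor(yy, xx)
    }
    n_ch <- sum(ok_ch); n_b <- sum(ok_b)
    r_ch <- if (n_ch >= min_days) r_of(y[ok_ch], change[ok_ch]) else NA_real_
    r_b <- if (n_b >= min_days) r_of(y[ok_b], df$b[ok_b]) else NA_real_
    reason <- if (n_ch < min_days || n_b < min_days) "too_few_days"
      else if (is.na(r_ch) || is.na(r_b)) "zero_variance" else NA_character_
    tibble(patient_id = df$patient_id[1], n_change = n_ch,
           r_change = r_ch, n_bscale = n_b, r_bscale = r_b,
           excluded = is.na(r_ch) | is.na(r_b), reason = reason)
  }
  patients <- records |>
    split(records$patient_id) |>
    purrr::map(per_patient) |>
    bind_rows()
  inc <- patients[!patients$excluded, , drop = FALSE]
  summary <- tibble(
    mean_r_change = if (nrow(inc)) mean(inc$r_change) else NA_real_,
    sd_r_change = if (nrow(inc) > 1) sd(inc$r_change) else NA_real_,
    mean_r_bscale = if (nrow(inc)) mean(inc$r_bscale) else NA_real_,
    sd_r_bscale = if (nrow(inc) > 1) sd(inc$r_bscale) else NA_real_,
    n_included = nrow(inc), n_excluded = sum(patients$excluded))
  structure(list(patients = patients, summary = summary),
            class = "report_correlation")
}

#' @export
print.report_correlation <- function(x, ...) {
  s <- x$summary
  cat("<report_correlation>\n")
  cat(sprintf("  reported increase vs count change: r = %s (SD %s)\n",
              fmt_rate(s$mean_r_change), fmt_rate(s$sd_r_change)))
  cat(sprintf("  reported increase vs B-scale count: r = %s (SD %s)\n",
              fmt_rate(s$mean_r_bscale), fmt_rate(s$sd_r_bscale)))
  cat(sprintf("  %d patient(s) included, %d excluded\n",
              s$n_included, s$n_excluded))
  invisible(x)
}

#' @describeIn cough_report_correlation per-patient coefficients.
#' @param x A `report_correlation`.
#' @param ... Unused.
#' @method tidy report_correlation
#' @export
tidy.report_correlation <- function(x, ...) x$patients

#' @describeIn cough_report_correlation across-patient summary.
#' @method glance report_correlation
#' @export
glance.report_correlation <- function(x, ...) x$summary
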