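#' Apply a k-of-n exceedance run rule to one daily series
#'
#' Core of the cough-monitor alert logic: day `t` is an alert day iff the
#' `n`-day window ending at `t` contains at least `k` observed exceedances
#' of the threshold, at least `min_observed` observed days, and (by
#' default) day `t` itself exceeds. Missing days are never exceedances.
#' Days are taken as consecutive calendar days; the input must be a
#' complete daily grid (use `NA` for missing values).
#'
#' @param values Numeric vector of daily values (deviation from baseline),
#'   `NA` = missing day.
#' @param rule [cough_alert_rule()].
#' @return Logical vector, `TRUE` on alert days (`FALSE` on missing days).
#' @export
#' @examples
#' run_rule_alerts(c(0, 3, 0, 3, 3), cough_alert_rule(threshold = 2))
run_rule_alerts <- function(values, rule = cough_alert_rule()) {
  stopifnot(inherits(rule, "cough_alert_rule"))
  observed <- !is.na(values)
  exceed <- observed & !is.na(values > rule$threshold) & values > rule$threshold
  t_len <- length(values)
  alert <- logical(t_len)
  for (t in seq_len(t_len)) {
    win <- max(1L, t - rule$n + 1L):t
    if (sum(observed[win]) < rule$min_observed) next
    if (sum(exceed[win]) < rule$k) next
    if (rule$require_current && !exceed[t]) next
    alert[t] <- TRUE
  }
  alert
}

#' Generate cough-monitor alerts from B-scale deviations
#'
#' Applies the k-of-n run rule to each patient's deviation-from-baseline
#' series (see [add_deviation()]).
#'
#' @param records Daily-record tibble with `patient_id`, `day` and
#'   `deviation` columns on a complete daily grid per patient.
#' @param rule [cough_alert_rule()].
#' @return An alert tibble: `patient_id`, `day`, `source` (`"cough"`),
#'   `value` (the deviation) and `alert` (logical).
#' @export
cough_alerts <- function(records, rule = cough_alert_rule()) {
  check_records(records, c("patient_id", "day", "deviation"))
  records |>
    arrange(.data$patient_id, .data$day) |>
    group_by(.data$patient_id) |>
    mutate(alert = run_rule_alerts(.data$deviation, rule)) |>
    ungroup() |>
    mutate(source = "cough", value = .data$deviation) |>
    select("patient_id", "day", "source", "value", "alert")
}

#' Score the daily symptom questionnaire
#'
#' Weighted sum of the eight binary items. A day with any missing item
#' yields a missing score.
#'
#' @param items Numeric vector of 8 responses in \{0, 1\}, or a matrix /
#'   data frame with 8 columns (one row per day).
#' @param config [questionnaire_config()].
#' @return Integer score(s) in `[0, max_score]`.
#' @export
#' @examples
#' questionnaire_score(c(1, 0, 1, 0, 0, 0, 0, 1))
questionnaire_score <- function(items, config = questionnaire_config()) {
  stopifnot(inherits(config, "questionnaire_config"))
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  if (ncol(items) != 8L)
    abort(sprintf("expected 8 questionnaire items, got %d.", ncol(items)))
  ok <- is.na(items) | items %in% c(0, 1)
  if (!all(ok)) abort("questionnaire items must be 0/1 (or NA).")
  score <- as.integer(items %*% config$weights)
  score[apply(items, 1, anyNA)] <- NA_integer_
  score
}

#' Generate absolute-threshold questionnaire alerts
#'
#' Alert on day `t` iff the day's score reaches `alert_high`, or the last
#' `sustained_days` consecutive observed calendar days (ending at `t`) all
#' score at least `alert_sustained`. Missing days break a consecutive run.
#'
#' @param records Daily-record tibble with `patient_id`, `day` and either a
#'   `score` column or item columns `q1`..`q8`.
#' @param config [questionnaire_config()].
#' @return An alert tibble (`source = "questionnaire"`, `value` = score).
#' @export
questionnaire_alerts <- function(records, config = questionnaire_config()) {
  records <- ensure_scores(records, config)
  records |>
    arrange(.data$patient_id, .data$day) |>
    group_by(.data$patient_id) |>
    mutate(alert = score_rule_alerts(.data$score, config)) |>
    ungroup() |>
    mutate(source = "questionnaire", value = as.numeric(.data$score)) |>
    select("patient_id", "day", "source", "value", "alert")
}

score_rule_alerts <- function(score, config) {
  n <- length(score)
  observed <- !is.na(score)
  high <- observed & score >= config$alert_high
  sust <- observed & score >= config$alert_sustained
  run <- integer(n)
  for (t in seq_len(n)) {
    run[t] <- if (sust[t]) (if (t > 1L) run[t - 1L] else 0L) + 1L else 0L
  }
  high | (run >= config$sustained_days)
}

#' Individualized questionnaire alerts
#'
#' Re-analyses the questionnaire with the cough-monitor methodology: each
#' patient's baseline symptom score is estimated (excluding
#' exacerbation-associated windows when events are supplied), and the
#' k-of-n run rule is applied to the deviation of the daily score from
#' that baseline. Patients who always answer "yes" have constant maximal
#' scores, defeating the absolute rule's specificity but yielding zero
#' deviation here.
#'
#' @param records Daily-record tibble with `patient_id`, `day` and a
#'   `score` column or `q1`..`q8` items.
#' @param rule [cough_alert_rule()] on score deviations (its `threshold`
#'   is in score points above baseline).
#' @param events Optional event tibble for baseline exclusion windows.
#' @param config [questionnaire_config()] used if scores must be computed.
#' @param pre,post,min_days,method Baseline options as in [add_deviation()].
#' @return An alert tibble (`source = "questionnaire_individualized"`,
#'   `value` = score deviation).
#' @export
individualized_questionnaire_alerts <- function(records,
                                                rule = cough_alert_rule(threshold = 2),
                                                events = NULL,
                                                config = questionnaire_config(),
                                                pre = 8L, post = 8L,
                                                min_days = 7L,
                                                method = c("median", "mean")) {
  records <- ensure_scores(records, config)
  dev <- add_deviation(records, events = events, col = "score",
                       pre = pre, post = post, min_days = min_days,
                       method = match.arg(method))
  dev |>
    arrange(.data$patient_id, .data$day) |>
    group_by(.data$patient_id) |>
    mutate(alert = run_rule_alerts(.data$deviation, rule)) |>
    ungroup() |>
    mutate(source = "questionnaire_individualized",
           value = .data$deviation) |>
    select("patient_id", "day", "source", "value", "alert")
}

ensure_scores <- function(records, config) {
  check_records(records)
  if (!"score" %in% names(records)) {
    items <- paste0("q", 1:8)
    check_records(records, items)
    records$score <- questionnaire_score(records[, items], config)
  }
  records
}

#' Generate alerts from one strategy
#'
#' Convenience dispatcher over [cough_alerts()], [questionnaire_alerts()]
#' and [individualized_questionnaire_alerts()].
#'
#' @param records Daily-record tibble (with the columns the chosen source
#'   requires).
#' @param source One of `"cough"`, `"questionnaire"`,
#'   `"questionnaire_individualized"`.
#' @param ... Passed to the strategy function.
#' @return An alert tibble.
#' @export
generate_alerts <- function(records,
                            source = c("cough", "questionnaire",
                                       "questionnaire_individualized"),
                            ...) {
  switch(match.arg(source),
         cough = cough_alerts(records, ...),
         questionnaire = questionnaire_alerts(records, ...),
         questionnaire_individualized =
           individualized_questionnaire_alerts(records, ...))
}
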