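#' Run the full telemonitoring analysis pipeline
#'
#' Composes the stages end to end: exacerbation detection and merging,
#' B-scale mapping, individualised baselines and deviations, alert
#' generation for the three strategies (cough monitor, absolute
#' questionnaire rule, individualized questionnaire rule), day labelling,
#' alert evaluation, the exacerbation-centred trend, and the self-report
#' vs count correlations. All randomness lives in the cohort generator;
#' this function is deterministic given its inputs.
#'
#' @param records Daily-record tibble (see [simulate_cohort()] for the
#'   schema).
#' @param config A [pipeline_config()].
#' @param prescriptions Optional prescribing-event tibble
#'   (`patient_id`, `day`) passed to [detect_exacerbations()].
#' @param events Optional pre-computed event tibble; when supplied,
#'   detection is skipped and the events are merged and used as given
#'   (e.g. ground-truth episodes).
#' @param out_dir Optional directory; when given, every intermediate
#'   artifact (B-series, alerts, events, day labels, trend, reports) is
#'   written as CSV/JSON-ready tables so each stage can be audited and
#'   re-run from its inputs.
#' @return A list of class `cough_pipeline`:
#'   `events` (merged), `records` (with `b`, `score`, `baseline`,
#'   `deviation`), `alerts` (all strategies, long), `labels` (per
#'   strategy), `evaluations` (named list of [evaluate_alerts()] reports),
#'   `trend` ([exacerbation_trend()]), `correlation`
#'   ([cough_report_correlation()]).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 4, seed = 3))
#' res <- run_pipeline(coh$records)
#' glance(res$evaluations$cough)
run_pipeline <- function(records, config = pipeline_config(),
                         prescriptions = NULL, events = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  check_records(records, c("patient_id", "day", "cough_count"))

  if (is.null(events))
    events <- detect_exacerbations(records, prescriptions = prescriptions)
  events <- merge_events(events, gap = config$merge_gap)

  recs <- add_bscale(records, config$bscale)
  recs$score <- questionnaire_score(recs[, paste0("q", 1:8)],
                                    config$questionnaire)

  dev <- suppressWarnings(add_deviation(
    recs, events = events, col = "b",
    pre = config$pre_window, post = config$post_window,
    min_days = config$min_baseline_days,
    method = config$baseline_method))
  n_dropped <- length(setdiff(unique(recs$patient_id),
                              unique(dev$patient_id)))
  if (n_dropped)
    message(sprintf("pipeline: %d patient(s) without a cough baseline excluded from cough alerts.",
                    n_dropped))

  al_cough <- cough_alerts(dev, config$cough_rule)
  al_quest <- questionnaire_alerts(recs, config$questionnaire)
  al_indiv <- suppressWarnings(individualized_questionnaire_alerts(
    recs, rule = config$indiv_rule, events = events,
    config = config$questionnaire, pre = config$pre_window,
    post = config$post_window, min_days = config$min_baseline_days,
    method = config$baseline_method))

  lab_cough <- classify_days(dev, events, pre = config$pre_window,
                             post = config$post_window,
                             signal_col = "cough_count")
  lab_quest <- classify_days(recs, events, pre = config$pre_window,
                             post = config$post_window,
                             signal_col = "score")
  lab_indiv <- classify_days(
    recs[recs$patient_id %in% unique(al_indiv$patient_id), , drop = FALSE],
    events, pre = config$pre_window, post = config$post_window,
    signal_col = "score")

  subset_events <- function(ev, ids) ev[ev$patient_id %in% ids, , drop = FALSE]
  evaluations <- list(
    cough = evaluate_alerts(al_cough,
                            subset_events(events, unique(dev$patient_id)),
                            lab_cough, window = config$pre_window),
    questionnaire = evaluate_alerts(al_quest, events, lab_quest,
                                    window = config$pre_window),
    questionnaire_individualized = evaluate_alerts(
      al_indiv, subset_events(events, unique(al_indiv$patient_id)),
      lab_indiv, window = config$pre_window))

  trend <- suppressWarnings(
    exacerbation_trend(recs, events, pre = config$pre_window,
                       post = config$post_window))
  correlation <- cough_report_correlation(
    recs, min_days = config$min_correlation_days)

  res <- structure(list(
    events = events, records = dev, alerts = bind_rows(al_cough, al_quest,
                                                       al_indiv),
    labels = list(cough = lab_cough, questionnaire = lab_quest,
                  questionnaire_individualized = lab_indiv),
    evaluations = evaluations, trend = trend, correlation = correlation),
    class = "cough_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.cough_pipeline <- function(x, ...) {
  cat("<cough_pipeline>\n")
  for (ev in x$evaluations) print(ev)
  print(x$correlation)
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(res$records, file.path(out_dir, "bseries.csv"), na = "")
  write_events(res$events, file.path(out_dir, "events.csv"))
  readr::write_csv(res$alerts, file.path(out_dir, "alerts.csv"), na = "")
  for (nm in names(res$labels))
    readr::write_csv(res$labels[[nm]],
                     file.path(out_dir, paste0("labels_", nm, ".csv")),
                     na = "")
  readr::write_csv(as_tibble(res$trend), file.path(out_dir, "trend.csv"),
                   na = "")
  reports <- bind_rows(purrr::map(res$evaluations, glance))
  readr::write_csv(reports, file.path(out_dir, "evaluation.csv"), na = "")
  readr::write_csv(res$correlation$patients,
                   file.path(out_dir, "correlation_patients.csv"), na = "")
  readr::write_csv(res$correlation$summary,
                   file.path(out_dir, "correlation_summary.csv"), na = "")
  invisible(out_dir)
}
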