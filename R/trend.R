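#' Exacerbation-centred cough trend on the B-scale
#'
#' Builds the mean B-scale cough profile over the 17 days around
#' exacerbation onset (relative days -8..+8), across all included epochs
#' (complete, non-overlapping; see [select_epochs()]). Each patient's
#' B-values are first normalised so that their average cough count over
#' the whole record is 0 on the B-scale; the profile then shows deviation
#' from the patient's own typical level.
#'
#' @param records Daily-record tibble with a `b` column ([add_bscale()]).
#' @param events Merged event tibble.
#' @param pre,post Epoch half-widths (default 8 and 8).
#' @return A tibble of class `cough_trend` with columns `rel_day`
#'   (-pre..+post), `mean_b` (mean normalised B), `sem` (standard error of
#'   the mean; 0 by convention when a single epoch contributes, flagged by
#'   `n_epochs`), and `n_epochs`. Zero included epochs yield an empty
#'   profile with a warning.
#' @export
exacerbation_trend <- function(records, events, pre = 8L, post = 8L) {
  check_records(records, c("patient_id", "day", "b"))
  epochs <- select_epochs(events, records, pre = pre, post = post)
  epochs <- epochs[epochs$included, , drop = FALSE]
  if (!nrow(epochs)) {
    warn("no complete, non-overlapping epochs; empty trend profile.")
    out <- tibble(rel_day = integer(), mean_b = numeric(),
                  sem = numeric(), n_epochs = integer())
    return(structure(out, class = c("cough_trend", class(out))))
  }
  centred <- records |>
    group_by(.data$patient_id) |>
    mutate(b_norm = .data$b - mean(.data$b, na.rm = TRUE)) |>
    ungroup()
  vals <- purrr::map(seq_len(nrow(epochs)), function(i) {
    rec <- centred[centred$patient_id == epochs$patient_id[i], ]
    days <- (epochs$onset[i] - pre):(epochs$onset[i] + post)
    tibble(rel_day = days - epochs$onset[i],
           b_norm = rec$b_norm[match(days, rec$day)])
  }) |> bind_rows()
  out <- vals |>
    group_by(.data$rel_day) |>
    summarise(mean_b = mean(.data$b_norm),
              sem = if (n() > 1) sd(.data$b_norm) / sqrt(n()) else 0,
              n_epochs = n(), .groups = "drop")
  structure(out, class = c("cough_trend", class(out)))
}

#' Plot an exacerbation-centred cough trend
#'
#' Mean normalised B-scale cough count by day relative to exacerbation
#' onset (day 0), with standard-error bars.
#'
#' @param object A `cough_trend` from [exacerbation_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cough_trend
#' @export
autoplot.cough_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_day, y = .data$mean_b)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_b - .data$sem,
                                        ymax = .data$mean_b + .data$sem),
                           width = 0.3, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Days relative to exacerbation onset",
                  y = "Mean cough count (B-scale, patient-centred)",
                  title = "Cough trend around exacerbation onset")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one patient's monitoring record
#'
#' B-scale deviation from baseline with the alert threshold, alert days
#' and exacerbation episodes overlaid; a quick visual audit of why alerts
#' did or did not fire.
#'
#' @param records Daily-record tibble with `deviation` ([add_deviation()]).
#' @param patient Patient id to plot.
#' @param alerts Optional alert tibble; alert days drawn as points.
#' @param events Optional event tibble; episodes drawn as shaded spans.
#' @param threshold Alert threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_patient_record <- function(records, patient, alerts = NULL,
                                events = NULL, threshold = 2) {
  check_records(records, c("patient_id", "day", "deviation"))
  rec <- records[records$patient_id == patient, , drop = FALSE]
  if (!nrow(rec)) abort(sprintf("no records for patient %s.", patient))
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$day, y = .data$deviation))
  if (!is.null(events)) {
    ev <- events[events$patient_id == patient, , drop = FALSE]
    if (nrow(ev))
      p <- p + ggplot2::geom_rect(
        data = ev, inherit.aes = FALSE, alpha = 0.15, fill = "firebrick",
        ggplot2::aes(xmin = .data$onset, xmax = .data$end,
                     ymin = -Inf, ymax = Inf))
  }
  p <- p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted") +
    ggplot2::geom_line(na.rm = TRUE)
  if (!is.null(alerts)) {
    al <- alerts[alerts$patient_id == patient & alerts$alert %in% TRUE, ]
    if (nrow(al))
      p <- p + ggplot2::geom_point(
        data = left_join(al, rec[, c("day", "deviation")], by = "day"),
        ggplot2::aes(x = .data$day, y = .data$deviation),
        colour = "firebrick", size = 2, na.rm = TRUE)
  }
  p + ggplot2::labs(x = "Study day", y = "B-scale deviation from baseline",
                    title = paste("Patient", patient))
}
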