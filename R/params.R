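#' B-scale mapping constants
#'
#' The B-scale is a logarithmic transform of daily cough counts,
#' `B = alpha * log(1 + beta * C)`, constructed so that day-to-day
#' variability of the mapped counts is approximately constant across
#' patients whose raw-count standard deviation grows linearly with their
#' mean. The published constants for 24-h cough count totals are
#' `alpha = 3.45` and `beta = 0.04`.
#'
#' @param alpha Positive scale factor of the transform.
#' @param beta Positive per-count compression rate (1/counts).
#' @param log_base Base of the logarithm. The defaults assume the natural
#'   logarithm; the base is carried as an explicit convention so it can be
#'   switched without touching downstream code.
#' @return An object of class `bscale_params`.
#' @seealso [bscale()], [bscale_inverse()]
#' @export
#' @examples
#' p <- bscale_params()
#' bscale(25, p) # 3.45 * log(2)
bscale_params <- function(alpha = 3.45, beta = 0.04, log_base = exp(1)) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  check_positive_scalar(log_base, "log_base")
  structure(list(alpha = alpha, beta = beta, log_base = log_base),
            class = "bscale_params")
}

#' @export
print.bscale_params <- function(x, ...) {
  cat(sprintf("<bscale_params> B = %g * log(1 + %g * C), log base %g\n",
              x$alpha, x$beta, x$log_base))
  invisible(x)
}

#' Run rule for deviation-based alerts
#'
#' An alert fires on day `t` when, within a window of `n` consecutive days
#' ending at `t`, at least `k` observed days exceed `threshold` (the
#' study's rule is "at least 2 out of 3 consecutive days"). Missing days
#' never count as exceedances. By default the alert day itself must exceed,
#' so an alert always coincides with an elevated value rather than echoing
#' two past days.
#'
#' @param threshold Positive exceedance threshold, in units of the series
#'   the rule is applied to (B-scale units above baseline for cough alerts;
#'   score points above baseline for the individualized questionnaire
#'   variant). The default of 2 B-scale units is a documented stand-in: the
#'   study describes its threshold only as pre-specified.
#' @param k,n Integers with `1 <= k <= n`: required exceedances and window
#'   length.
#' @param min_observed Minimum number of observed (non-missing) days a
#'   window must contain to be eligible.
#' @param require_current Logical; must day `t` itself exceed?
#' @return An object of class `cough_alert_rule`.
#' @export
cough_alert_rule <- function(threshold = 2, k = 2L, n = 3L,
                             min_observed = 2L, require_current = TRUE) {
  check_positive_scalar(threshold, "threshold")
  k <- check_count(k, "k"); n <- check_count(n, "n")
  min_observed <- check_count(min_observed, "min_observed")
  if (k > n) abort("`k` must not exceed `n` in a k-of-n rule.")
  structure(list(threshold = threshold, k = k, n = n,
                 min_observed = min_observed,
                 require_current = isTRUE(require_current)),
            class = "cough_alert_rule")
}

#' @export
print.cough_alert_rule <- function(x, ...) {
  cat(sprintf(
    "<cough_alert_rule> threshold %g, %d of %d days%s\n", x$threshold,
    x$k, x$n, if (x$require_current) ", alert day must exceed" else ""))
  invisible(x)
}

#' Daily symptom questionnaire configuration
#'
#' The daily questionnaire has eight weighted yes/no items with a total
#' score of 0-11. An alert is raised when the score reaches
#' `alert_high` (default 5) or stays at or above `alert_sustained`
#' (default 4) for `sustained_days` consecutive observed days.
#'
#' The published instrument's item weights are not restated here; the
#' default weights `c(2, 2, 2, 1, 1, 1, 1, 1)` are a non-canonical choice
#' that reproduces the 0-11 range and is fully configurable.
#'
#' @param weights Eight positive integer item weights.
#' @param alert_high Score that fires an alert on its own.
#' @param alert_sustained Score that fires when sustained.
#' @param sustained_days Consecutive observed days required at
#'   `alert_sustained` or above; missing days break the run.
#' @return An object of class `questionnaire_config`.
#' @export
questionnaire_config <- function(weights = c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L),
                                 alert_high = 5L, alert_sustained = 4L,
                                 sustained_days = 2L) {
  if (length(weights) != 8L || any(weights <= 0) || any(weights != round(weights)))
    abort("`weights` must be eight positive integers.")
  weights <- as.integer(weights)
  alert_high <- check_count(alert_high, "alert_high")
  alert_sustained <- check_count(alert_sustained, "alert_sustained")
  sustained_days <- check_count(sustained_days, "sustained_days")
  max_score <- sum(weights)
  if (!(alert_sustained < alert_high && alert_high <= max_score))
    abort("need `alert_sustained` < `alert_high` <= sum(weights).")
  structure(list(weights = weights, max_score = max_score,
                 alert_high = alert_high, alert_sustained = alert_sustained,
                 sustained_days = sustained_days),
            class = "questionnaire_config")
}

#' @export
print.questionnaire_config <- function(x, ...) {
  cat(sprintf(
    "<questionnaire_config> weights [%s] (max %d); alert at >=%d or >=%d on %d consecutive days\n",
    paste(x$weights, collapse = ","), x$max_score, x$alert_high,
    x$alert_sustained, x$sustained_days))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the stage configurations and the windowing constants used by
#' [run_pipeline()]: the 8-day pre-onset success window, the 8-day
#' post-episode margin, and the merge gap below which two treated episodes
#' count as a single exacerbation.
#'
#' @param bscale [bscale_params()].
#' @param cough_rule [cough_alert_rule()] for B-scale deviation alerts.
#' @param questionnaire [questionnaire_config()].
#' @param indiv_rule [cough_alert_rule()] applied to questionnaire-score
#'   deviations for the individualized questionnaire strategy.
#' @param pre_window,post_window Days before onset / after episode end that
#'   count as exacerbation-associated (both default 8).
#' @param merge_gap Episodes separated by fewer than this many clear days
#'   are merged (default 8).
#' @param min_baseline_days Minimum eligible days for a baseline estimate.
#' @param baseline_method `"median"` (default) or `"mean"`.
#' @param min_correlation_days Minimum paired days per patient for the
#'   self-report vs count correlation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bscale = bscale_params(),
                            cough_rule = cough_alert_rule(),
                            questionnaire = questionnaire_config(),
                            indiv_rule = cough_alert_rule(threshold = 2),
                            pre_window = 8L, post_window = 8L,
                            merge_gap = 8L, min_baseline_days = 7L,
                            baseline_method = c("median", "mean"),
                            min_correlation_days = 10L) {
  stopifnot(inherits(bscale, "bscale_params"),
            inherits(cough_rule, "cough_alert_rule"),
            inherits(questionnaire, "questionnaire_config"),
            inherits(indiv_rule, "cough_alert_rule"))
  pre_window <- check_count(pre_window, "pre_window")
  post_window <- check_count(post_window, "post_window")
  merge_gap <- check_count(merge_gap, "merge_gap")
  structure(list(bscale = bscale, cough_rule = cough_rule,
                 questionnaire = questionnaire, indiv_rule = indiv_rule,
                 pre_window = pre_window, post_window = post_window,
                 merge_gap = merge_gap,
                 min_baseline_days = check_count(min_baseline_days, "min_baseline_days"),
                 baseline_method = match.arg(baseline_method),
                 min_correlation_days = check_count(min_correlation_days, "min_correlation_days")),
            class = "pipeline_config")
}

# ---- internal validators ----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(sprintf("`%s` must be a single positive number.", name))
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    abort(sprintf("`%s` must be a single non-negative integer.", name))
  as.integer(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
    abort(sprintf("`%s` must be a length-2 numeric range with low <= high.", name))
  invisible(x)
}

check_records <- function(records, need = c("patient_id", "day")) {
  if (!is.data.frame(records))
    abort("`records` must be a data frame of daily records.")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    abort(sprintf("`records` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  invisible(records)
}
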