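#' Synthetic cohort configuration
#'
#' Parameters of the seeded cohort generator. Defaults describe a severe,
#' frequently exacerbating COPD telemonitoring cohort followed for 90
#' days: per-patient baseline mean daily cough counts drawn log-uniformly
#' over a wide (5-400) range; overdispersed daily counts whose standard
#' deviation is linear in the mean (`SD = sd_slope * mean +
#' sd_intercept`); about 1.5 treated exacerbations per patient per
#' horizon, each preceded by a multiplicative prodromal ramp in the mean
#' count; questionnaire items coupled to the exacerbation state; and
#' independently missing monitoring days.
#'
#' @param n_patients Number of patients.
#' @param horizon_days Monitoring days per patient (default 90).
#' @param baseline_mean_range Range of per-patient baseline mean daily
#'   counts, sampled log-uniformly.
#' @param sd_slope,sd_intercept Linear SD-mean law of daily counts,
#'   `SD = sd_slope * mean + sd_intercept`; `sd_slope` must be positive.
#' @param exacerbation_rate Expected episodes per patient per horizon
#'   (Poisson).
#' @param prodrome_days Integer range of prodrome lengths (days of rising
#'   mean count before onset).
#' @param prodrome_elevation Multiplicative elevation of the mean count
#'   reached at onset (the ramp is linear on the log scale).
#' @param treatment_days Integer range of treatment durations (episode
#'   lengths).
#' @param recovery_half_life Half-life, in days, of the exponential decay
#'   of the elevation after episode end.
#' @param severe_fraction Probability an episode is severe (hospital
#'   admission at onset).
#' @param missing_day_prob Marginal probability a day's cough count is
#'   missing (device failure). Questionnaire responses are diary-based and
#'   remain present.
#' @param missing_mode `"independent"` (default) or `"burst"`
#'   (two-state Markov chain with mean burst length
#'   `burst_length_mean`, matching the same marginal probability).
#' @param burst_length_mean Mean length of missing bursts in burst mode.
#' @param item_sensitivity,item_specificity Per-item probabilities of a
#'   "yes" during an exacerbation phase (prodrome through episode end) and
#'   of a "no" outside it; scalars or length-8 vectors.
#' @param always_yes_fraction Fraction of patients who answer every item
#'   "yes" every day (observed in practice, and the failure mode of
#'   absolute questionnaire rules).
#' @param seed Integer seed. Each patient gets an RNG stream derived from
#'   `(seed, patient index)`, so cohorts are reproducible under changes in
#'   `n_patients`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 50L, horizon_days = 90L,
                          baseline_mean_range = c(5, 400),
                          sd_slope = 0.25, sd_intercept = 2.5,
                          exacerbation_rate = 1.5,
                          prodrome_days = c(4L, 8L),
                          prodrome_elevation = 8,
                          treatment_days = c(5L, 14L),
                          recovery_half_life = 4,
                          severe_fraction = 0.2,
                          missing_day_prob = 0.05,
                          missing_mode = c("independent", "burst"),
                          burst_length_mean = 3,
                          item_sensitivity = 0.75,
                          item_specificity = 0.8,
                          always_yes_fraction = 0.04,
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 1L)
  horizon_days <- check_count(horizon_days, "horizon_days", min = 1L)
  check_range(baseline_mean_range, "baseline_mean_range")
  if (any(baseline_mean_range <= 0))
    abort("`baseline_mean_range` must be positive.")
  check_positive_scalar(sd_slope, "sd_slope")
  if (!is.numeric(sd_intercept) || sd_intercept < 0)
    abort("`sd_intercept` must be non-negative.")
  if (!is.numeric(exacerbation_rate) || exacerbation_rate < 0)
    abort("`exacerbation_rate` must be non-negative.")
  check_range(prodrome_days, "prodrome_days")
  check_positive_scalar(prodrome_elevation, "prodrome_elevation")
  check_range(treatment_days, "treatment_days")
  if (any(treatment_days < 1)) abort("`treatment_days` must be >= 1.")
  check_positive_scalar(recovery_half_life, "recovery_half_life")
  check_prob(severe_fraction, "severe_fraction")
  check_prob(missing_day_prob, "missing_day_prob")
  check_positive_scalar(burst_length_mean, "burst_length_mean")
  check_prob(item_sensitivity, "item_sensitivity")
  check_prob(item_specificity, "item_specificity")
  if (!length(item_sensitivity) %in% c(1L, 8L))
    abort("`item_sensitivity` must have length 1 or 8.")
  if (!length(item_specificity) %in% c(1L, 8L))
    abort("`item_specificity` must have length 1 or 8.")
  check_prob(always_yes_fraction, "always_yes_fraction")
  seed <- check_count(abs(seed), "seed")
  structure(list(
    n_patients = n_patients, horizon_days = horizon_days,
    baseline_mean_range = baseline_mean_range,
    sd_slope = sd_slope, sd_intercept = sd_intercept,
    exacerbation_rate = exacerbation_rate,
    prodrome_days = as.integer(prodrome_days),
    prodrome_elevation = prodrome_elevation,
    treatment_days = as.integer(treatment_days),
    recovery_half_life = recovery_half_life,
    severe_fraction = severe_fraction,
    missing_day_prob = missing_day_prob,
    missing_mode = match.arg(missing_mode),
    burst_length_mean = burst_length_mean,
    item_sensitivity = rep_len(item_sensitivity, 8L),
    item_specificity = rep_len(item_specificity, 8L),
    always_yes_fraction = always_yes_fraction,
    seed = seed), class = "cohort_config")
}

#' Simulate a telemonitoring cohort
#'
#' Generates daily records and the generating ground truth for a synthetic
#' cohort under a [cohort_config()]. Daily cough counts are negative
#' binomial, parameterised by the day's mean and the linear SD-mean law
#' (`SD = sd_slope * mean + sd_intercept`). Before each episode's onset
#' the log-mean ramps linearly from baseline up to `prodrome_elevation`
#' times baseline at onset; the elevation persists through treatment and
#' decays exponentially afterwards with the configured half-life.
#' Medication flags are set from onset through episode end, a hospital
#' marker is set at onset for severe episodes, and the eight questionnaire
#' items are conditionally independent Bernoulli draws given the
#' exacerbation-phase state. Simulated episodes are kept at least 10 clear
#' days apart so they remain distinct clinical events after merging.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cough_cohort`:
#' \describe{
#'   \item{records}{tibble of patient-days: `patient_id`, `day` (0-based),
#'     `cough_count` (`NA` = missing), `q1`..`q8`, `steroid`,
#'     `antibiotic`, `hospital`.}
#'   \item{patients}{ground-truth patient table: `patient_id`,
#'     `baseline_mean`, `always_yes`.}
#'   \item{episodes}{ground-truth episodes: `patient_id`, `onset`, `end`,
#'     `severity`, `prodrome_start`.}
#' }
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 3, seed = 7))
#' head(coh$records)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sims <- purrr::map(seq_len(config$n_patients),
                     function(i) simulate_patient(config, i))
  structure(list(
    records = bind_rows(purrr::map(sims, "records")),
    patients = bind_rows(purrr::map(sims, "patient")),
    episodes = bind_rows(purrr::map(sims, "episodes"))),
    class = "cough_cohort")
}

#' @export
print.cough_cohort <- function(x, ...) {
  cat(sprintf(
    "<cough_cohort> %d patients x %d days; %d ground-truth episode(s)\n",
    nrow(x$patients), if (nrow(x$patients)) max(x$records$day) + 1L else 0L,
    nrow(x$episodes)))
  invisible(x)
}

# one RNG stream per (seed, patient index)
patient_seed <- function(seed, i) {
  as.integer(((seed %% 65011) * 32717 + i * 7919) %% 2147483647)
}

simulate_patient <- function(config, i) {
  set.seed(patient_seed(config$seed, i))
  h <- config$horizon_days
  pid <- sprintf("P%03d", i)
  mu <- exp(runif(1, log(config$baseline_mean_range[1]),
                  log(config$baseline_mean_range[2])))
  always_yes <- runif(1) < config$always_yes_fraction

  episodes <- place_episodes(config, h)
  days <- 0:(h - 1L)

  # log-scale elevation fraction per day, max over episodes
  frac <- numeric(h)
  steroid <- antibiotic <- hospital <- integer(h)
  state <- logical(h)  # exacerbation phase: prodrome through episode end
  n_ep <- nrow(episodes)
  severity <- character(0)
  if (n_ep) {
    severity <- ifelse(runif(n_ep) < config$severe_fraction,
                       "severe", "moderate")
    for (e in seq_len(n_ep)) {
      onset <- episodes$onset[e]; end <- episodes$end[e]
      d <- episodes$prodrome[e]
      f <- numeric(h)
      ramp_days <- (onset - d):(onset - 1L)
      keep <- ramp_days >= 0
      f[ramp_days[keep] + 1L] <- (ramp_days[keep] - (onset - d)) / d
      f[days >= onset & days <= end] <- 1
      post <- days > end
      f[post] <- 2^(-(days[post] - end) / config$recovery_half_life)
      frac <- pmax(frac, f)
      state <- state | (days >= onset - d & days <= end)
      span <- days >= onset & days <= end
      med <- c(runif(1) < 0.7, runif(1) < 0.6)
      if (!any(med)) med[1] <- TRUE
      if (med[1]) steroid[span] <- 1L
      if (med[2]) antibiotic[span] <- 1L
      if (severity[e] == "severe") hospital[onset + 1L] <- 1L
    }
  }

  mu_t <- mu * config$prodrome_elevation^frac
  sd_t <- config$sd_slope * mu_t + config$sd_intercept
  counts <- draw_nb(mu_t, sd_t)

  miss <- draw_missing(h, config)
  counts[miss] <- NA_integer_

  q <- matrix(0L, nrow = h, ncol = 8)
  if (always_yes) {
    q[] <- 1L
  } else {
    for (j in 1:8) {
      p <- ifelse(state, config$item_sensitivity[j],
                  1 - config$item_specificity[j])
      q[, j] <- rbinom(h, 1L, p)
    }
  }
  colnames(q) <- paste0("q", 1:8)

  records <- tibble(patient_id = pid, day = days,
                    cough_count = as.integer(counts)) |>
    dplyr::bind_cols(as_tibble(q)) |>
    mutate(steroid = steroid, antibiotic = antibiotic, hospital = hospital)

  list(
    records = records,
    patient = tibble(patient_id = pid, baseline_mean = mu,
                     always_yes = always_yes),
    episodes = if (n_ep) {
      tibble(patient_id = pid, onset = episodes$onset, end = episodes$end,
             severity = severity,
             prodrome_start = episodes$onset - episodes$prodrome)
    } else {
      tibble(patient_id = character(), onset = integer(), end = integer(),
             severity = character(), prodrome_start = integer())
    })
}

# non-overlapping episode placement with >= 10 clear days separation
place_episodes <- function(config, h) {
  n_ep <- rpois(1, config$exacerbation_rate)
  placed <- data.frame(onset = integer(), end = integer(),
                       prodrome = integer())
  for (e in seq_len(n_ep)) {
    for (try in 1:100) {
      len <- sample(config$treatment_days[1]:config$treatment_days[2], 1)
      d <- sample(config$prodrome_days[1]:config$prodrome_days[2], 1)
      # keep at least a two-day treatment footprint inside the horizon,
      # so every simulated episode meets the case definition
      onset <- sample(0:(h - 2L), 1)
      end <- min(onset + len - 1L, h - 1L)
      if (nrow(placed) == 0 ||
          all(onset > placed$end + 10L | end < placed$onset - 10L)) {
        placed <- rbind(placed,
                        data.frame(onset = onset, end = end, prodrome = d))
        break
      }
    }
  }
  placed[order(placed$onset), , drop = FALSE]
}

# negative binomial by (mean, SD); Poisson fallback when variance <= mean
draw_nb <- function(mu, sd) {
  v <- sd^2
  out <- integer(length(mu))
  over <- v > mu
  if (any(over)) {
    size <- mu[over]^2 / (v[over] - mu[over])
    out[over] <- rnbinom(sum(over), mu = mu[over], size = size)
  }
  if (any(!over)) out[!over] <- rpois(sum(!over), mu[!over])
  out
}

draw_missing <- function(h, config) {
  p <- config$missing_day_prob
  if (p == 0) return(logical(h))
  if (config$missing_mode == "independent")
    return(runif(h) < p)
  # two-state Markov chain with stationary missing fraction p and mean
  # burst length burst_length_mean
  p_exit <- 1 / config$burst_length_mean
  p_enter <- min(1, p_exit * p / (1 - p))
  miss <- logical(h)
  cur <- runif(1) < p
  for (t in seq_len(h)) {
    miss[t] <- cur
    cur <- if (cur) runif(1) >= p_exit else runif(1) < p_enter
  }
  miss
}
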