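#' Read and write cohort files
#'
#' Plain-CSV serialisation of a cohort. `write_cohort()` writes
#' `records.csv` (one row per patient-day; missing cough counts are empty
#' cells, never zeros), `events.csv` (ground-truth or detected episodes)
#' and `patients.csv` into a directory; `read_cohort()` reads them back.
#' The round trip is the identity, including the missing-day encoding,
#' and writing the same cohort twice produces byte-identical files.
#'
#' The daily-record schema is: `patient_id`, `day` (integer, 0-based from
#' study start), `cough_count` (integer or empty = missing), `q1`..`q8`
#' (0/1), `steroid`, `antibiotic`, `hospital` (0/1).
#'
#' @param cohort A `cough_cohort` (or a list with `records` and optionally
#'   `episodes`/`patients` tibbles).
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `cough_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_records(cohort$records, file.path(dir, "records.csv"))
  if (!is.null(cohort$episodes))
    write_events(cohort$episodes, file.path(dir, "events.csv"))
  if (!is.null(cohort$patients))
    readr::write_csv(cohort$patients, file.path(dir, "patients.csv"),
                     na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- list(records = read_records(file.path(dir, "records.csv")))
  ev_path <- file.path(dir, "events.csv")
  if (file.exists(ev_path)) out$episodes <- read_events(ev_path)
  pat_path <- file.path(dir, "patients.csv")
  if (file.exists(pat_path))
    out$patients <- readr::read_csv(
      pat_path, na = "",
      col_types = readr::cols(patient_id = readr::col_character(),
                              baseline_mean = readr::col_double(),
                              always_yes = readr::col_logical()),
      progress = FALSE)
  structure(out, class = "cough_cohort")
}

#' @rdname write_cohort
#' @param records Daily-record tibble.
#' @param path CSV file path.
#' @export
write_records <- function(records, path) {
  check_records(records, c("patient_id", "day", "cough_count"))
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_records <- function(path) {
  spec <- readr::cols(patient_id = readr::col_character(),
                      day = readr::col_integer(),
                      cough_count = readr::col_integer(),
                      .default = readr::col_integer())
  out <- readr::read_csv(path, na = "", col_types = spec, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs))
    abort(sprintf("malformed daily-record CSV %s: first problem at line %d (expected %s).",
                  path, probs$row[1], probs$expected[1]))
  out
}

#' @rdname write_cohort
#' @param events Event tibble (`patient_id`, `onset`, `end`, `severity`,
#'   and optionally `source` or `prodrome_start`).
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_events <- function(path) {
  parsers <- list(patient_id = readr::col_character(),
                  onset = readr::col_integer(),
                  end = readr::col_integer(),
                  severity = readr::col_character(),
                  source = readr::col_character(),
                  prodrome_start = readr::col_integer())
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE, progress = FALSE))
  spec <- do.call(readr::cols, parsers[intersect(hdr, names(parsers))])
  out <- readr::read_csv(path, na = "", col_types = spec, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs))
    abort(sprintf("malformed events CSV %s: first problem at line %d.",
                  path, probs$row[1]))
  out
}

#' Read a cohort configuration from YAML
#'
#' Reads a [cohort_config()] whose fields are given as YAML keys; missing
#' keys take the package defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort(sprintf("unknown cohort_config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  if (!is.null(seed)) vals$seed <- seed
  do.call(cohort_config, vals)
}
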