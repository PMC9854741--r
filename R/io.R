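#' Read vital-sign observations from CSV
#'
#' The on-disk convention is long-format CSV with columns `patient_id`,
#' `timestamp` (ISO-8601, seconds resolution), `signal` (`PR`, `SPO2`, `RR`)
#' and `value`. Rows that cannot be interpreted — unparseable timestamp,
#' non-numeric or non-positive value, unknown signal, or SpO2 above 100% —
#' are dropped and counted rather than aborting the read, mirroring routine
#' screening of dirty export data.
#'
#' @param path Path to a CSV file.
#' @return A tibble of observations sorted by patient, signal and time, with
#'   attribute `n_rejected` giving the dropped-row count (also reported via
#'   `message()` when non-zero). An empty file yields an empty tibble.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    out <- empty_observations()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  need <- c("patient_id", "timestamp", "signal", "value")
  if (!all(need %in% names(raw))) {
    stop("observations file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ts <- parse_timestamp(raw$timestamp)
  val <- suppressWarnings(as.numeric(raw$value))
  sig <- toupper(trimws(raw$signal))
  ok <- !is.na(ts) & !is.na(val) & val > 0 & sig %in% SIGNALS &
    !(sig == "SPO2" & val > 100)
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    message("read_observations: rejected ", n_rej, " invalid row",
            if (n_rej > 1) "s", " from ", basename(path))
  }
  out <- tibble::tibble(
    patient_id = as.character(raw$patient_id)[ok],
    timestamp = ts[ok],
    signal = sig[ok],
    value = val[ok]
  )
  out <- out[order(out$patient_id, out$signal, out$timestamp), , drop = FALSE]
  attr(out, "n_rejected") <- n_rej
  out
}

#' Read wearable-on-arm facts from CSV
#'
#' @param path CSV with columns `patient_id`, `timestamp`.
#' @return Tibble sorted by patient and time.
#' @export
read_facts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    return(tibble::tibble(patient_id = character(),
                          timestamp = as_time(numeric())))
  }
  if (!all(c("patient_id", "timestamp") %in% names(raw))) {
    stop("facts file must have columns patient_id, timestamp", call. = FALSE)
  }
  ts <- parse_timestamp(raw$timestamp)
  ok <- !is.na(ts)
  out <- tibble::tibble(patient_id = as.character(raw$patient_id)[ok],
                        timestamp = ts[ok])
  out[order(out$patient_id, out$timestamp), , drop = FALSE]
}

#' Read the admission/discharge table from CSV
#'
#' @param path CSV with columns `patient_id`, `admit_timestamp`,
#'   `discharge_timestamp`.
#' @return Tibble, one row per patient.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "admit_timestamp", "discharge_timestamp")
  if (!all(need %in% names(raw))) {
    stop("patients file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    patient_id = as.character(raw$patient_id),
    admit_timestamp = parse_timestamp(raw$admit_timestamp),
    discharge_timestamp = parse_timestamp(raw$discharge_timestamp)
  )
}

#' Read a cohort directory
#'
#' Expects `observations.csv`, `facts.csv` and `patients.csv` under `dir`,
#' as written by [write_cohort()].
#'
#' @param dir Directory path.
#' @return A [vs_cohort()].
#' @export
read_cohort <- function(dir) {
  vs_cohort(
    observations = read_observations(file.path(dir, "observations.csv")),
    facts = read_facts(file.path(dir, "facts.csv")),
    patients = read_patients(file.path(dir, "patients.csv")),
    metadata = list(source = dir)
  )
}

#' Write a cohort to a directory of CSV files
#'
#' @param cohort A [vs_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- cohort$observations
  obs$timestamp <- format_timestamp(obs$timestamp)
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE)
  facts <- cohort$facts
  facts$timestamp <- format_timestamp(facts$timestamp)
  write.csv(facts, file.path(dir, "facts.csv"), row.names = FALSE)
  pat <- cohort$patients
  pat$admit_timestamp <- format_timestamp(pat$admit_timestamp)
  pat$discharge_timestamp <- format_timestamp(pat$discharge_timestamp)
  write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE)
  invisible(dir)
}

REPORT_COLUMNS <- c("ruleset", "observation_rate", "aggregation_window",
                    "W_AP", "patient_rate", "alarm_rate", "alarm_rate_sd",
                    "EDT_median", "EDT_IQR", "included_windows")

#' Write a condition-grid report
#'
#' Serialises the per-condition alarm metrics (one row per ruleset x
#' observation-rate/aggregation-window condition) as twin CSV and JSON
#' files; [read_report()] round-trips either losslessly.
#'
#' @param results Tibble of condition results, as returned by [run_grid()].
#' @param path Output path; the extension is replaced so both `path.csv`
#'   and `path.json` are written (a bare stem is fine).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results) || !nrow(results)) {
    stop("results must be non-empty", call. = FALSE)
  }
  missing_cols <- setdiff(REPORT_COLUMNS, names(results))
  if (length(missing_cols)) {
    stop("results is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stem <- sub("\\.(csv|json)$", "", path)
  out <- as.data.frame(results)[, REPORT_COLUMNS]
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  write.csv(out, csv_path, row.names = FALSE)
  jsonlite::write_json(out, json_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read back a condition-grid report
#'
#' @param path A `.csv` or `.json` report written by [write_report()].
#' @return Tibble of condition results.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    out <- jsonlite::fromJSON(path)
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE)
  }
  for (col in setdiff(REPORT_COLUMNS, c("ruleset", "observation_rate",
                                        "aggregation_window"))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  tibble::as_tibble(out)
}
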