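#' Assemble a monitoring cohort
#'
#' A cohort bundles everything the alarm pipeline needs: the continuous
#' vital-sign observation stream, the wearable-on-arm facts used for
#' adherence, and the admission/discharge record per patient.
#'
#' @param observations Tibble with columns `patient_id`, `timestamp`
#'   (POSIXct), `signal` (one of `"PR"`, `"SPO2"`, `"RR"`) and `value`.
#' @param patients Tibble with columns `patient_id`, `admit_timestamp`,
#'   `discharge_timestamp`.
#' @param facts Tibble with columns `patient_id`, `timestamp`; one row per
#'   wearable-on-arm event.
#' @param metadata Free-form list recording provenance (generator config and
#'   seed, or source files).
#'
#' @return An object of class `vs_cohort`: a list with elements
#'   `observations`, `facts`, `patients`, `metadata`. Observations and facts
#'   are sorted by patient, signal and time.
#' @export
vs_cohort <- function(observations = NULL, patients = NULL, facts = NULL,
                      metadata = list()) {
  observations <- observations %||% empty_observations()
  facts <- facts %||% tibble::tibble(patient_id = character(),
                                     timestamp = as_time(numeric()))
  patients <- patients %||% tibble::tibble(
    patient_id = character(),
    admit_timestamp = as_time(numeric()),
    discharge_timestamp = as_time(numeric())
  )
  observations$timestamp <- as_time(observations$timestamp)
  facts$timestamp <- as_time(facts$timestamp)
  if (nrow(patients)) {
    patients$admit_timestamp <- as_time(patients$admit_timestamp)
    patients$discharge_timestamp <- as_time(patients$discharge_timestamp)
    if (anyDuplicated(patients$patient_id)) {
      stop("duplicate patient_id in patients table", call. = FALSE)
    }
    bad <- patients$discharge_timestamp <= patients$admit_timestamp
    if (any(bad)) {
      stop("discharge_timestamp must be after admit_timestamp for: ",
           paste(patients$patient_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  # observations must fall within [admission - 1 day, discharge + 1 day];
  # out-of-stay rows are dropped with a count (dirty-export tolerance)
  if (nrow(patients) && nrow(observations)) {
    idx <- match(observations$patient_id, patients$patient_id)
    lo <- patients$admit_timestamp[idx] - 86400
    hi <- patients$discharge_timestamp[idx] + 86400
    ok <- is.na(idx) | (observations$timestamp >= lo &
                          observations$timestamp <= hi)
    if (any(!ok)) {
      message("vs_cohort: dropped ", sum(!ok),
              " observation(s) outside the admission window")
      observations <- observations[ok, , drop = FALSE]
    }
  }
  observations <- observations[order(observations$patient_id,
                                     observations$signal,
                                     observations$timestamp), , drop = FALSE]
  facts <- facts[order(facts$patient_id, facts$timestamp), , drop = FALSE]
  structure(
    list(observations = tibble::as_tibble(observations),
         facts = tibble::as_tibble(facts),
         patients = tibble::as_tibble(patients),
         metadata = metadata),
    class = "vs_cohort"
  )
}

empty_observations <- function() {
  tibble::tibble(patient_id = character(),
                 timestamp = as_time(numeric()),
                 signal = character(),
                 value = numeric())
}

#' @export
print.vs_cohort <- function(x, ...) {
  cat("<vs_cohort> ", nrow(x$patients), " patients, ",
      format(nrow(x$observations), big.mark = ","), " observations, ",
      format(nrow(x$facts), big.mark = ","), " wear facts\n", sep = "")
  if (nrow(x$patients)) {
    los <- length_of_stay(x)
    cat("  length of stay: median ", round(median(los$los_days), 2),
        " days\n", sep = "")
  }
  invisible(x)
}

#' Device rates associated with a cohort
#'
#' Returns the per-signal observation rates (obs/min) recorded in the
#' cohort's generator config, or the wearable's nominal rates when the
#' cohort carries no config (e.g. read from disk).
#'
#' @param cohort A [vs_cohort()].
#' @return Named numeric vector over `PR`, `SPO2`, `RR`.
#' @export
cohort_rates <- function(cohort) {
  cfg <- cohort$metadata$config
  if (!is.null(cfg$rates)) cfg$rates else DEVICE_RATES
}

#' Number of patients in a cohort
#' @param cohort A [vs_cohort()].
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Extract one patient's record from a cohort
#'
#' @param cohort A [vs_cohort()].
#' @param patient_id Identifier present in `cohort$patients`.
#' @return A list with `patient_id`, `admit`, `discharge`, `observations`
#'   (tibble for this patient), and `facts`.
#' @export
cohort_patient <- function(cohort, patient_id) {
  row <- cohort$patients[cohort$patients$patient_id == patient_id, ]
  if (!nrow(row)) stop("unknown patient_id: ", patient_id, call. = FALSE)
  list(
    patient_id = patient_id,
    admit = row$admit_timestamp[1],
    discharge = row$discharge_timestamp[1],
    observations = cohort$observations[
      cohort$observations$patient_id == patient_id, , drop = FALSE],
    facts = cohort$facts[cohort$facts$patient_id == patient_id, , drop = FALSE]
  )
}

#' Length of stay
#'
#' The time between admission and discharge, `LoS = T_d - T_a`, in
#' fractional days.
#'
#' @param cohort A [vs_cohort()] (all patients are summarised).
#' @return Tibble with `patient_id` and `los_days`.
#' @export
length_of_stay <- function(cohort) {
  p <- cohort$patients
  tibble::tibble(
    patient_id = p$patient_id,
    los_days = as.numeric(difftime(p$discharge_timestamp, p$admit_timestamp,
                                   units = "days"))
  )
}

#' Length of wear
#'
#' The time between the first and last vital-sign observation of each
#' patient, `L_w = T_vs_f - T_vs_i`, in fractional days. Patients with no
#' observations at all get `NA` (wear is undefined, which is distinct from a
#' zero-length wear produced by a single observation).
#'
#' @param cohort A [vs_cohort()].
#' @return Tibble with `patient_id` and `wear_days`.
#' @export
length_of_wear <- function(cohort) {
  obs <- cohort$observations
  out <- tibble::tibble(patient_id = cohort$patients$patient_id,
                        wear_days = NA_real_)
  if (nrow(obs)) {
    spans <- dplyr::summarise(
      dplyr::group_by(obs, .data$patient_id),
      wear_days = as.numeric(difftime(max(.data$timestamp),
                                      min(.data$timestamp), units = "days")),
      .groups = "drop"
    )
    idx <- match(out$patient_id, spans$patient_id)
    out$wear_days <- spans$wear_days[idx]
  }
  out
}
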