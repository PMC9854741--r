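#' Build 4-hour assessment windows for one patient
#'
#' The stay is divided into consecutive 4-h windows from admission; a
#' trailing partial window is dropped (the inclusion rule needs all
#' sixteen 15-min windows). A window is included in alarm assessment when
#' at least half of its 15-min windows are adherent (>= 8 of 16).
#'
#' @param admit,discharge Stay bounds.
#' @param adherence 15-min grid tibble from [adherence_windows()] computed
#'   on the same admission-aligned grid.
#' @param window_h Assessment window length in hours (default 4).
#' @return Tibble with `start`, `end`, `adherent_quarter_hours`,
#'   `included`.
#' @export
build_assessment_windows <- function(admit, discharge, adherence,
                                     window_h = 4) {
  admit <- as_time(admit); discharge <- as_time(discharge)
  per_window <- as.integer(window_h * 4)  # 15-min windows per assessment
  los_h <- as.numeric(discharge - admit, units = "hours")
  n_aw <- floor(los_h / window_h)
  if (n_aw < 1) {
    return(tibble::tibble(start = as_time(numeric()),
                          end = as_time(numeric()),
                          adherent_quarter_hours = integer(),
                          included = logical()))
  }
  starts <- admit + (seq_len(n_aw) - 1) * window_h * 3600
  grp <- rep(seq_len(n_aw), each = per_window)
  adh <- adherence$adherent[seq_len(n_aw * per_window)]
  counts <- as.integer(tapply(adh, grp, sum))
  tibble::tibble(
    start = starts,
    end = starts + window_h * 3600,
    adherent_quarter_hours = counts,
    included = counts >= ceiling(per_window / 2)
  )
}

#' Assign alarm triggers to assessment windows
#'
#' Groups a trigger timestamp log into the patient's assessment windows
#' (membership is half-open, `[start, end)`). Triggers falling in excluded
#' (low-adherence) windows are discarded. Each included window gains the
#' first (`T_i`) and last (`T_f`) trigger timestamp, the trigger count,
#' and the positive-alarm flag `W_AP` (at least one trigger).
#'
#' @param windows Tibble from [build_assessment_windows()].
#' @param trigger_times POSIXct vector (ruleset-level union, or one
#'   rule's log).
#' @return `windows` with added columns `trigger_count`, `T_i`, `T_f`,
#'   `W_AP`.
#' @export
assign_triggers <- function(windows, trigger_times) {
  n <- nrow(windows)
  windows$trigger_count <- integer(n)
  windows$T_i <- as_time(rep(NA_real_, n))
  windows$T_f <- as_time(rep(NA_real_, n))
  if (n && length(trigger_times)) {
    tt <- sort(as.numeric(trigger_times))
    ws <- as.numeric(windows$start)
    idx <- findInterval(tt, ws)  # window index; 0 = before first window
    step <- as.numeric(windows$end[1]) - ws[1]
    in_window <- idx >= 1 & tt < ws[pmax(idx, 1)] + step
    ok <- in_window & windows$included[pmax(idx, 1)]
    if (any(ok)) {
      first <- tapply(tt[ok], idx[ok], min)
      last <- tapply(tt[ok], idx[ok], max)
      cnt <- tapply(tt[ok], idx[ok], length)
      at <- as.integer(names(first))
      windows$trigger_count[at] <- as.integer(cnt)
      windows$T_i[at] <- as_time(as.numeric(first))
      windows$T_f[at] <- as_time(as.numeric(last))
    }
  }
  windows$W_AP <- windows$trigger_count >= 1
  windows
}

#' Early detection time of positive alarm windows
#'
#' EDT is the time, in hours, between the first trigger in an assessment
#' window and the window's end: 4 h means the ruleset criteria were met at
#' the very start of the window (earliest possible detection), 0 means at
#' the very end. Windows without a trigger get `NA`.
#'
#' @param windows Tibble from [assign_triggers()].
#' @return Numeric vector of EDT hours (length `nrow(windows)`), in
#'   `[0, 4]` where defined.
#' @export
early_detection_time <- function(windows) {
  ifelse(windows$W_AP,
         (as.numeric(windows$end) - as.numeric(windows$T_i)) / 3600,
         NA_real_)
}

#' Alarm metrics for one condition over a cohort
#'
#' Aggregates per-patient assessment windows evaluated under a single
#' (ruleset, observation-rate, aggregation-window) condition into the four
#' headline metrics: total positive alarm windows (`W_AP`), patient rate
#' (% of patients with at least one positive window), alarm rate (mean +/-
#' SD over patients of positive windows per day of stay), and EDT pooled
#' over all positive windows as median (IQR).
#'
#' @param window_list Named list (by patient_id) of assessment-window
#'   tibbles from [assign_triggers()].
#' @param los Tibble with `patient_id`, `los_days` ([length_of_stay()]).
#' @param ruleset_id,observation_rate,aggregation_window Condition labels
#'   stored in the result row.
#' @param denominator `"contributing"` (patients with at least one
#'   included assessment window, default) or `"all"` patients.
#' @return One-row tibble with the report columns.
#' @export
condition_metrics <- function(window_list, los, ruleset_id = NA_character_,
                              observation_rate = NA_character_,
                              aggregation_window = NA_character_,
                              denominator = c("contributing", "all")) {
  denominator <- match.arg(denominator)
  pids <- names(window_list)
  per_patient <- lapply(pids, function(pid) {
    w <- window_list[[pid]]
    inc <- w[w$included, , drop = FALSE]
    list(n_included = nrow(inc),
         n_wap = sum(inc$W_AP),
         edt = early_detection_time(inc))
  })
  n_included <- vapply(per_patient, `[[`, numeric(1), "n_included")
  n_wap <- vapply(per_patient, `[[`, numeric(1), "n_wap")
  contributing <- n_included > 0
  denom <- if (denominator == "contributing") sum(contributing) else
    length(pids)
  if (denom == 0 || sum(n_included) == 0) {
    warning("no included assessment windows under this condition",
            call. = FALSE)
  }
  wap_total <- sum(n_wap)
  patient_rate <- if (denom > 0) 100 * sum(n_wap > 0) / denom else NA_real_
  los_days <- los$los_days[match(pids, los$patient_id)]
  rates <- (n_wap / los_days)[contributing]
  edt_all <- unlist(lapply(per_patient, `[[`, "edt"))
  edt_all <- edt_all[!is.na(edt_all)]
  tibble::tibble(
    ruleset = ruleset_id,
    observation_rate = observation_rate,
    aggregation_window = aggregation_window,
    W_AP = wap_total,
    patient_rate = patient_rate,
    alarm_rate = if (length(rates)) mean(rates) else NA_real_,
    alarm_rate_sd = if (length(rates) > 1) sd(rates) else NA_real_,
    EDT_median = if (length(edt_all)) median(edt_all) else NA_real_,
    EDT_IQR = if (length(edt_all))
      unname(diff(quantile(edt_all, c(0.25, 0.75)))) else NA_real_,
    included_windows = sum(n_included)
  )
}
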