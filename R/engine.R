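#' Evaluate one alarm rule against a patient's streams
#'
#' Single-signal rules trigger at every observation timestamp whose value
#' breaches the condition. Combination rules anchor on the rule's
#' first-listed signal: a trigger is logged at a breaching observation time
#' `t` of that signal when every other condition has a breaching
#' observation within the overlap window of `t` (`"anchor"` semantics,
#' pairwise to the anchor; the maximum spread across a three-signal rule is
#' therefore twice the overlap). `"span"` semantics instead require the
#' anchor and its nearest breaching partners to fit inside one overlap-wide
#' interval. No refractory period is applied — downstream assessment
#' windows binarise alarm activity anyway.
#'
#' @param rule An [alarm_rule()].
#' @param streams Named list of per-signal tibbles (`PR`, `SPO2`, `RR`),
#'   each with `timestamp` and `value`, time-sorted. Signals the rule needs
#'   but that are absent (or empty) mean the rule cannot fire.
#' @param overlap_mode `"anchor"` (default) or `"span"`.
#' @return POSIXct vector of trigger timestamps (a subset of the anchor
#'   signal's observation timestamps).
#' @export
evaluate_rule <- function(rule, streams, overlap_mode = c("anchor", "span")) {
  overlap_mode <- match.arg(overlap_mode)
  conds <- rule$conditions
  breach_times <- lapply(conds, function(cond) {
    s <- streams[[cond$signal]]
    if (is.null(s) || !nrow(s)) return(numeric())
    as.numeric(s$timestamp[condition_met(cond, s$value)])
  })
  anchor <- breach_times[[1]]
  if (length(conds) == 1 || !length(anchor)) {
    return(as_time(anchor))
  }
  keep <- rep(TRUE, length(anchor))
  gaps <- matrix(0, nrow = length(anchor), ncol = length(conds) - 1)
  for (j in seq_along(conds)[-1]) {
    other <- breach_times[[j]]
    if (!length(other)) return(as_time(numeric()))
    # distance from each anchor time to the nearest breaching time of the
    # other signal (both series sorted)
    i_prev <- findInterval(anchor, other)
    d_prev <- ifelse(i_prev >= 1, anchor - other[pmax(i_prev, 1)], Inf)
    i_next <- pmin(i_prev + 1, length(other))
    d_next <- ifelse(i_prev + 1 <= length(other), other[i_next] - anchor, Inf)
    nearest <- pmin(d_prev, d_next)
    keep <- keep & nearest <= rule$overlap_s
    gaps[, j - 1] <- ifelse(d_prev <= d_next, -d_prev, d_next)
  }
  if (overlap_mode == "span" && ncol(gaps) > 1) {
    # nearest partners must fit, with the anchor, in one overlap-wide span
    lo <- pmin(0, apply(gaps, 1, min))
    hi <- pmax(0, apply(gaps, 1, max))
    keep <- keep & (hi - lo) <= rule$overlap_s
  }
  as_time(anchor[keep])
}

#' Run a full ruleset over a patient's streams
#'
#' Produces the trigger timestamp log: per-rule trigger times plus the
#' ruleset-level union (each distinct timestamp retained once).
#'
#' @param ruleset An [alarm_ruleset()].
#' @param streams Named list of per-signal stream tibbles (see
#'   [evaluate_rule()]).
#' @param overlap_mode Passed to [evaluate_rule()].
#' @return A `trigger_log`: list with `ruleset_id`, `by_rule` (named list
#'   of POSIXct vectors) and `triggers` (sorted unique union, POSIXct).
#' @export
run_ruleset <- function(ruleset, streams, overlap_mode = "anchor") {
  by_rule <- lapply(ruleset$rules, evaluate_rule, streams = streams,
                    overlap_mode = overlap_mode)
  names(by_rule) <- vapply(ruleset$rules, function(r) r$rule_id, character(1))
  all_t <- sort(unique(as.numeric(unlist(by_rule, use.names = FALSE))))
  structure(list(ruleset_id = ruleset$ruleset_id,
                 by_rule = by_rule,
                 triggers = as_time(all_t)),
            class = "trigger_log")
}

#' @export
print.trigger_log <- function(x, ...) {
  cat("<trigger_log> ruleset ", x$ruleset_id, ": ",
      length(x$triggers), " union triggers (",
      paste(sprintf("%s: %d", names(x$by_rule),
                    vapply(x$by_rule, length, integer(1))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Split a cohort's observations into per-signal streams by patient
#'
#' @param cohort A [vs_cohort()].
#' @return Named list (by patient_id) of named lists (by signal) of stream
#'   tibbles.
#' @export
patient_streams <- function(cohort) {
  obs <- cohort$observations
  out <- lapply(cohort$patients$patient_id, function(pid) {
    po <- obs[obs$patient_id == pid, , drop = FALSE]
    sapply(SIGNALS, function(sig) {
      po[po$signal == sig, c("timestamp", "value"), drop = FALSE]
    }, simplify = FALSE)
  })
  names(out) <- cohort$patients$patient_id
  out
}
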