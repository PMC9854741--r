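#' Build a single vital-sign condition
#'
#' A condition is one comparison against a signal: a strict or inclusive
#' one-sided threshold (`lt`, `le`, `gt`, `ge`) or an inclusive range
#' (`between`). Boundary semantics are preserved exactly: `SpO2 <= 91`
#' fires at 91.0 while `SpO2 < 92` fires at 91.99 but not 92.0.
#'
#' @param signal One of `"PR"`, `"SPO2"`, `"RR"`.
#' @param op One of `"lt"`, `"le"`, `"gt"`, `"ge"`, `"between"`.
#' @param value Threshold for the one-sided operators.
#' @param lower,upper Inclusive bounds for `between`.
#' @return A `vital_condition` list.
#' @export
vital_condition <- function(signal, op, value = NULL, lower = NULL,
                            upper = NULL) {
  signal <- match.arg(signal, SIGNALS)
  op <- match.arg(op, c("lt", "le", "gt", "ge", "between"))
  if (op == "between") {
    stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
    cond <- list(signal = signal, op = op, lower = lower, upper = upper)
  } else {
    stopifnot(is.numeric(value))
    cond <- list(signal = signal, op = op, value = value)
  }
  structure(cond, class = "vital_condition")
}

condition_met <- function(cond, values) {
  switch(cond$op,
         lt = values < cond$value,
         le = values <= cond$value,
         gt = values > cond$value,
         ge = values >= cond$value,
         between = values >= cond$lower & values <= cond$upper)
}

format_condition <- function(cond) {
  if (cond$op == "between") {
    sprintf("%s <= %s <= %s", cond$lower, cond$signal, cond$upper)
  } else {
    op <- c(lt = "<", le = "<=", gt = ">", ge = ">=")[[cond$op]]
    sprintf("%s %s %s", cond$signal, op, cond$value)
  }
}

#' Build an alarm rule
#'
#' A rule holds one condition per involved signal (one to three signals).
#' Multi-signal (combination) rules fire only when all conditions are
#' breached within the overlap window of one another.
#'
#' @param rule_id Identifier, e.g. `"A2-01"`.
#' @param conditions List of [vital_condition()]s, at most one per signal.
#' @param overlap_s Overlap window in seconds for combination rules
#'   (default 30); ignored for single-signal rules.
#' @return An `alarm_rule` list.
#' @export
alarm_rule <- function(rule_id, conditions, overlap_s = 30) {
  if (inherits(conditions, "vital_condition")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1, length(conditions) <= 3)
  sigs <- vapply(conditions, function(c) c$signal, character(1))
  if (anyDuplicated(sigs)) {
    stop("at most one condition per signal in a rule", call. = FALSE)
  }
  structure(list(rule_id = rule_id, conditions = conditions,
                 overlap_s = overlap_s),
            class = "alarm_rule")
}

#' Build an alarm ruleset
#'
#' @param ruleset_id Identifier (`"A1"`, `"A2"`, `"A3"`, or custom).
#' @param rules List of [alarm_rule()]s with unique ids.
#' @return An `alarm_ruleset` list.
#' @export
alarm_ruleset <- function(ruleset_id, rules) {
  ids <- vapply(rules, function(r) r$rule_id, character(1))
  if (anyDuplicated(ids)) stop("rule_ids must be unique", call. = FALSE)
  structure(list(ruleset_id = ruleset_id, rules = rules),
            class = "alarm_ruleset")
}

#' @export
print.alarm_ruleset <- function(x, ...) {
  cat("<alarm_ruleset> ", x$ruleset_id, " (", length(x$rules), " rules)\n",
      sep = "")
  for (r in x$rules) {
    cat("  ", r$rule_id, ": ",
        paste(vapply(r$conditions, format_condition, character(1)),
              collapse = " & "),
        if (length(r$conditions) > 1) sprintf("  [overlap %ds]", r$overlap_s),
        "\n", sep = "")
  }
  invisible(x)
}

between <- function(signal, lower, upper) {
  vital_condition(signal, "between", lower = lower, upper = upper)
}

#' Built-in alarm rulesets
#'
#' Three rulesets spanning common track-and-trigger practice:
#' * `A1` — a subset of NEWS2 threshold bands: five single-signal rules
#'   (RR < 9, RR > 24, SpO2 <= 91, PR < 41, PR > 130) and five three-signal
#'   combination rules over NEWS2 scoring bands.
#' * `A2` — five conventional single-signal rules (SpO2 < 92, PR > 100,
#'   PR < 60, RR > 20, RR < 10).
#' * `A3` — a conservative set: three combination rules and a single
#'   bradycardia rule (PR < 45).
#'
#' @param id `"A1"`, `"A2"` or `"A3"`.
#' @return An [alarm_ruleset()].
#' @export
builtin_ruleset <- function(id) {
  id <- match.arg(id, c("A1", "A2", "A3"))
  switch(id,
    A1 = alarm_ruleset("A1", list(
      alarm_rule("A1-01", vital_condition("RR", "lt", 9)),
      alarm_rule("A1-02", vital_condition("RR", "gt", 24)),
      alarm_rule("A1-03", vital_condition("SPO2", "le", 91)),
      alarm_rule("A1-04", vital_condition("PR", "lt", 41)),
      alarm_rule("A1-05", vital_condition("PR", "gt", 130)),
      alarm_rule("A1-06", list(between("RR", 9, 11), between("SPO2", 92, 93),
                               between("PR", 111, 130))),
      alarm_rule("A1-07", list(between("RR", 21, 24), between("SPO2", 92, 93),
                               between("PR", 91, 110))),
      alarm_rule("A1-08", list(between("RR", 21, 24), between("SPO2", 94, 95),
                               between("PR", 111, 130))),
      alarm_rule("A1-09", list(between("RR", 21, 24), between("SPO2", 92, 93),
                               between("PR", 111, 130))),
      alarm_rule("A1-10", list(between("RR", 21, 24), between("SPO2", 92, 93),
                               between("PR", 41, 50)))
    )),
    A2 = alarm_ruleset("A2", list(
      alarm_rule("A2-01", vital_condition("SPO2", "lt", 92)),
      alarm_rule("A2-02", vital_condition("PR", "gt", 100)),
      alarm_rule("A2-03", vital_condition("PR", "lt", 60)),
      alarm_rule("A2-04", vital_condition("RR", "gt", 20)),
      alarm_rule("A2-05", vital_condition("RR", "lt", 10))
    )),
    A3 = alarm_ruleset("A3", list(
      alarm_rule("A3-01", list(vital_condition("RR", "gt", 25),
                               vital_condition("PR", "gt", 90))),
      alarm_rule("A3-02", list(vital_condition("RR", "gt", 25),
                               vital_condition("SPO2", "lt", 90))),
      alarm_rule("A3-03", list(vital_condition("RR", "lt", 10),
                               vital_condition("SPO2", "lt", 90))),
      alarm_rule("A3-04", vital_condition("PR", "lt", 45))
    ))
  )
}

#' Read an alarm ruleset from JSON
#'
#' Schema: `{"id": ..., "rules": [{"rule_id", "overlap_s", "conditions":
#' [{"signal", "op", "value"} or {"signal", "op": "between", "lower",
#' "upper"}]}]}` — custom thresholds are configuration, not code.
#'
#' @param path JSON file path.
#' @return An [alarm_ruleset()].
#' @export
read_ruleset <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(spec$rules, function(r) {
    conds <- lapply(r$conditions, function(cn) {
      if (identical(cn$op, "between")) {
        vital_condition(cn$signal, "between", lower = cn$lower,
                        upper = cn$upper)
      } else {
        vital_condition(cn$signal, cn$op, value = cn$value)
      }
    })
    alarm_rule(r$rule_id, conds, overlap_s = r$overlap_s %||% 30)
  })
  alarm_ruleset(spec$id, rules)
}

#' Write an alarm ruleset to JSON
#'
#' @param ruleset An [alarm_ruleset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  spec <- list(
    id = ruleset$ruleset_id,
    rules = lapply(ruleset$rules, function(r) {
      list(rule_id = r$rule_id, overlap_s = r$overlap_s,
           conditions = lapply(r$conditions, unclass))
    })
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
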