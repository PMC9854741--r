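#' Published benchmark alarm metrics
#'
#' The alarm-metric grid reported for a 76-patient healthcare-at-home
#' cohort evaluated with this pipeline design (three rulesets x eight
#' observation-rate/aggregation-window conditions; 3270 included 4-h
#' assessment windows). Shipped so that condition-to-condition comparisons
#' can be recomputed from the printed grid; the underlying patient data
#' are not redistributable, so these rows are reference numbers, not
#' package output.
#'
#' @return List with `metrics` (24-row tibble: `ruleset`, `condition`,
#'   `observation_rate`, `aggregation_window`, `W_AP`, `patient_rate`,
#'   `alarm_rate`, `alarm_rate_sd`, `EDT_median`, `EDT_IQR`),
#'   `assessed_windows` (3270) and `n_patients` (76).
#' @export
reference_alarm_metrics <- function() {
  path <- system.file("extdata", "reference_alarm_metrics.csv",
                      package = "alarmsim")
  m <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  list(metrics = m, assessed_windows = 3270L, n_patients = 76L)
}

lookup_cell <- function(metrics, ruleset, condition, metric) {
  row <- metrics[metrics$ruleset == ruleset & metrics$condition == condition, ]
  if (nrow(row) != 1) {
    stop("no unique row for ruleset ", ruleset, ", condition ", condition,
         call. = FALSE)
  }
  row[[metric]]
}

#' Difference of one alarm metric between two conditions
#'
#' Recomputes condition-to-condition comparisons from a metrics grid, e.g.
#' how much earlier a 15-min schedule detects than a 4-h schedule
#' (`condition_delta(m, "EDT_median", "A1", "VS_4", "VS_15")`), or how far
#' the patient rate falls between a 15-min and a 4-h aggregation window.
#'
#' @param metrics Metrics tibble with `ruleset`, `condition` and metric
#'   columns ([reference_alarm_metrics()]`$metrics` or a grid produced by
#'   [run_grid()] after adding a `condition` label).
#' @param metric Column name, e.g. `"W_AP"`, `"patient_rate"`,
#'   `"alarm_rate"`, `"EDT_median"`.
#' @param ruleset Ruleset id.
#' @param from,to Condition labels; the delta is `to - from`.
#' @param pct If TRUE, return the percent change relative to `from`.
#' @return A single number.
#' @export
condition_delta <- function(metrics, metric, ruleset, from, to, pct = FALSE) {
  a <- lookup_cell(metrics, ruleset, from, metric)
  b <- lookup_cell(metrics, ruleset, to, metric)
  if (pct) 100 * (b - a) / a else b - a
}

#' Change in positive-window share between two conditions
#'
#' Expresses the change in `W_AP` between two conditions as a percentage
#' of the total number of assessed windows, the form in which
#' rate-vs-schedule comparisons are usually quoted.
#'
#' @inheritParams condition_delta
#' @param total_windows Total included assessment windows across the
#'   evaluation (3270 for the reference grid).
#' @return Percentage-point change in the share of positive windows.
#' @export
wap_share_change <- function(metrics, ruleset, from, to, total_windows) {
  100 * (lookup_cell(metrics, ruleset, to, "W_AP") -
           lookup_cell(metrics, ruleset, from, "W_AP")) / total_windows
}

#' Per-condition percent reduction of a metric between two rulesets
#'
#' For every condition present in both rulesets, computes
#' `100 * (a - b) / a` — the percent reduction achieved by ruleset `b`
#' relative to ruleset `a` (e.g. combination-heavy A3 vs single-signal
#' A2).
#'
#' @inheritParams condition_delta
#' @param ruleset_a,ruleset_b Ruleset ids (reduction of `b` relative to
#'   `a`).
#' @return Tibble with `condition` and `reduction_pct`.
#' @export
ruleset_reduction <- function(metrics, metric, ruleset_a, ruleset_b) {
  conds <- intersect(metrics$condition[metrics$ruleset == ruleset_a],
                     metrics$condition[metrics$ruleset == ruleset_b])
  red <- vapply(conds, function(cn) {
    a <- lookup_cell(metrics, ruleset_a, cn, metric)
    b <- lookup_cell(metrics, ruleset_b, cn, metric)
    100 * (a - b) / a
  }, numeric(1))
  tibble::tibble(condition = conds, reduction_pct = unname(red))
}

#' Attach the short condition label to a grid result
#'
#' Maps (`observation_rate`, `aggregation_window`) report labels back to
#' the compact condition names (`VS_12` ... `AW_4`) used by the delta
#' helpers.
#'
#' @param results Tibble from [run_grid()].
#' @return `results` with a `condition` column.
#' @export
label_conditions <- function(results) {
  cond <- ifelse(results$observation_rate == "VS_OD",
                 results$aggregation_window, results$observation_rate)
  tibble::add_column(results, condition = cond, .after = "ruleset")
}
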