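#' Full evaluation report for a scored cohort
#'
#' Runs the evaluation layer end to end: overall and stratified
#' standardised incidence ratios (by sex, age group, family history and
#' risk quantiles of both horizons), ROC discrimination, the calibration
#' slope for the 10-year risk, and the likelihood-ratio comparison of the
#' family-history-only model against the combined model.
#'
#' @param scores a `risk_score_set` from [score_cohort()].
#' @param cohort cohort data frame with outcome columns (`case_status`,
#'   `followup_years`).
#' @param incidence incidence [rate_table()].
#' @param k number of quantile strata, default 5.
#' @param max_followup_years follow-up truncation for the SIRs, default
#'   10.
#' @return List with elements `overall`, `by_sex`, `by_age_group`,
#'   `by_fh`, `quantiles_10y`, `quantiles_lifetime` (data frames of SIR
#'   rows), `auc_10y`, `auc_lifetime`, `calibration_10y`,
#'   `model_comparison`.
#' @export
evaluate_cohort <- function(scores, cohort, incidence, k = 5,
                            max_followup_years = 10) {
  stopifnot(nrow(scores) == nrow(cohort))
  strat <- function(by, measure = "risk_10y") {
    sir_table(stratified_sir(scores, cohort, incidence, stratify_by = by,
                             measure = measure, k = k,
                             max_followup_years = max_followup_years))
  }
  y <- cohort$case_status
  cal <- tryCatch(calibration_slope(y, pmin(pmax(scores$risk_10y, 1e-12),
                                            1 - 1e-12)),
                  error = function(e) list(error = conditionMessage(e)))
  cmp <- tryCatch(compare_nested_models(y, scores$fh_rr, scores$combined_rr),
                  error = function(e) list(error = conditionMessage(e)))
  list(
    overall = strat("overall"),
    by_sex = strat("sex"),
    by_age_group = strat("age_group"),
    by_fh = strat("fh"),
    quantiles_10y = strat("quantile", "risk_10y"),
    quantiles_lifetime = strat("quantile", "risk_lifetime"),
    auc_10y = unclass(auc(y, scores$risk_10y)),
    auc_lifetime = unclass(auc(y, scores$risk_lifetime)),
    calibration_10y = if (inherits(cal, "calibration_result")) unclass(cal) else cal,
    model_comparison = cmp
  )
}
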