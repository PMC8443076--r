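#' Expected case count from population rates and cohort person-time
#'
#' Accumulates, over each individual's follow-up, person-time in each
#' (sex, year-of-age) cell multiplied by the population incidence rate of
#' that cell. The final partial year contributes exact fractional
#' person-years. Follow-up is truncated at `max_followup_years` when
#' given (e.g. 10 for a 10-year standardised incidence ratio).
#'
#' @param cohort data frame with columns `sex`, `age_at_entry`,
#'   `followup_years`.
#' @param incidence incidence [rate_table()].
#' @param max_followup_years optional truncation of follow-up time.
#' @return Expected number of cases (positive real).
#' @export
expected_cases <- function(cohort, incidence, max_followup_years = NULL) {
  fu <- cohort$followup_years
  if (any(fu < 0)) stop("followup_years must be non-negative")
  if (!is.null(max_followup_years)) fu <- pmin(fu, max_followup_years)
  total <- 0
  for (s in unique(cohort$sex)) {
    sel <- cohort$sex == s
    ages0 <- cohort$age_at_entry[sel]
    t <- fu[sel]
    n_years <- max(ceiling(t))
    if (n_years == 0) next
    max_age <- max(ages0 + ceiling(t)) - 1L
    rates <- get_rates(incidence, s, seq.int(min(ages0), max_age))
    off <- min(ages0)
    # person-years in year k of follow-up: min(max(t - k, 0), 1)
    for (k in seq_len(n_years) - 1L) {
      py <- pmin(pmax(t - k, 0), 1)
      live <- py > 0
      total <- total + sum(py[live] * rates[ages0[live] + k - off + 1L])
    }
  }
  total
}

#' Standardised incidence ratio with Poisson log-likelihood CI
#'
#' SIR = O / E with confidence interval
#' `exp(log(O/E) +/- z * 1/sqrt(O))`, the quadratic approximation to the
#' Poisson log likelihood for the log-rate parameter. With `O = 0` the
#' point estimate is 0 and the interval is `[0, upper]` with the exact
#' Poisson upper limit `qgamma(1 - (1 - conf_level)/2, 1) / E`, flagged
#' via the `zero_observed` field.
#'
#' @param observed non-negative integer count of observed cases.
#' @param expected positive expected count.
#' @param conf_level confidence level, default 0.95.
#' @param label optional stratum label.
#' @return Object of class `sir_result`: `label`, `observed`, `expected`,
#'   `sir`, `ci_low`, `ci_high`, `zero_observed`.
#' @examples
#' sir(2992, 3253.20)  # 0.92 (0.88-0.95)
#' @export
sir <- function(observed, expected, conf_level = 0.95, label = "") {
  if (observed < 0 || expected <= 0) {
    stop("observed must be >= 0 and expected > 0")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- observed / expected
  if (observed == 0) {
    res <- list(label = label, observed = observed, expected = expected,
                sir = 0, ci_low = 0,
                ci_high = stats::qgamma(1 - (1 - conf_level) / 2, 1) / expected,
                zero_observed = TRUE)
  } else {
    half <- z / sqrt(observed)
    res <- list(label = label, observed = observed, expected = expected,
                sir = est, ci_low = est * exp(-half),
                ci_high = est * exp(half), zero_observed = FALSE)
  }
  class(res) <- "sir_result"
  res
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf("%sSIR = %.2f (O = %d, E = %.2f, 95%% CI %.2f-%.2f)%s\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$sir, x$observed, x$expected, x$ci_low, x$ci_high,
              if (x$zero_observed) " [zero observed]" else ""))
  invisible(x)
}

#' Collect a list of sir_result objects into a data frame
#' @param results list of `sir_result` objects.
#' @return Data frame with one row per stratum.
#' @export
sir_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label, observed = r$observed, expected = r$expected,
               sir = r$sir, ci_low = r$ci_low, ci_high = r$ci_high,
               stringsAsFactors = FALSE)
  }))
}

# Rank-based group assignment for quantile strata: stable ties on input
# order, boundary individuals to the lower stratum.
quantile_groups <- function(x, k) {
  n <- length(x)
  rnk <- order(order(x))            # ties broken by original position
  ceiling(rnk * k / n)
}

#' Standardised incidence ratios by cohort stratum
#'
#' Partitions the cohort by the requested rule and computes one SIR per
#' stratum. Quantile strata are rank-based with ties broken by input
#' order, so strata partition the cohort exactly.
#'
#' @param scores a `risk_score_set` (from [score_cohort()]) aligned with
#'   `cohort`, or `NULL` for rules not using a risk measure.
#' @param cohort data frame with `sex`, `age_at_entry`, `n_affected_fdr`,
#'   `case_status`, `followup_years`.
#' @param incidence incidence [rate_table()].
#' @param stratify_by one of `"quantile"`, `"top_fraction"`,
#'   `"bottom_fraction"`, `"fh"`, `"sex"`, `"age_group"`, `"overall"`.
#' @param measure column of `scores` to stratify on (e.g. `"risk_10y"`,
#'   `"risk_lifetime"`); required for quantile/fraction rules.
#' @param k number of quantile strata (default 5).
#' @param fraction tail fraction for top/bottom rules (default 0.1).
#' @param max_followup_years passed to [expected_cases()].
#' @param conf_level confidence level for the CIs.
#' @return List of `sir_result` objects, one per stratum.
#' @export
stratified_sir <- function(scores, cohort, incidence,
                           stratify_by = c("quantile", "top_fraction",
                                           "bottom_fraction", "fh", "sex",
                                           "age_group", "overall"),
                           measure = "risk_10y", k = 5, fraction = 0.1,
                           max_followup_years = NULL, conf_level = 0.95) {
  stratify_by <- match.arg(stratify_by)
  if (stratify_by %in% c("quantile", "top_fraction", "bottom_fraction")) {
    if (is.null(scores) || !measure %in% names(scores)) {
      stop("scores with column '", measure, "' required for rule ", stratify_by)
    }
    if (nrow(scores) != nrow(cohort)) stop("scores and cohort not aligned")
    x <- scores[[measure]]
  }
  grp <- switch(stratify_by,
    overall = rep("overall", nrow(cohort)),
    quantile = sprintf("%s %02d/%d", measure, quantile_groups(x, k), k),
    top_fraction = ifelse(order(order(-x)) <= ceiling(fraction * length(x)),
                          sprintf("top %d%%", round(100 * fraction)), NA),
    bottom_fraction = ifelse(order(order(x)) <= ceiling(fraction * length(x)),
                             sprintf("bottom %d%%", round(100 * fraction)), NA),
    fh = paste0("fdr", pmin(cohort$n_affected_fdr, 2)),
    sex = as.character(cohort$sex),
    age_group = cut(cohort$age_at_entry, c(40, 50, 60, 70),
                    right = FALSE, labels = c("40-49", "50-59", "60-69"))
  )
  keep <- !is.na(grp)
  grp <- as.character(grp[keep])
  sub <- cohort[keep, , drop = FALSE]
  out <- lapply(sort(unique(grp)), function(lab) {
    sel <- grp == lab
    if (!any(sel)) stop("empty stratum: ", lab)
    obs <- sum(sub$case_status[sel])
    exp_ <- expected_cases(sub[sel, , drop = FALSE], incidence,
                           max_followup_years)
    sir(obs, exp_, conf_level = conf_level, label = lab)
  })
  out
}

#' ROC area under the curve with DeLong confidence interval
#'
#' Mann-Whitney AUC (probability a random case outscores a random
#' control, ties counted one half) with a DeLong CI.
#'
#' @param case_status binary vector (1 = case).
#' @param score numeric risk score.
#' @param conf_level confidence level, default 0.95.
#' @return Object of class `discrimination_result`: `auc`, `ci_low`,
#'   `ci_high`.
#' @export
auc <- function(case_status, score, conf_level = 0.95) {
  if (length(unique(case_status)) < 2) {
    stop("need at least one case and one control")
  }
  roc <- pROC::roc(response = case_status, predictor = score,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(roc, conf.level = conf_level, method = "delong")
  res <- list(auc = as.numeric(pROC::auc(roc)),
              ci_low = max(0, ci[1]), ci_high = min(1, ci[3]))
  class(res) <- "discrimination_result"
  res
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci_low, x$ci_high))
  invisible(x)
}

#' Calibration slope (dispersion coefficient)
#'
#' No-intercept logistic regression of observed case status on the
#' log-odds of the model's predicted probability. A slope of 1 indicates
#' well-dispersed predictions; under the standard convention a slope > 1
#' means predictions are too moderate (under-dispersed) and a slope < 1
#' too extreme. The p-value is a two-sided Wald test of the null that the
#' slope equals 1.
#'
#' @param case_status binary vector (1 = case).
#' @param predicted_prob predicted probabilities, strictly in (0, 1).
#' @param conf_level confidence level, default 0.95.
#' @return Object of class `calibration_result`: `slope`, `se`, `ci_low`,
#'   `ci_high`, `p_vs_one`.
#' @export
calibration_slope <- function(case_status, predicted_prob, conf_level = 0.95) {
  if (any(predicted_prob <= 0) || any(predicted_prob >= 1)) {
    stop("predicted_prob must be strictly in (0, 1)")
  }
  lo <- stats::qlogis(predicted_prob)
  if (stats::sd(lo) == 0) {
    stop("degenerate predictor: all predicted probabilities identical")
  }
  fit <- stats::glm(case_status ~ lo - 1, family = stats::binomial())
  if (!fit$converged) stop("calibration regression did not converge")
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- list(slope = beta, se = se,
              ci_low = beta - z * se, ci_high = beta + z * se,
              p_vs_one = 2 * stats::pnorm(-abs(beta - 1) / se))
  class(res) <- "calibration_result"
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration slope = %.3f (95%% CI %.3f-%.3f), p[slope=1] = %.4g\n",
              x$slope, x$ci_low, x$ci_high, x$p_vs_one))
  invisible(x)
}

#' Likelihood-ratio comparison of family-history vs combined model
#'
#' Fits a logistic model of case status on the log family-history score
#' and a nested model adding the polygenic term
#' `log(score_combined / score_fh)`; returns the likelihood-ratio
#' chi-square with 1 degree of freedom. Identical scores give chi-square
#' 0.
#'
#' @param case_status binary vector.
#' @param score_fh positive family-history relative-risk scores.
#' @param score_combined positive combined relative-risk scores.
#' @return List: `chisq`, `df`, `p`.
#' @export
compare_nested_models <- function(case_status, score_fh, score_combined) {
  if (any(score_fh <= 0) || any(score_combined <= 0)) {
    stop("scores must be positive")
  }
  l_fh <- log(score_fh)
  l_add <- log(score_combined) - l_fh
  if (stats::sd(l_add) == 0) {
    return(list(chisq = 0, df = 1L, p = 1))
  }
  fit0 <- stats::glm(case_status ~ l_fh, family = stats::binomial())
  fit1 <- stats::glm(case_status ~ l_fh + l_add, family = stats::binomial())
  if (!fit0$converged || !fit1$converged) {
    stop("nested-model logistic fits did not converge (separation?)")
  }
  chisq <- as.numeric(2 * (stats::logLik(fit1) - stats::logLik(fit0)))
  chisq <- max(chisq, 0)
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Sequential eligibility waterfall
#'
#' Applies named filters in order and reports how many records remain and
#' how many were dropped at each step.
#'
#' @param records a data frame.
#' @param filters named list of predicate functions, each taking the data
#'   frame and returning a logical keep-vector.
#' @return Data frame: `filter`, `n_remaining`, `n_dropped`; first row is
#'   the unfiltered count.
#' @export
eligibility_waterfall <- function(records, filters) {
  if (is.null(names(filters)) || any(!nzchar(names(filters)))) {
    stop("filters must be a named list")
  }
  out <- data.frame(filter = "(all records)", n_remaining = nrow(records),
                    n_dropped = 0L, stringsAsFactors = FALSE)
  for (nm in names(filters)) {
    keep <- filters[[nm]](records)
    if (!is.logical(keep) || length(keep) != nrow(records)) {
      stop("filter '", nm, "' must return one logical per record")
    }
    keep[is.na(keep)] <- FALSE
    dropped <- sum(!keep)
    records <- records[keep, , drop = FALSE]
    out <- rbind(out, data.frame(filter = nm, n_remaining = nrow(records),
                                 n_dropped = dropped,
                                 stringsAsFactors = FALSE))
  }
  attr(out, "final_records") <- records
  out
}

#' Association between family history and the PRS
#'
#' Logistic regression of an any-family-history indicator on the PRS;
#' returns the odds ratio per unit of PRS with a Wald confidence
#' interval. A small positive association violates the multiplicative
#' independence assumption of the combined model.
#'
#' @param fh_binary binary vector (1 = any affected first-degree
#'   relative).
#' @param prs numeric polygenic risk scores.
#' @param conf_level confidence level, default 0.95.
#' @return List: `or`, `ci_low`, `ci_high`, `p`.
#' @export
fh_prs_association <- function(fh_binary, prs, conf_level = 0.95) {
  if (length(unique(fh_binary)) < 2) {
    stop("fh_binary has a single class")
  }
  if (stats::sd(prs) == 0) stop("constant PRS: coefficient undefined")
  fit <- stats::glm(fh_binary ~ prs, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge")
  beta <- stats::coef(fit)["prs"]
  se <- sqrt(stats::vcov(fit)["prs", "prs"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(exp(beta)),
       ci_low = unname(exp(beta - z * se)),
       ci_high = unname(exp(beta + z * se)),
       p = unname(2 * stats::pnorm(-abs(beta) / se)))
}
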