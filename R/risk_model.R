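#' Centre a vector of relative-risk scores to mean 1
#'
#' Divides scores by their (optionally weighted) mean so the weighted mean
#' of the result is exactly 1 up to float rounding.
#'
#' @param scores positive numeric vector.
#' @param weights optional non-negative weights with positive sum; default
#'   equal weights.
#' @return Centred scores.
#' @examples
#' centre_scores(c(1, 3), weights = c(0.75, 0.25))  # c(2/3, 2)
#' @export
centre_scores <- function(scores, weights = NULL) {
  if (length(scores) == 0) stop("scores must be non-empty")
  if (any(!is.finite(scores)) || any(scores <= 0)) {
    stop("scores must be positive and finite")
  }
  if (is.null(weights)) {
    m <- mean(scores)
  } else {
    if (length(weights) != length(scores) || any(weights < 0)) {
      stop("weights must be non-negative and match scores in length")
    }
    sw <- sum(weights)
    if (sw <= 0) stop("weights must have positive sum")
    m <- sum(weights * scores) / sw
  }
  scores / m
}

#' Combine PRS and family-history relative risks
#'
#' The combined relative risk is the product of the two centred factors
#' (independence of the polygenic and family-history components on the
#' multiplicative scale). Cohort-level re-centring of the product, if
#' wanted, is applied afterwards with [centre_scores()].
#'
#' @param prs_rr positive polygenic relative risk(s).
#' @param fh_rr positive family-history relative risk(s).
#' @return Elementwise product.
#' @export
combined_relative_risk <- function(prs_rr, fh_rr) {
  if (any(prs_rr <= 0) || any(fh_rr <= 0)) {
    stop("relative risks must be positive")
  }
  prs_rr * fh_rr
}

# Core survival-product accumulation, vectorised over rr for one
# (sex, entry age) stratum. lambda/m are per-year hazards aligned to the
# yearly horizon. Within year a, total hazard h = lambda*rr + m; the
# cancer share of the within-year event mass is lambda*rr / h
# (cause-specific allocation under constant competing hazards), so
#   mass_a = [lambda_a rr / h_a] (1 - exp(-h_a)) S_a,
#   S_a    = prod_{u<a} exp(-h_u).
# This never exceeds 1 for any rr and reduces to 1 - exp(-sum lambda rr)
# when m = 0.
cuminc_from_hazards <- function(rr, lambda, m) {
  n <- length(rr)
  surv <- rep(1, n)
  risk <- rep(0, n)
  for (a in seq_along(lambda)) {
    lam <- lambda[a] * rr
    h <- lam + m[a]
    mass <- ifelse(h > 0, (lam / h) * (1 - exp(-h)), 0)
    risk <- risk + mass * surv
    surv <- surv * exp(-h)
  }
  risk
}

#' Absolute risk over a horizon from age/sex rate tables
#'
#' Converts a relative risk into an absolute probability of diagnosis by
#' accumulating yearly cause-specific probability mass over the horizon:
#' treating table rates as annual hazards, the cancer hazard in year of
#' age `a` is `lambda(a, sex) * rr` and the competing (death) hazard is
#' `m(a, sex)` (zero when `mortality` is omitted, as in the full-lifetime
#' risk convention). The result lies in `[0, 1]`, is monotone in `rr` and
#' in horizon length, and never increases when mortality is included.
#'
#' @param rr positive relative risk(s); vectorised.
#' @param sex `"female"` or `"male"` (scalar).
#' @param entry_age integer age at the start of the horizon (scalar).
#' @param horizon_years length of the horizon in years, or `NULL` if
#'   `end_age` is given.
#' @param end_age accumulate risk up to (not including) this birthday,
#'   e.g. 85 for lifetime risk; or `NULL` if `horizon_years` is given.
#' @param incidence incidence [rate_table()].
#' @param mortality optional all-cause mortality [rate_table()]; omit to
#'   ignore competing mortality.
#' @return Numeric vector of absolute risks, one per `rr`.
#' @examples
#' inc <- rate_table(rep("female", 45), 40:84, rep(0.01, 45))
#' absolute_risk(1, "female", 50, horizon_years = 10, incidence = inc)
#' @export
absolute_risk <- function(rr, sex, entry_age, horizon_years = NULL,
                          end_age = NULL, incidence, mortality = NULL) {
  if (any(rr <= 0)) stop("rr must be positive")
  if (is.null(horizon_years) == is.null(end_age)) {
    stop("give exactly one of horizon_years or end_age")
  }
  n_years <- if (!is.null(horizon_years)) as.integer(horizon_years)
             else as.integer(end_age) - as.integer(entry_age)
  if (n_years < 0) stop("horizon ends before entry age")
  if (n_years == 0) return(rep(0, length(rr)))
  ages <- seq.int(entry_age, entry_age + n_years - 1L)
  lambda <- get_rates(incidence, sex, ages)
  m <- if (is.null(mortality)) rep(0, n_years) else get_rates(mortality, sex, ages)
  cuminc_from_hazards(rr, lambda, m)
}

#' Score a cohort: relative and absolute risks per individual
#'
#' End-to-end composition: PRS from dosages and panel, centred
#' family-history relative risk, combined relative risk (re-centred over
#' the cohort by default), then absolute 10-year risk (with competing
#' mortality when a mortality table is given) and full lifetime risk to
#' `lifetime_end_age` (mortality excluded, matching the lifetime-risk
#' convention).
#'
#' @param cohort data frame with columns `individual_id`, `sex`,
#'   `age_at_entry`, `n_affected_fdr`.
#' @param dosages risk-allele dosage matrix (rows match
#'   `cohort$individual_id`).
#' @param panel a [snp_panel()].
#' @param fh a [fh_model()]; if not yet centred, it is centred on the
#'   cohort's observed family-history distribution.
#' @param incidence incidence [rate_table()].
#' @param mortality optional mortality [rate_table()] (used for the
#'   10-year risk only).
#' @param horizon_years short-term horizon, default 10.
#' @param lifetime_end_age lifetime-risk end age, default 85; the horizon
#'   runs from each individual's entry age to this birthday.
#' @param centre_mode `"product"` (default) re-centres the combined
#'   relative risk to cohort mean 1 after multiplication; `"factors"`
#'   leaves the combined score as the exact product of the two centred
#'   factors.
#' @param missing_policy passed to [compute_prs()].
#' @return Data frame of class `risk_score_set`: `individual_id`,
#'   `prs_rr`, `fh_rr`, `combined_rr`, `risk_10y`, `risk_lifetime`.
#' @export
score_cohort <- function(cohort, dosages, panel, fh, incidence,
                         mortality = NULL, horizon_years = 10,
                         lifetime_end_age = 85,
                         centre_mode = c("product", "factors"),
                         missing_policy = "neutral") {
  centre_mode <- match.arg(centre_mode)
  need <- c("individual_id", "sex", "age_at_entry", "n_affected_fdr")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns: ", paste(need, collapse = ", "))
  }
  ids <- as.character(cohort$individual_id)
  if (!is.null(rownames(dosages))) {
    idx <- match(ids, rownames(dosages))
    if (anyNA(idx)) stop("dosage matrix is missing individual(s): ",
                         paste(utils::head(ids[is.na(idx)]), collapse = ", "))
    dosages <- dosages[idx, , drop = FALSE]
  } else if (nrow(dosages) != nrow(cohort)) {
    stop("unnamed dosage matrix must have one row per cohort individual")
  }

  prs <- unname(compute_prs(dosages, panel, missing_policy))
  if (is.null(fh$centred_rr)) {
    obs <- tabulate(pmin(cohort$n_affected_fdr, 2L) + 1L, nbins = 3L)
    fh <- centre_fh_model(fh, obs / sum(obs))
  }
  fh_rr <- fh_relative_risk(cohort$n_affected_fdr, fh)
  combined <- combined_relative_risk(prs, fh_rr)
  if (centre_mode == "product") combined <- centre_scores(combined)

  risk_10y <- numeric(nrow(cohort))
  risk_life <- numeric(nrow(cohort))
  key <- interaction(cohort$sex, cohort$age_at_entry, drop = TRUE)
  for (g in levels(key)) {
    sel <- which(key == g)
    s <- cohort$sex[sel[1]]
    a <- cohort$age_at_entry[sel[1]]
    risk_10y[sel] <- absolute_risk(combined[sel], s, a,
                                   horizon_years = horizon_years,
                                   incidence = incidence,
                                   mortality = mortality)
    risk_life[sel] <- absolute_risk(combined[sel], s, a,
                                    end_age = lifetime_end_age,
                                    incidence = incidence)
  }
  out <- data.frame(individual_id = ids, prs_rr = prs, fh_rr = fh_rr,
                    combined_rr = combined, risk_10y = risk_10y,
                    risk_lifetime = risk_life, stringsAsFactors = FALSE)
  class(out) <- c("risk_score_set", "data.frame")
  out
}
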