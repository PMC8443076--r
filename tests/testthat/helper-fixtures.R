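# Shared fixture builders: random panels, flat rate tables, tiny cohorts.

make_test_panel <- function(m = 45, seed = 101,
                            or_sd = 0.1, freq_range = c(0.1, 0.9)) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  risk <- sample(bases, m, replace = TRUE)
  other <- vapply(risk, function(b) sample(setdiff(bases, b), 1), "")
  snp_panel(sprintf("rs%04d", seq_len(m)), risk, other,
            odds_ratio = exp(stats::rnorm(m, 0, or_sd)),
            risk_allele_freq = stats::runif(m, freq_range[1], freq_range[2]))
}

identity_panel <- function(m = 45) {
  snp_panel(sprintf("rs%04d", seq_len(m)), "A", "G",
            odds_ratio = rep(1, m), risk_allele_freq = rep(0.5, m))
}

flat_incidence <- function(rate = 0.01, ages = 40:84) {
  rate_table(rep(c("female", "male"), each = length(ages)),
             rep(ages, 2), rep(rate, 2 * length(ages)))
}

# independent per-year accumulation oracle for the absolute risk:
# explicit loop allocating cause-specific mass, no shared code with
# cuminc machinery in R/
abs_risk_oracle <- function(rr, lambda, m) {
  surv <- 1
  risk <- 0
  for (a in seq_along(lambda)) {
    h <- lambda[a] * rr + m[a]
    if (h > 0) {
      risk <- risk + (lambda[a] * rr / h) * (1 - exp(-h)) * surv
    }
    surv <- surv * exp(-h)
  }
  risk
}

# brute-force pairwise AUC oracle: win fraction over all case-control
# pairs, ties counted one half
auc_oracle <- function(status, score) {
  cases <- score[status == 1]
  ctrls <- score[status == 0]
  tot <- 0
  for (x in cases) {
    tot <- tot + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  }
  tot / (length(cases) * length(ctrls))
}
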