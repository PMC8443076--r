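test_that("expected cases accumulate person-time times population rates", {
  ages <- 40:84
  inc <- rate_table(rep("female", length(ages)), ages,
                    c(rep(0, 20), 0.001, 0.002, 0.003, rep(0, 22)))
  one <- data.frame(sex = "female", age_at_entry = 60L, followup_years = 1.0)
  expect_equal(expected_cases(one, inc), 0.001)
  # 2.5 years from age 60, rates 0.001 / 0.002 / 0.003
  two <- data.frame(sex = "female", age_at_entry = 60L, followup_years = 2.5)
  expect_equal(expected_cases(two, inc), 0.001 + 0.002 + 0.5 * 0.003)
  # truncation
  expect_equal(expected_cases(two, inc, max_followup_years = 1.5),
               0.001 + 0.5 * 0.002)
  # mixed follow-up lengths do not corrupt each other's age indexing
  mix <- data.frame(sex = c("female", "female"),
                    age_at_entry = c(60L, 40L),
                    followup_years = c(1, 25))
  expect_equal(expected_cases(mix, inc), 0.001 + 0.001 + 0.002 + 0.003)
  expect_equal(expected_cases(data.frame(sex = "female", age_at_entry = 60L,
                                         followup_years = 0), inc), 0)
})

test_that("SIR point estimate and Poisson log-likelihood CI", {
  r <- sir(100, 100)
  expect_equal(r$sir, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  # closed form of the CI
  expect_equal(r$ci_low, exp(log(1) - qnorm(0.975) / sqrt(100)))
  # zero observed: defined one-sided upper bound
  r0 <- sir(0, 10)
  expect_equal(r0$sir, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, qgamma(0.975, 1) / 10)
  expect_true(r0$zero_observed)
  expect_error(sir(-1, 10))
  expect_error(sir(5, 0))
})

test_that("stratified SIRs partition the cohort and conserve O and E", {
  rates <- simulate_rate_tables()
  cfg <- sim_config(n_individuals = 4000, seed = 51)
  pan <- make_test_panel(m = 10, seed = 52)
  sim <- simulate_cohort(cfg, pan, rates)
  sc <- score_cohort(sim$cohort, sim$dosages, pan, fh_model(cfg$fh_rr),
                     rates$incidence, rates$mortality)
  overall <- stratified_sir(sc, sim$cohort, rates$incidence,
                            stratify_by = "overall",
                            max_followup_years = 10)[[1]]
  # k = 1 reproduces the overall SIR
  q1 <- stratified_sir(sc, sim$cohort, rates$incidence, "quantile",
                       measure = "risk_10y", k = 1,
                       max_followup_years = 10)[[1]]
  expect_equal(q1$sir, overall$sir)
  # quintiles: near-equal sizes, conservation of observed and expected
  q5 <- stratified_sir(sc, sim$cohort, rates$incidence, "quantile",
                       measure = "risk_10y", k = 5,
                       max_followup_years = 10)
  tab <- sir_table(q5)
  expect_equal(sum(tab$observed), overall$observed)
  expect_equal(sum(tab$expected), overall$expected, tolerance = 1e-9)
  # by family history and by sex cover everyone too
  for (by in c("fh", "sex", "age_group")) {
    tb <- sir_table(stratified_sir(sc, sim$cohort, rates$incidence, by,
                                   max_followup_years = 10))
    expect_equal(sum(tb$observed), overall$observed)
    expect_equal(sum(tb$expected), overall$expected, tolerance = 1e-9)
  }
  # constant scores: five near-equal strata, SIRs close to overall
  const <- sc
  const$risk_10y <- rep(0.5, nrow(const))
  qc <- sir_table(stratified_sir(const, sim$cohort, rates$incidence,
                                 "quantile", measure = "risk_10y", k = 5,
                                 max_followup_years = 10))
  sizes <- table(crcrisk:::quantile_groups(const$risk_10y, 5))
  expect_lte(diff(range(sizes)), 1)
})

test_that("top/bottom fraction strata select the right tail", {
  rates <- simulate_rate_tables()
  cfg <- sim_config(n_individuals = 2000, seed = 53)
  pan <- make_test_panel(m = 10, seed = 54)
  sim <- simulate_cohort(cfg, pan, rates)
  sc <- score_cohort(sim$cohort, sim$dosages, pan, fh_model(cfg$fh_rr),
                     rates$incidence, rates$mortality)
  top <- stratified_sir(sc, sim$cohort, rates$incidence, "top_fraction",
                        measure = "combined_rr", fraction = 0.05,
                        max_followup_years = 10)[[1]]
  n_top <- ceiling(0.05 * nrow(sc))
  cutoff <- sort(sc$combined_rr, decreasing = TRUE)[n_top]
  sel <- sc$combined_rr >= cutoff
  expect_equal(top$observed, sum(sim$cohort$case_status[sel]))
})

test_that("AUC equals the brute-force pairwise win fraction", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.8, 0.6, 0.7, 0.1))$auc, 0.75)
  # pROC warns that a degenerate CI accompanies a perfect AUC
  expect_equal(suppressWarnings(auc(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))$auc),
               1.0)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "case")
  # oracle equivalence on random instances with ties
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    status <- rbinom(n, 1, 0.3)
    if (length(unique(status)) < 2) next
    score <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    r <- auc(status, score)
    expect_equal(r$auc, auc_oracle(status, score), tolerance = 1e-12)
    expect_lte(r$ci_low, r$auc)
    expect_gte(r$ci_high, r$auc)
  }
})

test_that("calibration slope recovers the generating coefficient", {
  set.seed(62)
  n <- 50000
  lo <- rnorm(n, -4, 1)
  p <- plogis(lo)
  y <- rbinom(n, 1, p)
  r <- calibration_slope(y, p)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  expect_gt(r$p_vs_one, 0.05)
  # predictions with the logit shrunk by 2 recover slope ~ 2
  r2 <- calibration_slope(y, plogis(lo / 2))
  expect_equal(r2$slope, 2, tolerance = 0.15)
  expect_lt(r2$p_vs_one, 1e-6)
  # degenerate constant predictor is flagged, not silently fit
  expect_error(calibration_slope(y, rep(mean(y), n)), "degenerate")
  expect_error(calibration_slope(y, rep(1, n)), "strictly")
})

test_that("nested-model comparison is an LRT with one degree of freedom", {
  set.seed(63)
  n <- 20000
  fh <- exp(rnorm(n, 0, 0.3))
  prs <- exp(rnorm(n, 0, 0.4))
  base_lo <- log(0.02) + log(fh) + log(prs)
  y <- rbinom(n, 1, plogis(base_lo))
  # identical scores: chi-square exactly 0
  r0 <- compare_nested_models(y, fh, fh)
  expect_equal(r0$chisq, 0)
  expect_equal(r0$df, 1L)
  # real polygenic effect: strongly significant
  r1 <- compare_nested_models(y, fh, fh * prs)
  expect_gt(r1$chisq, 10)
  expect_lt(r1$p, 0.01)
  # pure-noise polygenic term: not significant at this seed
  noise <- exp(rnorm(n, 0, 0.4))
  r2 <- compare_nested_models(y, fh, fh * noise)
  expect_gt(r2$p, 0.01)
})

test_that("eligibility waterfall applies filters sequentially", {
  rec <- data.frame(id = 1:10,
                    sex_ok = c(FALSE, rep(TRUE, 9)),
                    age = c(45, 30, rep(50, 8)),
                    geno = c(rep(TRUE, 2), FALSE, rep(TRUE, 7)))
  filters <- list(
    "sex concordant" = function(d) d$sex_ok,
    "aged 40-69" = function(d) d$age >= 40 & d$age <= 69,
    "genotyped" = function(d) d$geno
  )
  wf <- eligibility_waterfall(rec, filters)
  expect_equal(wf$n_remaining, c(10, 9, 8, 7))
  expect_equal(wf$n_dropped, c(0, 1, 1, 1))
  # conservation: total dropped + final = initial
  expect_equal(sum(wf$n_dropped) + wf$n_remaining[nrow(wf)], nrow(rec))
  # permuting the order changes per-step drops but not the final set
  wf2 <- eligibility_waterfall(rec, filters[c(3, 1, 2)])
  expect_setequal(attr(wf2, "final_records")$id,
                  attr(wf, "final_records")$id)
  # all pass
  wf3 <- eligibility_waterfall(rec[4:10, ], filters)
  expect_equal(wf3$n_dropped, rep(0L, 4))
  expect_error(eligibility_waterfall(rec, list(function(d) TRUE)), "named")
})

test_that("family-history vs PRS association recovers a known slope", {
  set.seed(64)
  n <- 20000
  prs <- exp(rnorm(n, 0, 0.5))
  # independent: CI covers OR = 1
  fh0 <- rbinom(n, 1, 0.11)
  r0 <- fh_prs_association(fh0, prs)
  expect_lt(r0$ci_low, 1)
  expect_gt(r0$ci_high, 1)
  # known log-odds slope 0.2 per unit PRS
  fh1 <- rbinom(n, 1, plogis(qlogis(0.11) + 0.2 * prs))
  r1 <- fh_prs_association(fh1, prs)
  expect_lt(r1$ci_low, exp(0.2))
  expect_gt(r1$ci_high, exp(0.2))
  expect_error(fh_prs_association(rep(1, n), prs), "single class")
  expect_error(fh_prs_association(fh0, rep(1, n)), "constant")
})

test_that("evaluate_cohort assembles a coherent report", {
  rates <- simulate_rate_tables()
  cfg <- sim_config(n_individuals = 4000, seed = 65)
  pan <- make_test_panel(m = 10, seed = 66)
  sim <- simulate_cohort(cfg, pan, rates)
  sc <- score_cohort(sim$cohort, sim$dosages, pan, fh_model(cfg$fh_rr),
                     rates$incidence, rates$mortality)
  rep <- evaluate_cohort(sc, sim$cohort, rates$incidence)
  expect_equal(nrow(rep$quantiles_10y), 5)
  expect_equal(sum(rep$quantiles_lifetime$observed), rep$overall$observed)
  expect_true(rep$auc_10y$auc > 0.5)   # model-generated outcomes discriminate
  expect_true(is.numeric(rep$model_comparison$chisq))
})
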