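---
title: "Methods: polygenic and family-history colorectal cancer risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic and family-history colorectal cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcrisk)
```

# The model

`crcrisk` implements a two-factor multiplicative relative-risk model
for colorectal cancer and the machinery to turn it into absolute risks
and to judge it.

## Polygenic risk score

Each panel SNP is described by a per-risk-allele odds ratio $OR$ and a
risk-allele frequency $p$. Under Hardy–Weinberg equilibrium the three
genotypes occur with probabilities $(1-p)^2$, $2p(1-p)$, $p^2$ and
carry unnormalised relative risks $1$, $OR$, $OR^2$ (per-allele effects
multiply, i.e. additivity on the log-odds scale). Their population
average is

$$\mu = (1-p)^2 + 2p(1-p)\,OR + p^2\,OR^2,$$

and dividing through by $\mu$ gives genotype weights $1/\mu$, $OR/\mu$,
$OR^2/\mu$ whose Hardy–Weinberg expectation is exactly 1. The PRS of an
individual is the product of these weights across the panel. Assuming
the panel SNPs are independent (the intended use; linkage
disequilibrium between panel members is out of scope), the population
expectation of the PRS is the product of per-SNP expectations, i.e. 1,
which is what lets the PRS act directly as a relative risk against
population baseline rates.

The product is accumulated as a sum of log-weights and exponentiated
once; with 45 terms this avoids accumulation error in the direct
product and makes the log-additivity property exact to float rounding.

Missing genotypes default to the *neutral* policy: the missing SNP
contributes its Hardy–Weinberg expected weight, which is exactly 1, so
missingness cannot shift the cohort mean away from 1. An
`expected-dosage` policy (log-weight interpolated at dosage $2p$) and a
`fail` policy are available; expected-dosage gives a slightly sharper
individual score at the cost of a mean-1 guarantee that is only
approximate.

Panels genotyped on arrays often lack index SNPs; the panel format
carries an optional surrogate id per SNP and `resolve_surrogates()`
maps each index SNP to itself or its surrogate, erroring (with names)
when neither is available. Haplotype-defined risk loci are represented
through their tag SNPs as ordinary panel rows; no phasing is attempted.
When genotypes come from VCF, dosages are oriented by matching the
panel's risk allele against REF/ALT, trying the reverse-strand
complement only for strand-unambiguous pairs (not A/T, not C/G);
ambiguous mismatches are hard errors because a silent strand guess
corrupts the score with no diagnostic.

## Family history and the combined score

Relative risks for 0, 1 and 2+ affected first-degree relatives are
user-supplied (the literature values are reported in meta-analyses of
cohort studies rather than shipped here) and centred to
prevalence-weighted mean 1. By default the centring prevalences are the
cohort's observed family-history distribution; a fixed external
distribution can be supplied instead when scoring individuals outside a
cohort context.

The combined relative risk is the product of the two centred factors.
Whether the product should be re-centred once more over the cohort is
genuinely open — centring each factor makes the product's mean only
approximately 1 (the factors are assumed independent, and even then the
mean of a product of sample-centred terms is not exactly 1). The
package supports both: `centre_mode = "product"` (default) re-centres
the product so the cohort mean is exactly 1, and `"factors"` preserves
the exact identity `combined = prs * fh`. The difference is a single
cohort-level scale factor, typically within a fraction of a percent.

## Absolute risk

Rate tables give per-person-year hazards by sex and single year of age
(5-year-banded tables are expanded by constant interpolation within
band). No formula for the hazard-to-probability conversion is
universal, so the package fixes one: treat table rates as annual
hazards; in a year at age $a$ with cancer hazard $\lambda_a rr$ and
competing mortality $m_a$, the probability mass assigned to a cancer
diagnosis is

$$\frac{\lambda_a rr}{\lambda_a rr + m_a}
  \left(1 - e^{-\lambda_a rr - m_a}\right) S_a, \qquad
  S_a = \prod_{u < a} e^{-\lambda_u rr - m_u},$$

the cause-specific allocation under constant hazards within the year.
This keeps the result in $[0,1]$ for arbitrarily large $rr$ (a naive
$\sum \lambda rr$ does not), is exactly $1 - e^{-\lambda rr h}$ for
constant hazard without mortality, and satisfies the survival-product
splitting identity across horizons to $10^{-10}$.

Two conventions follow the field's practice: the 10-year risk accounts
for competing mortality; the lifetime risk to age 85 excludes it.
Lifetime risk runs from the individual's entry age to their 85th
birthday, not from birth — for a cohort recruited at ages 40–69 a
from-birth risk would be essentially constant across participants and
useless for stratification, whereas the entry-age convention produces
the age-dependent spread seen in per-participant risk distributions.
Because the combined score is centred to mean 1, population rates are
used directly as the baseline hazard with no division by the cohort
mean of $rr$; this is an approximation (the mean of the *risk* is not
exactly the risk at the mean $rr$) and is the standard
centre-then-apply construction.

Ages are integer years at entry; person-time is fractional; all age
intervals are half-open $[a, a+1)$.

## Evaluation

* **SIR**: $O/E$ with $E$ accumulated as person-time times the
  population rate of each (sex, age) cell, exact fractional final
  years, and follow-up truncatable (10 years for the short-horizon
  analyses). The interval is the quadratic approximation to the Poisson
  log likelihood for the log-rate, $\exp(\log(O/E) \pm z/\sqrt{O})$.
  With $O = 0$ the log-based interval is undefined; the package reports
  a point estimate of 0 with the exact Poisson upper limit and flags
  the stratum. Reported intervals are rounded half-even at display
  time; full precision is kept in all outputs.
* **Stratification**: quantile strata are rank-based with ties broken
  by input order and boundary individuals assigned to the lower
  stratum — deterministic and partition-exact, so observed and expected
  counts are conserved across strata. Fixed age-group strata are
  40–49/50–59/60–69 at entry. Top/bottom tail fractions use the same
  rank rule.
* **Discrimination**: Mann–Whitney AUC with ties counted one half; the
  interval is DeLong's, the standard choice for paired ROC comparisons.
  The test suite holds the implementation to the brute-force pairwise
  win fraction on random instances.
* **Calibration / dispersion**: no-intercept logistic regression of
  case status on the log-odds of the predicted probability; slope 1
  under perfect calibration. The test of slope $= 1$ is a Wald test (a
  likelihood-ratio variant exists; Wald matches the conventional
  reporting of a coefficient with its CI). We follow the standard
  reading that a slope $> 1$ means predictions are too moderate
  (under-dispersed) and $< 1$ too extreme; some applied reports invert
  this wording.
* **Model comparison**: the family-history-only and combined models are
  nested on the log scale, so a likelihood-ratio test with one degree
  of freedom compares logistic fits with and without the polygenic
  term $\log(\text{combined}/\text{fh})$.

# The simulator

The synthetic-data module exists so that every stage — panel reading,
PRS, centring, absolute risk, SIR, calibration — can be exercised
end-to-end with known truth. Its defaults emulate a middle-aged
population cohort: entry ages 40–69 with decade weights
22.1% / 33.2% / 44.7% (uniform within decade), 54% female,
family-history prevalences 88.9% / 10.5% / 0.6% for 0 / 1 / 2+
affected first-degree relatives, and administrative censoring after 7
years (recruitment windows of population cohorts typically put 6–10
years of registry follow-up behind the censoring date). Genotypes are
Binomial(2, $p$) per SNP (Hardy–Weinberg, no linkage disequilibrium).
Rate tables are Gompertz, $\lambda(a) = \lambda_0 e^{\gamma(a-40)}$ per
sex with male rates 25% higher — the male excess seen in colorectal
cancer registries — with defaults $\lambda_0 = 5\times10^{-4}$,
$\gamma = 0.09$ for incidence (rates roughly doubling every 8 years, in
the range of registry data for these ages) and
$\lambda_0 = 1.5\times10^{-3}$ for all-cause mortality. The default
family-history relative risks (1, 2.07, 3.87) are of the magnitude
meta-analyses of cohort studies report for 1 and 2+ affected
first-degree relatives; they are a synthetic stand-in, not shipped
literature values, and all simulator defaults are stated once here and
used unchanged by the tests.

Outcomes are generated from the model's own hazards: each year an
exponential clock with rate $\lambda(a, \text{sex}) \cdot rr_{\rm true} +
m(a, \text{sex})$ decides whether an event precedes the year boundary,
and the cause is allocated with probability proportional to each
hazard. This is exactly the data-generating process the scoring model
assumes, which makes the recovery tests well-posed: the overall SIR
converges to 1, the calibration slope to 1, and SIRs across
relative-risk quintiles increase monotonically. Family history is
independent of genotypes by default; a log-odds knob induces a
controlled association between the two for sensitivity analyses of the
independence assumption.

The whole simulation consumes a single seeded RNG stream (one
`set.seed` per simulation) rather than re-seeding per component, so
caller-side draws with nearby seeds cannot accidentally replay a
component's stream — a correlation which, when it couples outcome
noise to genotype noise, visibly biases calibration-slope recovery.

What passing simulation tests does **not** show: robustness to linkage
disequilibrium between panel SNPs, mis-specified odds ratios or allele
frequencies, family-history misreport, secular trends or cohort
selection effects (e.g. healthy-volunteer bias, which in real cohorts
shows up as an overall SIR below 1), or age-dependent familial effects.
Real-data behaviour on those axes is out of the simulator's reach by
design.

# Numerical and design choices

* Genotype-weight normalisation is exact: the Hardy–Weinberg mean of
  the weights is 1 to $10^{-12}$ per SNP, and the simulated cohort mean
  PRS is checked within 3 Monte-Carlo standard errors.
* `centre_scores` divides by the weighted mean; the result's weighted
  mean is 1 to float rounding, with empty input and zero-weight sums
  rejected.
* The absolute-risk accumulation is validated against an independent
  per-year oracle (explicit loop, no shared code) at $10^{-12}$ and the
  constant-hazard closed form at $10^{-10}$.
* Quantile ties: stable on input order; with heavily tied scores the
  strata remain equal-sized to within one individual.
* Degenerate inputs fail loudly rather than silently: constant
  predictors in the calibration regression, single-class outcomes in
  the AUC, unresolvable panel SNPs, ambiguous strand flips, rate tables
  with gaps or insufficient coverage.
* Problem sizes used by the checks: the analytic identities run at
  $n = 10^5$ genotypes (seconds), and calibration-slope recovery at
  $n = 2\times10^5$ individuals, where the slope's standard error
  (~0.004 at the simulated incidence) is small enough to detect
  percent-level miscalibration.

# Known limitations

* Family-history risk does not depend on the consultand's age or the
  relatives' ages at diagnosis, so risks are somewhat overestimated for
  older adults with mild family history and underestimated for young
  adults with early-onset relatives.
* No modifiable risk factors (smoking, BMI, alcohol, screening
  history); the model captures the non-modifiable baseline only.
* The PRS-as-relative-risk construction assumes odds ratios approximate
  hazard ratios (rare-disease) and SNP independence; both are
  approximations inherited from the construction itself.
* Lifetime risk to 85 without competing mortality is an upper-bound
  convention, not a prediction of experienced risk.
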