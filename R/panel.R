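#' Construct and validate a SNP panel
#'
#' A panel is a data frame with one row per SNP carrying the per-risk-allele
#' odds ratio and the risk-allele frequency used to weight genotypes, plus
#' an optional surrogate identifier (the SNP actually genotyped when the
#' index SNP is unavailable on the array).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param risk_allele single-base risk alleles (A/C/G/T).
#' @param other_allele single-base non-risk alleles.
#' @param odds_ratio per-risk-allele odds ratios (> 0).
#' @param risk_allele_freq risk-allele frequencies, strictly in (0, 1).
#' @param surrogate_id optional surrogate SNP identifiers (`NA` if none).
#' @return A data frame of class `snp_panel`.
#' @examples
#' snp_panel("rs1", "A", "G", odds_ratio = 1.2, risk_allele_freq = 0.3)
#' @export
snp_panel <- function(snp_id, risk_allele, other_allele,
                      odds_ratio, risk_allele_freq,
                      surrogate_id = NA_character_) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    risk_allele = toupper(as.character(risk_allele)),
    other_allele = toupper(as.character(other_allele)),
    odds_ratio = as.numeric(odds_ratio),
    risk_allele_freq = as.numeric(risk_allele_freq),
    surrogate_id = as.character(surrogate_id),
    stringsAsFactors = FALSE
  )
  panel$surrogate_id[panel$surrogate_id %in% c("", "NA")] <- NA_character_
  validate_snp_panel(panel)
}

#' Validate a SNP panel data frame
#'
#' @param panel data frame with columns `snp_id`, `risk_allele`,
#'   `other_allele`, `odds_ratio`, `risk_allele_freq`, `surrogate_id`.
#' @return The panel, classed as `snp_panel`, invisibly checked.
#' @export
validate_snp_panel <- function(panel) {
  required <- c("snp_id", "risk_allele", "other_allele",
                "odds_ratio", "risk_allele_freq", "surrogate_id")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$snp_id)) {
    dup <- unique(panel$snp_id[duplicated(panel$snp_id)])
    stop("duplicate snp_id in panel: ", paste(dup, collapse = ", "))
  }
  bad <- which(!(panel$odds_ratio > 0) | !is.finite(panel$odds_ratio))
  if (length(bad) > 0) {
    stop("odds_ratio must be > 0; offending snp_id: ",
         paste(panel$snp_id[bad], collapse = ", "))
  }
  bad <- which(!(panel$risk_allele_freq > 0 & panel$risk_allele_freq < 1))
  if (length(bad) > 0) {
    stop("risk_allele_freq must be in (0, 1); offending snp_id: ",
         paste(panel$snp_id[bad], collapse = ", "))
  }
  bad <- which(panel$risk_allele == panel$other_allele)
  if (length(bad) > 0) {
    stop("risk_allele must differ from other_allele; offending snp_id: ",
         paste(panel$snp_id[bad], collapse = ", "))
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Unscaled population-average risk for one SNP
#'
#' Evaluates mu = (1 - p)^2 + 2 p (1 - p) OR + p^2 OR^2, the expectation of
#' the unnormalised genotype relative risk (1, OR, OR^2) under
#' Hardy-Weinberg equilibrium at risk-allele frequency p. Dividing the
#' genotype risks by mu normalises the population-average risk to 1.
#'
#' @param odds_ratio per-risk-allele odds ratio(s), > 0.
#' @param p risk-allele frequency(ies), strictly in (0, 1).
#' @return Numeric vector of mu values.
#' @examples
#' compute_mu(2, 0.25)  # 1.5625
#' @export
compute_mu <- function(odds_ratio, p) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds_ratio must be a positive finite number")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly in (0, 1)")
  }
  (1 - p)^2 + 2 * p * (1 - p) * odds_ratio + p^2 * odds_ratio^2
}

#' Normalised genotype risk weights for a panel
#'
#' For each SNP returns (mu, w0, w1, w2) = (mu, 1/mu, OR/mu, OR^2/mu):
#' the multiplicative risk weight carried by 0, 1 or 2 copies of the risk
#' allele, scaled so the Hardy-Weinberg expectation of the weight is
#' exactly 1.
#'
#' @param panel a `snp_panel` (or data frame with `odds_ratio` and
#'   `risk_allele_freq` columns), or a single-row list-alike.
#' @return Data frame with columns `snp_id`, `mu`, `w0`, `w1`, `w2`.
#' @examples
#' genotype_weights(snp_panel("rs1", "A", "G", 2, 0.25))
#' @export
genotype_weights <- function(panel) {
  or <- panel$odds_ratio
  p <- panel$risk_allele_freq
  mu <- compute_mu(or, p)
  data.frame(
    snp_id = if (!is.null(panel$snp_id)) panel$snp_id else NA_character_,
    mu = mu,
    w0 = 1 / mu,
    w1 = or / mu,
    w2 = or^2 / mu,
    stringsAsFactors = FALSE
  )
}

#' Resolve panel SNPs against the SNPs actually available
#'
#' Each panel SNP maps to itself when its id is available; otherwise to its
#' surrogate when that is available. SNPs with neither available are an
#' error listing them by name.
#'
#' @param panel a `snp_panel`.
#' @param available_snp_ids character vector of genotyped SNP ids.
#' @return Data frame with columns `snp_id` (index SNP) and `used_id`
#'   (the id to read dosages from).
#' @export
resolve_surrogates <- function(panel, available_snp_ids) {
  used <- ifelse(panel$snp_id %in% available_snp_ids,
                 panel$snp_id,
                 ifelse(!is.na(panel$surrogate_id) &
                          panel$surrogate_id %in% available_snp_ids,
                        panel$surrogate_id,
                        NA_character_))
  if (anyNA(used)) {
    stop("panel SNP(s) not genotyped and no available surrogate: ",
         paste(panel$snp_id[is.na(used)], collapse = ", "))
  }
  data.frame(snp_id = panel$snp_id, used_id = used,
             stringsAsFactors = FALSE)
}
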