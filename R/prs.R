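#' Compute the multiplicative polygenic risk score
#'
#' The PRS of an individual is the product over panel SNPs of the
#' normalised genotype weight (1/mu, OR/mu, OR^2/mu for 0, 1, 2 risk
#' alleles). Because each per-SNP weight has Hardy-Weinberg expectation 1,
#' the population expectation of the PRS over independent SNPs is 1. The
#' product is accumulated in log space and exponentiated once, which keeps
#' long (e.g. 45-term) products numerically stable.
#'
#' @param dosages integer matrix of risk-allele counts (individuals in
#'   rows, SNPs in columns; dimnames required), entries 0/1/2 or `NA`.
#'   Columns may be named by index or surrogate SNP id.
#' @param panel a [snp_panel()].
#' @param missing_policy how to treat `NA` dosages:
#'   * `"neutral"` (default): substitute the Hardy-Weinberg expected
#'     weight, which is exactly 1, so a missing genotype contributes
#'     nothing and the population mean stays 1;
#'   * `"expected-dosage"`: interpolate the log-weight at dosage `2p`;
#'   * `"fail"`: error on any missing genotype.
#' @return Named numeric vector of per-individual PRS values (> 0).
#' @examples
#' pan <- snp_panel("rs1", "A", "G", 2, 0.25)
#' g <- matrix(0L, 1, 1, dimnames = list("i1", "rs1"))
#' compute_prs(g, pan)  # 0.64 = 1/mu
#' @export
compute_prs <- function(dosages, panel,
                        missing_policy = c("neutral", "expected-dosage", "fail")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(colnames(dosages))) {
    stop("dosage matrix must have SNP ids as column names")
  }
  map <- resolve_surrogates(panel, colnames(dosages))
  g <- dosages[, map$used_id, drop = FALSE]
  bad <- g[!is.na(g) & !(g %in% c(0, 1, 2))]
  if (length(bad) > 0) {
    stop("dosages must be 0, 1, 2 or NA; found: ",
         paste(utils::head(unique(bad)), collapse = ", "))
  }

  log_or <- log(panel$odds_ratio)
  log_mu <- log(compute_mu(panel$odds_ratio, panel$risk_allele_freq))
  # per-entry log-weight: g * log(OR) - log(mu), column-wise
  contrib <- sweep(sweep(g, 2, log_or, `*`), 2, log_mu, `-`)

  if (anyNA(g)) {
    if (missing_policy == "fail") {
      stop("missing genotypes present and missing_policy = \"fail\"")
    }
    na_idx <- which(is.na(g), arr.ind = TRUE)
    fill <- switch(missing_policy,
      "neutral" = 0,
      "expected-dosage" = {
        p <- panel$risk_allele_freq
        (2 * p * log_or - log_mu)[na_idx[, "col"]]
      }
    )
    contrib[na_idx] <- fill
  }
  prs <- exp(rowSums(contrib))
  names(prs) <- rownames(dosages)
  prs
}
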