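#' Read a SNP panel from TSV
#'
#' Expected header: `snp_id  risk_allele  other_allele  odds_ratio
#' risk_allele_freq  surrogate_id` (surrogate blank when none). Rows are
#' validated; malformed values are reported with their line number.
#'
#' @param path path to a tab-separated panel file.
#' @return A [snp_panel()].
#' @export
read_panel <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("", "NA"))
  need <- c("snp_id", "risk_allele", "other_allele",
            "odds_ratio", "risk_allele_freq")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"surrogate_id" %in% names(raw)) raw$surrogate_id <- NA_character_
  or <- suppressWarnings(as.numeric(raw$odds_ratio))
  p <- suppressWarnings(as.numeric(raw$risk_allele_freq))
  bad <- which(is.na(or) | is.na(p))
  if (length(bad) > 0) {
    stop("non-numeric odds_ratio/risk_allele_freq at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  bad <- which(!(p > 0 & p < 1))
  if (length(bad) > 0) {
    stop("risk_allele_freq outside (0,1) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  bad <- which(!(or > 0))
  if (length(bad) > 0) {
    stop("odds_ratio must be > 0 at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  snp_panel(raw$snp_id, raw$risk_allele, raw$other_allele, or, p,
            raw$surrogate_id)
}

#' Write a SNP panel to TSV
#' @param panel a [snp_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read genotypes as a risk-allele dosage matrix
#'
#' Two formats:
#' * `dosage`: TSV with individuals in rows (first column
#'   `individual_id`) and SNP ids as remaining column names; cells
#'   0/1/2 or NA. Dosages are taken to already count risk alleles.
#' * `vcf`: a VCF with GT genotypes. ALT counts are converted to
#'   risk-allele counts by matching the panel's risk allele against
#'   REF/ALT; when neither matches directly, the reverse-strand
#'   complement is tried, but only for strand-unambiguous SNPs (not
#'   A/T or C/G) — an ambiguous mismatch is an error, since silently
#'   guessing the strand corrupts scores. Non-biallelic sites are
#'   skipped with a warning.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"dosage"` or `"vcf"`.
#' @param panel a [snp_panel()]; required for VCF orientation, optional
#'   (orientation already applied) for dosage TSV.
#' @return Integer dosage matrix with individual and SNP dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "dosage", "vcf"),
                           panel = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "dosage") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    if (names(tab)[1] != "individual_id") {
      stop("dosage TSV must start with an 'individual_id' column")
    }
    ids <- as.character(tab[[1]])
    g <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(g) <- "integer"
    rownames(g) <- ids
    return(g)
  }
  read_genotypes_vcf(path, panel)
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

read_genotypes_vcf <- function(path, panel) {
  if (is.null(panel)) stop("a panel is required to orient VCF genotypes")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single-site VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning("skipping ", sum(multi), " non-biallelic site(s)")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]

  # ALT allele counts from GT strings such as 0/1, 1|1, ./.
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(v) {
      if (any(v == "." | is.na(v))) return(NA_integer_)
      sum(v == "1")
    }, integer(1))
  }
  g_alt <- t(apply(gt, 1, alt_count))
  if (ncol(gt) == 1) g_alt <- matrix(g_alt, ncol = 1)
  colnames(g_alt) <- colnames(gt)

  used <- resolve_surrogates(panel, ids)
  out <- matrix(NA_integer_, nrow = ncol(g_alt), ncol = nrow(panel),
                dimnames = list(colnames(g_alt), panel$snp_id))
  ambiguous <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  for (i in seq_len(nrow(panel))) {
    row <- match(used$used_id[i], ids)
    ref <- toupper(fix[row, "REF"]); alt <- toupper(fix[row, "ALT"])
    risk <- panel$risk_allele[i]; other <- panel$other_allele[i]
    dos <- g_alt[row, ]
    if (risk == alt && other == ref) {
      out[, i] <- dos
    } else if (risk == ref && other == alt) {
      out[, i] <- 2L - dos
    } else if (!ambiguous(risk, other) &&
               complement_base(risk) == alt && complement_base(other) == ref) {
      out[, i] <- dos
    } else if (!ambiguous(risk, other) &&
               complement_base(risk) == ref && complement_base(other) == alt) {
      out[, i] <- 2L - dos
    } else {
      stop("allele mismatch for ", panel$snp_id[i], " (site ",
           used$used_id[i], "): panel ", risk, "/", other,
           " vs VCF ", ref, "/", alt,
           if (ambiguous(risk, other)) " [strand-ambiguous pair]" else "")
    }
  }
  out
}

#' Write a dosage matrix to TSV
#' @param dosages integer dosage matrix with dimnames.
#' @param path output path.
#' @export
write_dosages <- function(dosages, path) {
  df <- data.frame(individual_id = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-individual phenotype table from TSV
#'
#' Expected columns: `individual_id`, `sex`, `age_at_entry`,
#' `n_affected_fdr`, `case_status`, `followup_years`.
#'
#' @param path input path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("individual_id", "sex", "age_at_entry", "n_affected_fdr",
            "case_status", "followup_years")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("phenotype file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$individual_id <- as.character(tab$individual_id)
  tab
}

#' Write a phenotype table to TSV
#' @param cohort data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a rate table from CSV
#'
#' Accepts single-year (`sex,age,rate`) or banded
#' (`sex,age_lo,age_hi,rate`) layouts; bands are expanded by constant
#' interpolation.
#'
#' @param path input path.
#' @return A [rate_table()].
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("sex", "age", "rate") %in% names(tab))) {
    return(rate_table(tab$sex, tab$age, tab$rate))
  }
  if (all(c("sex", "age_lo", "age_hi", "rate") %in% names(tab))) {
    return(expand_rate_bands(tab))
  }
  stop("rate CSV must have columns sex,age,rate or sex,age_lo,age_hi,rate")
}

#' Write a rate table to CSV
#' @param table a [rate_table()].
#' @param path output path.
#' @export
write_rate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write per-individual risk scores to TSV
#' @param scores a `risk_score_set`.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-individual risk scores from TSV
#' @param path input path.
#' @return A `risk_score_set` data frame.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$individual_id <- as.character(tab$individual_id)
  class(tab) <- c("risk_score_set", "data.frame")
  tab
}

#' Write an evaluation report as JSON
#'
#' Serialises stratified SIRs plus any discrimination/calibration/model
#' comparison results at full float precision.
#'
#' @param report list, typically from [evaluate_cohort()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits panel TSV, dosage TSV, phenotype TSV and incidence/mortality
#' CSVs, the interchange formats the scoring and evaluation entry points
#' read back.
#'
#' @param sim result of [simulate_cohort()].
#' @param panel the [snp_panel()] used.
#' @param rates list with `incidence` and `mortality` tables.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_dataset <- function(sim, panel, rates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(panel, file.path(dir, "panel.tsv"))
  write_dosages(sim$dosages, file.path(dir, "dosages.tsv"))
  write_phenotypes(sim$cohort, file.path(dir, "phenotypes.tsv"))
  write_rate_table(rates$incidence, file.path(dir, "incidence.csv"))
  if (!is.null(rates$mortality)) {
    write_rate_table(rates$mortality, file.path(dir, "mortality.csv"))
  }
  invisible(dir)
}
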