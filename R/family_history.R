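#' Family-history relative-risk model
#'
#' Holds the relative risks for having 0, 1 or 2+ first-degree relatives
#' (FDRs) diagnosed with colorectal cancer, together with the population
#' prevalence of each category, and the derived centred relative risks
#' whose prevalence-weighted mean is exactly 1.
#'
#' @param rr numeric vector of length 3: relative risks for 0, 1 and 2+
#'   affected FDRs (names `fdr0`, `fdr1`, `fdr2plus` optional).
#' @param prevalence numeric vector of length 3 summing to 1 (category
#'   prevalences), or `NULL` to defer centring until a cohort's observed
#'   distribution is supplied via [centre_fh_model()].
#' @return Object of class `fh_model` with elements `raw_rr`,
#'   `prevalence`, `centred_rr` (the latter two `NULL` until centred).
#' @examples
#' fh_model(c(1, 2, 4), c(0.889, 0.105, 0.006))
#' @export
fh_model <- function(rr, prevalence = NULL) {
  rr <- as.numeric(rr)
  if (length(rr) != 3 || any(!is.finite(rr)) || any(rr <= 0)) {
    stop("rr must be 3 positive relative risks (0, 1, 2+ affected FDRs)")
  }
  names(rr) <- c("fdr0", "fdr1", "fdr2plus")
  m <- structure(list(raw_rr = rr, prevalence = NULL, centred_rr = NULL),
                 class = "fh_model")
  if (!is.null(prevalence)) m <- centre_fh_model(m, prevalence)
  m
}

#' Centre a family-history model to population mean 1
#'
#' Divides the raw relative risks by their prevalence-weighted mean so the
#' population-average family-history relative risk is exactly 1.
#'
#' @param model an `fh_model`.
#' @param prevalence numeric vector of length 3 (prevalence of 0, 1, 2+
#'   affected FDRs) summing to 1 within 1e-9.
#' @return The centred `fh_model`.
#' @export
centre_fh_model <- function(model, prevalence) {
  prevalence <- as.numeric(prevalence)
  if (length(prevalence) != 3 || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-9) {
    stop("prevalence must be 3 non-negative values summing to 1")
  }
  names(prevalence) <- names(model$raw_rr)
  mean_rr <- sum(prevalence * model$raw_rr)
  model$prevalence <- prevalence
  model$centred_rr <- model$raw_rr / mean_rr
  model
}

#' Centred relative risk for a count of affected first-degree relatives
#'
#' Counts of 2 or more collapse to the 2+ category.
#'
#' @param n_affected_fdr integer vector of affected-FDR counts (>= 0).
#' @param model a centred `fh_model`.
#' @return Numeric vector of centred relative risks.
#' @export
fh_relative_risk <- function(n_affected_fdr, model) {
  if (is.null(model$centred_rr)) {
    stop("fh_model has not been centred; supply prevalences first")
  }
  if (any(n_affected_fdr < 0) || any(n_affected_fdr != floor(n_affected_fdr))) {
    stop("n_affected_fdr must be non-negative integers")
  }
  idx <- pmin(n_affected_fdr, 2L) + 1L
  unname(model$centred_rr[idx])
}

#' @export
print.fh_model <- function(x, ...) {
  cat("Family-history relative-risk model\n")
  cat("  raw RR (0 / 1 / 2+ FDR):", format(x$raw_rr, digits = 4), "\n")
  if (is.null(x$centred_rr)) {
    cat("  not yet centred (no prevalences)\n")
  } else {
    cat("  prevalence:            ", format(x$prevalence, digits = 4), "\n")
    cat("  centred RR:            ", format(x$centred_rr, digits = 4), "\n")
  }
  invisible(x)
}
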