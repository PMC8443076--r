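#' Construct an age- and sex-specific rate table
#'
#' A rate table stores a per-person-year hazard (incidence or all-cause
#' mortality) on a single-year age grid for each sex. Ages must be
#' contiguous within sex.
#'
#' @param sex character vector, `"female"` or `"male"`.
#' @param age integer ages (years).
#' @param rate non-negative rates per person-year.
#' @return Data frame of class `rate_table` with columns `sex`, `age`,
#'   `rate`, sorted by sex then age.
#' @export
rate_table <- function(sex, age, rate) {
  tab <- data.frame(sex = as.character(sex), age = as.integer(age),
                    rate = as.numeric(rate), stringsAsFactors = FALSE)
  if (!all(tab$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (any(tab$rate < 0) || any(!is.finite(tab$rate))) {
    stop("rates must be finite and non-negative")
  }
  tab <- tab[order(tab$sex, tab$age), , drop = FALSE]
  for (s in unique(tab$sex)) {
    a <- tab$age[tab$sex == s]
    if (anyDuplicated(a)) stop("duplicate age for sex ", s)
    if (length(a) > 1 && any(diff(a) != 1)) {
      stop("ages must be contiguous (no gaps) for sex ", s)
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("rate_table", "data.frame")
  tab
}

#' Expand a banded rate table to single-year ages
#'
#' Tables published in age bands (e.g. 5-year ONS bands) are expanded by
#' constant interpolation: every age in `[age_lo, age_hi]` gets the band's
#' rate.
#'
#' @param banded data frame with columns `sex`, `age_lo`, `age_hi`, `rate`.
#' @return A single-year [rate_table()].
#' @export
expand_rate_bands <- function(banded) {
  need <- c("sex", "age_lo", "age_hi", "rate")
  if (!all(need %in% names(banded))) {
    stop("banded table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(banded$age_hi < banded$age_lo)) stop("age_hi < age_lo in band")
  rows <- lapply(seq_len(nrow(banded)), function(i) {
    ages <- seq.int(banded$age_lo[i], banded$age_hi[i])
    data.frame(sex = banded$sex[i], age = ages, rate = banded$rate[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rate_table(out$sex, out$age, out$rate)
}

#' Look up rates for one sex over a run of ages
#'
#' @param table a `rate_table`.
#' @param sex `"female"` or `"male"`.
#' @param ages integer ages; all must be covered by the table.
#' @return Numeric vector of rates, one per age.
#' @export
get_rates <- function(table, sex, ages) {
  sub <- table[table$sex == sex, , drop = FALSE]
  idx <- match(ages, sub$age)
  if (anyNA(idx)) {
    stop("rate table does not cover age(s) ",
         paste(ages[is.na(idx)], collapse = ", "), " for sex ", sex)
  }
  sub$rate[idx]
}
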