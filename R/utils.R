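# Shared helpers: day arithmetic and display rounding conventions.

#' Round half away from zero
#'
#' Rounding convention used for ages and displayed percentages. Base R's
#' `round()` rounds half to even; claims-derived ages and table percentages
#' follow the usual half-up convention instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(59.45, 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Whole days between two calendar dates (b - a).
days_between <- function(a, b) {
  as.integer(as.Date(b) - as.Date(a))
}

# Months on the 30.4375-day average-month scale used for follow-up times.
DAYS_PER_MONTH <- 30.4375

days_to_months <- function(d) as.numeric(d) / DAYS_PER_MONTH

#' Percentage with 1-decimal half-up rounding
#'
#' @param count numerator count(s).
#' @param denominator denominator count.
#' @param digits decimal places (default 1, matching summary-table display).
#' @return numeric percentage(s), `NA` when the denominator is zero.
#' @export
percent_of <- function(count, denominator, digits = 1) {
  if (length(denominator) == 1 && denominator == 0) {
    return(rep(NA_real_, length(count)))
  }
  round_half_up(100 * count / denominator, digits)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_date_safe <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

abort_ctx <- function(msg, class) {
  rlang::abort(msg, class = paste0("cohortpath_", class))
}
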