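#' Round half away from zero
#'
#' Commercial rounding used for all displayed figures (grams to 1 d.p.,
#' elasticities to 2 d.p., dollars to whole units). Base `round()` rounds
#' half to even, which does not reproduce printed trial tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.5)    # 1, not 0
#' round_half_up(-0.5)   # -1
#' round_half_up(2.345, 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Present value under constant-rate discounting
#'
#' @param value Undiscounted amount (dollars, person-years, ...).
#' @param years_from_now Delay in years; 0 returns `value` unchanged.
#' @param rate Annual discount rate; default 3% as standard in
#'   health-economic evaluation.
#' @return `value / (1 + rate)^years_from_now`.
#' @export
#' @examples
#' discount_value(103, 1)        # 100
#' discount_value(100, 24)       # 49.19
discount_value <- function(value, years_from_now, rate = 0.03) {
  stopifnot(rate >= 0)
  if (any(years_from_now < 0)) {
    abort("`years_from_now` must be non-negative.")
  }
  value / (1 + rate)^years_from_now
}

# shared argument checks ------------------------------------------------

check_arm <- function(arm) {
  ok <- c("discount_only", "discount_plus_education")
  if (!all(arm %in% ok)) {
    abort(paste0(
      "Unknown arm: ", paste(setdiff(arm, ok), collapse = ", "),
      ". Valid arms: ", paste(ok, collapse = ", "), "."
    ))
  }
  invisible(arm)
}

check_period <- function(period) {
  ok <- c("during", "followup")
  if (!all(period %in% ok)) {
    abort(paste0(
      "Unknown period: ", paste(setdiff(period, ok), collapse = ", "),
      ". Valid periods: ", paste(ok, collapse = ", "), "."
    ))
  }
  invisible(period)
}
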