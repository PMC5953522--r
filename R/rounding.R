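#' Decimal half-up rounding
#'
#' Rounds to a fixed number of decimal places with ties going away from zero,
#' the convention used for financial reporting. Base R's `round()` uses
#' round-half-to-even, which turns e.g. `56.5 * 3.7 = 209.05` into `209.0`
#' where a fee schedule must print `209.1`. Binary floating point stores
#' `209.05` as `209.04999...`, so the value is first snapped to 9 decimal
#' places to strip representation noise before the half-up decision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(209.05, 1)   # 209.1
#' round_half_up(124.5 * 3.7, 1)  # 460.7
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  scaled <- round(x * p, 9)
  sign(scaled) * floor(abs(scaled) + 0.5) / p
}

#' Convert birr to US dollars
#'
#' Divides by the exchange rate and reports half-up to 2 decimals, the
#' precision used for dollar columns in the fee schedules.
#'
#' @param amount_birr amount in Ethiopian birr.
#' @param exchange_rate birr per US$ (default 22).
#' @return amount in US$, rounded half-up to 2 decimals.
#' @export
to_usd <- function(amount_birr, exchange_rate = 22) {
  if (!is.numeric(exchange_rate) || length(exchange_rate) != 1L ||
      exchange_rate <= 0) {
    abort("`exchange_rate` must be a single positive number")
  }
  round_half_up(amount_birr / exchange_rate, 2)
}
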