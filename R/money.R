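#' Monetary amounts
#'
#' A minimal currency-tagged amount: a non-negative value in USD or KES,
#' carried at full precision and rounded half-even to cents only at
#' presentation and aggregation boundaries (see [round_cents()]).
#'
#' @param value Numeric amount, `>= 0`.
#' @param currency `"USD"` or `"KES"`.
#' @return A `prep_money` object.
#' @export
#' @examples
#' money(25.50)
#' money(1e6, "KES")
money <- function(value, currency = "USD") {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("money: `value` must be a single non-missing number", call. = FALSE)
  }
  if (value < 0) stop("money: `value` must be >= 0", call. = FALSE)
  currency <- match.arg(currency, c("USD", "KES"))
  structure(list(value = as.numeric(value), currency = currency),
            class = "prep_money")
}

#' @rdname money
#' @param x Object to test or print.
#' @export
is_money <- function(x) inherits(x, "prep_money")

#' @rdname money
#' @param ... Unused.
#' @export
print.prep_money <- function(x, ...) {
  cat(sprintf("%s %.2f\n", x$currency, round_cents(x$value)))
  invisible(x)
}

#' Round to cents, half-even
#'
#' Banker's rounding to two decimals, used wherever amounts cross a report
#' or aggregation boundary.
#'
#' @param x Numeric vector.
#' @return `x` rounded to 2 decimal places with ties going to the even cent.
#' @export
round_cents <- function(x) round(x, 2)

#' Round half-up
#'
#' Commercial rounding (0.5 always rounds away from zero), used for display
#' of whole minutes and whole percents.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_up(c(28.5, 30.47)) # 29 30
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert an amount to USD
#'
#' USD amounts pass through unchanged; KES amounts are divided by the
#' KES-per-USD exchange rate and rounded half-even to cents. The operation
#' is idempotent on USD inputs.
#'
#' @param amount A [money()] amount (or bare numeric, taken as USD).
#' @param params [economic_params()] supplying `exchange_rate_kes_per_usd`.
#' @return A `prep_money` amount in USD.
#' @export
#' @examples
#' p <- economic_params()
#' convert_to_usd(money(105.50, "KES"), p)
convert_to_usd <- function(amount, params = economic_params()) {
  if (is.numeric(amount)) amount <- money(amount, "USD")
  if (!is_money(amount)) stop("convert_to_usd: not a money amount", call. = FALSE)
  rate <- params$exchange_rate_kes_per_usd
  if (!is.numeric(rate) || rate <= 0) {
    stop("convert_to_usd: exchange rate must be positive", call. = FALSE)
  }
  switch(amount$currency,
    USD = amount,
    KES = money(round_cents(amount$value / rate), "USD"),
    stop("convert_to_usd: unsupported currency ", amount$currency, call. = FALSE)
  )
}

#' Inflate an amount forward by whole years
#'
#' Compounds `amount * (1 + rate)^years`. Amounts already expressed in the
#' analysis base year are left alone (`years = 0`).
#'
#' @param amount A [money()] amount or bare numeric.
#' @param rate Annual inflation rate as a fraction (e.g. 0.044).
#' @param years Non-negative integer number of years to inflate over.
#' @return Same type as `amount`.
#' @export
#' @examples
#' inflation_adjust(100, 0.044, 1) # 104.40
inflation_adjust <- function(amount, rate, years) {
  if (!is.numeric(years) || length(years) != 1L || is.na(years) || years < 0 ||
      years != as.integer(years)) {
    stop("inflation_adjust: `years` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("inflation_adjust: `rate` must be a fraction in [0, 1)", call. = FALSE)
  }
  f <- (1 + rate)^years
  if (is_money(amount)) money(amount$value * f, amount$currency) else amount * f
}
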