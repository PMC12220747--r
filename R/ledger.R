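#' Economic parameters of the costing analysis
#'
#' Bundles the exchange rate, inflation and discount rates, and the
#' personnel time denominators used to turn annual salaries into hourly
#' wages. Defaults are the 2019 Kenya configuration: 105.50 KES/USD, 4.4%
#' inflation, a 3% discount rate, a 2,080-hour work year and 231 weekdays
#' worked per annum.
#'
#' @param exchange_rate_kes_per_usd Positive KES-per-USD rate.
#' @param inflation_rate Annual inflation as a fraction in `[0, 1)`.
#' @param discount_rate Annual discount rate as a fraction in `[0, 1)`.
#' @param annual_work_hours Positive hours worked per provider per year.
#' @param weekdays_per_year Positive integer weekdays worked per annum.
#' @return A `prep_params` object (a validated list).
#' @export
#' @examples
#' economic_params()
economic_params <- function(exchange_rate_kes_per_usd = kes_per_usd_2019,
                            inflation_rate = 0.044,
                            discount_rate = 0.03,
                            annual_work_hours = 2080,
                            weekdays_per_year = 231L) {
  stopifnot(
    "exchange_rate_kes_per_usd must be positive" = exchange_rate_kes_per_usd > 0,
    "inflation_rate must be in [0, 1)" =
      inflation_rate >= 0 && inflation_rate < 1,
    "discount_rate must be in [0, 1)" = discount_rate >= 0 && discount_rate < 1,
    "annual_work_hours must be positive" = annual_work_hours > 0,
    "weekdays_per_year must be positive" = weekdays_per_year > 0
  )
  structure(list(
    exchange_rate_kes_per_usd = exchange_rate_kes_per_usd,
    inflation_rate = inflation_rate,
    discount_rate = discount_rate,
    annual_work_hours = annual_work_hours,
    weekdays_per_year = as.integer(weekdays_per_year)
  ), class = "prep_params")
}

#' A single cost-ledger entry
#'
#' One input to the costing engine: a named amount in one of the ten cost
#' categories, with a cost basis saying how it accrues. One-off amounts
#' (capital, start-up) must carry a useful life of 1-5 years and are
#' annuitized by the engine; `per_visit` and `per_client_month` amounts are
#' scaled by the arm's accruals; `per_year` amounts enter as-is. An entry
#' may be tagged with the arm it belongs to; untagged fixed entries are
#' allocated across arms by visit share.
#'
#' @param name Item label, unique within a ledger.
#' @param category One of [cost_categories()].
#' @param amount Numeric amount (or [money()]).
#' @param basis One of [cost_bases()].
#' @param currency `"USD"` or `"KES"` when `amount` is bare numeric.
#' @param useful_life_years Integer in 1-5; required iff `basis = "one_off"`.
#' @param arm Optional `"soc"` or `"intervention"`.
#' @param base_year Optional year the amount was priced in; amounts priced
#'   before the 2019 base year are inflated forward by the ledger's
#'   inflation rate.
#' @return A one-row `data.frame` in the ledger item schema.
#' @export
cost_item <- function(name, category, amount, basis = "per_year",
                      currency = "USD", useful_life_years = NA_integer_,
                      arm = NA_character_, base_year = NA_integer_) {
  if (is_money(amount)) {
    currency <- amount$currency
    amount <- amount$value
  }
  item <- data.frame(
    name = as.character(name), category = as.character(category),
    amount = as.numeric(amount), basis = as.character(basis),
    currency = as.character(currency),
    useful_life_years = as.integer(useful_life_years),
    arm = as.character(arm), base_year = as.integer(base_year),
    stringsAsFactors = FALSE
  )
  validate_items(item)
  item
}

validate_items <- function(items) {
  if (nrow(items) == 0L) return(invisible(items))
  bad <- setdiff(items$category, names(cost_categories()))
  if (length(bad)) {
    stop("ledger: unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(items$basis, cost_bases())
  if (length(bad)) {
    stop("ledger: unknown basis: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(items$currency, c("USD", "KES"))
  if (length(bad)) {
    stop("ledger: unknown currency: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- items$arm[!is.na(items$arm) & !items$arm %in% arms()]
  if (length(bad)) {
    stop("ledger: unknown arm: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(items$amount)) || any(items$amount < 0)) {
    stop("ledger: item amount must be a non-negative number (field `amount`)",
         call. = FALSE)
  }
  one_off <- items$basis == "one_off"
  if (any(one_off & is.na(items$useful_life_years))) {
    stop("ledger: one_off item missing `useful_life_years`: ",
         paste(items$name[one_off & is.na(items$useful_life_years)],
               collapse = ", "), call. = FALSE)
  }
  if (any(!one_off & !is.na(items$useful_life_years))) {
    stop("ledger: `useful_life_years` only allowed for one_off items",
         call. = FALSE)
  }
  life <- items$useful_life_years[one_off]
  if (any(life < 1L | life > 5L)) {
    stop("ledger: `useful_life_years` must be in 1..5", call. = FALSE)
  }
  if (anyDuplicated(items[c("name", "arm")])) {
    stop("ledger: duplicate item name/arm pair", call. = FALSE)
  }
  invisible(items)
}

#' Per-arm annual accruals
#'
#' Annual service volumes driving variable costs and fixed-cost allocation:
#' clinic visits, PrEP client-months dispensed (one 30-pill bottle = one
#' client-month), scheduled visits per client-year (4 under quarterly
#' standard-of-care dispensing, 2 under six-month dispensing) and bottles
#' dispensed per visit (3 and 6 respectively).
#'
#' @param arm `"soc"` or `"intervention"`.
#' @param annual_visits Positive visit count.
#' @param prep_client_months Positive client-month count.
#' @param visits_per_client_year Positive scheduled annual visit count.
#' @param bottles_per_visit Positive bottles dispensed per visit.
#' @return A `prep_accrual` object.
#' @seealso [generate_accruals()] for the study defaults.
#' @export
accrual <- function(arm, annual_visits, prep_client_months,
                    visits_per_client_year, bottles_per_visit) {
  arm <- match.arg(arm, arms())
  counts <- c(annual_visits, prep_client_months, visits_per_client_year,
              bottles_per_visit)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("accrual: all counts must be positive", call. = FALSE)
  }
  structure(list(
    arm = arm, annual_visits = annual_visits,
    prep_client_months = prep_client_months,
    visits_per_client_year = visits_per_client_year,
    bottles_per_visit = bottles_per_visit
  ), class = "prep_accrual")
}

#' Assemble a cost ledger
#'
#' A ledger is the machine-readable cost-input table behind the analysis:
#' economic parameters, cadre salary tables (one per scenario tag), unit
#' prices for drugs and test kits, and the itemised cost entries. Usually
#' read from YAML with [load_ledger()].
#'
#' @param name Ledger label.
#' @param scenario_tag Active salary table, e.g. `"trial"` or `"moh"`.
#' @param params [economic_params()].
#' @param salaries `data.frame` with columns `cadre`, `annual_salary`,
#'   `currency`, `scenario_tag`.
#' @param unit_prices `data.frame` with columns `item`, `price`, `currency`.
#' @param items `data.frame` of [cost_item()] rows (may be empty).
#' @param applied_scenarios Internal record of scenario names already
#'   applied (see [apply_scenario()]).
#' @return A validated `prep_ledger` object.
#' @export
prep_ledger <- function(name, scenario_tag, params, salaries, unit_prices,
                        items, applied_scenarios = character()) {
  out <- structure(list(
    name = name, scenario_tag = scenario_tag, params = params,
    salaries = salaries, unit_prices = unit_prices, items = items,
    applied_scenarios = applied_scenarios
  ), class = "prep_ledger")
  validate_ledger(out)
}

#' @rdname prep_ledger
#' @param ledger A `prep_ledger`.
#' @export
validate_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "prep_ledger"))
  if (!inherits(ledger$params, "prep_params")) {
    stop("ledger: `params` must be economic_params()", call. = FALSE)
  }
  sal <- ledger$salaries
  need <- c("cadre", "annual_salary", "currency", "scenario_tag")
  if (!all(need %in% names(sal))) {
    stop("ledger: salaries must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(sal$cadre, cadres())
  if (length(bad)) stop("ledger: unknown cadre: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(sal$annual_salary <= 0)) {
    stop("ledger: `annual_salary` must be positive", call. = FALSE)
  }
  if (anyDuplicated(sal[c("cadre", "scenario_tag")])) {
    stop("ledger: duplicate (cadre, scenario_tag) salary", call. = FALSE)
  }
  if (!ledger$scenario_tag %in% sal$scenario_tag) {
    stop("ledger: no salary table for scenario_tag '", ledger$scenario_tag,
         "'", call. = FALSE)
  }
  up <- ledger$unit_prices
  if (!all(c("item", "price", "currency") %in% names(up))) {
    stop("ledger: unit_prices must have columns item, price, currency",
         call. = FALSE)
  }
  bad <- setdiff(up$item, price_items())
  if (length(bad)) stop("ledger: unknown priced item: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(up$price <= 0)) stop("ledger: `price` must be positive", call. = FALSE)
  if (anyDuplicated(up$item)) stop("ledger: duplicate unit price", call. = FALSE)
  validate_items(ledger$items)
  ledger
}

empty_items <- function() {
  data.frame(name = character(), category = character(), amount = numeric(),
             basis = character(), currency = character(),
             useful_life_years = integer(), arm = character(),
             base_year = integer(), stringsAsFactors = FALSE)
}

#' Read a cost ledger from YAML
#'
#' Reads a ledger document with sections `meta` (`name`, `scenario_tag`),
#' `economic_params`, `salaries`, `unit_prices` and `items` (see the schema
#' shipped at `inst/extdata/ledger-schema.json` and the packaged fixtures,
#' e.g. `system.file("extdata", "trial_2019.yaml", package = "prepcost")`).
#' Every invariant of the data model is validated on load; violations name
#' the offending field.
#'
#' @param path Path to a ledger YAML file.
#' @return A `prep_ledger`.
#' @export
#' @examples
#' led <- load_ledger(system.file("extdata", "trial_2019.yaml",
#'                                package = "prepcost"))
#' led
load_ledger <- function(path) {
  if (!file.exists(path)) stop("load_ledger: no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (sect in c("meta", "economic_params", "salaries", "unit_prices", "items")) {
    if (is.null(doc[[sect]])) {
      stop("load_ledger: missing section `", sect, "`", call. = FALSE)
    }
  }
  ep <- doc$economic_params
  params <- do.call(economic_params, ep)
  bind_rows_of <- function(lst, defaults) {
    rows <- lapply(lst, function(r) {
      miss <- setdiff(names(defaults)[vapply(defaults, is.null, TRUE)], names(r))
      if (length(miss)) {
        stop("load_ledger: entry missing field `", miss[[1]], "`", call. = FALSE)
      }
      for (f in names(defaults)) if (is.null(r[[f]])) r[[f]] <- defaults[[f]]
      as.data.frame(r[names(defaults)], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  salaries <- bind_rows_of(doc$salaries, list(
    cadre = NULL, annual_salary = NULL, currency = "USD", scenario_tag = NULL))
  unit_prices <- bind_rows_of(doc$unit_prices, list(
    item = NULL, price = NULL, currency = "USD"))
  items <- if (length(doc$items) == 0L) empty_items() else {
    bind_rows_of(doc$items, list(
      name = NULL, category = NULL, amount = NULL, basis = "per_year",
      currency = "USD", useful_life_years = NA_integer_, arm = NA_character_,
      base_year = NA_integer_))
  }
  items$useful_life_years <- as.integer(items$useful_life_years)
  items$base_year <- as.integer(items$base_year)
  prep_ledger(
    name = doc$meta$name %||% tools::file_path_sans_ext(basename(path)),
    scenario_tag = doc$meta$scenario_tag,
    params = params, salaries = salaries, unit_prices = unit_prices,
    items = items,
    applied_scenarios = as.character(doc$meta$applied_scenarios %||% character())
  )
}

#' Write a cost ledger to YAML
#'
#' Inverse of [load_ledger()]: `load_ledger(write_ledger(x, f))` is
#' content-identical to `x`.
#'
#' @param ledger A `prep_ledger`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  validate_ledger(ledger)
  df_to_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- lapply(row, function(v) if (is.factor(v)) as.character(v) else v)
      row[!vapply(row, function(v) is.na(v), TRUE)]
    })
  }
  doc <- list(
    meta = c(list(name = ledger$name, scenario_tag = ledger$scenario_tag),
             if (length(ledger$applied_scenarios))
               list(applied_scenarios = as.list(ledger$applied_scenarios))),
    economic_params = unclass(ledger$params),
    salaries = df_to_list(ledger$salaries),
    unit_prices = df_to_list(ledger$unit_prices),
    items = df_to_list(ledger$items)
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Ledger accessors
#'
#' `ledger_salaries()` returns the active (or named) salary table in USD;
#' `unit_price()` returns one commodity price in USD.
#'
#' @param ledger A `prep_ledger`.
#' @param scenario_tag Salary table to select; defaults to the ledger's
#'   active tag.
#' @return `ledger_salaries()`: `data.frame` with `cadre`, `annual_salary`
#'   (USD). `unit_price()`: a single numeric USD price.
#' @export
ledger_salaries <- function(ledger, scenario_tag = ledger$scenario_tag) {
  sal <- ledger$salaries[ledger$salaries$scenario_tag == scenario_tag, ,
                         drop = FALSE]
  if (nrow(sal) == 0L) {
    stop("ledger: no salary table for scenario_tag '", scenario_tag, "'",
         call. = FALSE)
  }
  sal$annual_salary <- mapply(function(v, cur) {
    convert_to_usd(money(v, cur), ledger$params)$value
  }, sal$annual_salary, sal$currency)
  sal[c("cadre", "annual_salary")]
}

#' @rdname ledger_salaries
#' @param item One of [price_items()].
#' @export
unit_price <- function(ledger, item) {
  row <- ledger$unit_prices[ledger$unit_prices$item == item, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("ledger: missing unit price for '", item, "'", call. = FALSE)
  }
  convert_to_usd(money(row$price[[1]], row$currency[[1]]), ledger$params)$value
}

# Items in USD at the 2019 base year: currency conversion plus forward
# inflation for entries priced in earlier years.
items_in_usd <- function(ledger, base_year = 2019L) {
  items <- ledger$items
  if (nrow(items) == 0L) return(items)
  items$amount <- vapply(seq_len(nrow(items)), function(i) {
    v <- convert_to_usd(money(items$amount[i], items$currency[i]),
                        ledger$params)$value
    if (!is.na(items$base_year[i]) && items$base_year[i] < base_year) {
      v <- inflation_adjust(v, ledger$params$inflation_rate,
                            base_year - items$base_year[i])
    }
    v
  }, numeric(1))
  items$currency <- "USD"
  items
}

#' @export
print.prep_ledger <- function(x, ...) {
  cat(sprintf("<prep_ledger> %s (scenario_tag: %s)\n", x$name, x$scenario_tag))
  cat(sprintf("  %d cost items, %d salaries, %d unit prices\n",
              nrow(x$items), nrow(x$salaries), nrow(x$unit_prices)))
  cat(sprintf("  discount %.1f%%, inflation %.1f%%, %.0f work hours/yr, %s KES/USD\n",
              100 * x$params$discount_rate, 100 * x$params$inflation_rate,
              x$params$annual_work_hours, x$params$exchange_rate_kes_per_usd))
  invisible(x)
}

#' @export
print.prep_accrual <- function(x, ...) {
  cat(sprintf("<prep_accrual> %s: %d visits/yr, %d client-months, %d visits/client-yr, %d bottles/visit\n",
              x$arm, x$annual_visits, x$prep_client_months,
              x$visits_per_client_year, x$bottles_per_visit))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
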