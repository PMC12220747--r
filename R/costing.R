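#' Annuity factor for annuitizing one-off costs
#'
#' The present value of a 1-per-year annuity over `life_years` years at
#' discount rate `rate`: `(1 - (1 + r)^-n) / r`, with the `r = 0` limit
#' equal to `n`. A one-off outlay divided by this factor gives its
#' equivalent annual cost.
#'
#' @param rate Annual discount rate in `[0, 1)`.
#' @param life_years Useful life in whole years, `>= 1`.
#' @return Dimensionless factor.
#' @export
#' @examples
#' annuity_factor(0.03, 5) # 4.579707
annuity_factor <- function(rate, life_years) {
  if (length(life_years) != 1L || is.na(life_years) || life_years < 1) {
    stop("annuity_factor: `life_years` must be >= 1", call. = FALSE)
  }
  if (rate < 0 || rate >= 1) {
    stop("annuity_factor: `rate` must be in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(as.numeric(life_years))
  # -expm1/log1p form of (1 - (1 + r)^-n) / r: stable as r -> 0
  -expm1(-life_years * log1p(rate)) / rate
}

#' Annualize ledger items
#'
#' Spreads one-off costs (capital, start-up, training) over their useful
#' life: the default annuity convention divides by
#' [annuity_factor()] at the ledger's discount rate; the straight-line
#' alternative divides by the life in years. Recurring items pass through
#' unchanged.
#'
#' @param items Ledger item `data.frame` (USD amounts).
#' @param params [economic_params()].
#' @param convention `"annuity"` (default) or `"straight_line"`.
#' @return `items` with an `annual_amount` column.
#' @export
annualize <- function(items, params, convention = c("annuity", "straight_line")) {
  convention <- match.arg(convention)
  if (nrow(items) == 0L) {
    items$annual_amount <- numeric(0)
    return(items)
  }
  items$annual_amount <- vapply(seq_len(nrow(items)), function(i) {
    if (items$basis[i] != "one_off") return(items$amount[i])
    life <- items$useful_life_years[i]
    if (is.na(life)) {
      stop("annualize: one_off item '", items$name[i],
           "' missing useful_life_years", call. = FALSE)
    }
    div <- if (convention == "annuity") {
      annuity_factor(params$discount_rate, life)
    } else {
      as.numeric(life)
    }
    items$amount[i] / div
  }, numeric(1))
  items
}

# Sum of an item's annual contribution for one arm. Driver-scaled bases
# (per_visit, per_client_month) use the arm's own accruals; recurring and
# one-off amounts not tagged with an arm are allocated by visit share.
item_annual_contribution <- function(item, arm, acc, visit_share) {
  amt <- item$annual_amount
  scaled <- switch(item$basis,
    per_visit = amt * acc$annual_visits,
    per_client_month = amt * acc$prep_client_months,
    amt # per_year and annualized one_off
  )
  if (!is.na(item$arm)) {
    if (item$arm != arm) 0 else scaled
  } else if (item$basis %in% c("per_visit", "per_client_month")) {
    scaled
  } else {
    scaled * visit_share
  }
}

#' Variable cost totals for one arm
#'
#' Accrues the five volume-driven categories over a year:
#' * `personnel_clinical`: the wage-weighted time-and-motion cost of one
#'   visit ([personnel_cost_per_visit()]) plus any per-visit personnel
#'   ledger items, times annual visits (plus per-client-month personnel
#'   items times client-months).
#' * `prep_drugs`: per-client-month drug items times client-months; when a
#'   ledger carries no drug item, the ex-works `prep_30day` unit price is
#'   used instead.
#' * `laboratory`: per visit, one rapid HIV test plus consumable items;
#'   intervention visits additionally carry self-test kits
#'   (`hivst_kits_per_visit`, default 2, priced at the mean of the
#'   oral-fluid and blood-based kit prices under 1:1 allocation); plus any
#'   per-client-month laboratory items (e.g. creatinine monitoring).
#' * `recurrent_training`, `supplies`: taken from ledger items.
#'
#' @param ledger A `prep_ledger`.
#' @param acc The arm's [accrual()].
#' @param tam Per-arm mean activity minutes, as from [activity_means()] or
#'   [reference_activity_means()].
#' @param arm `"soc"` or `"intervention"`.
#' @param visit_share Arm's share of total visits (used only for untagged
#'   non-driver items).
#' @param options List of engine switches: `hivst_kits_per_visit`,
#'   `hivst_kit_price` (default mean of the two kit prices),
#'   `annualization` convention.
#' @return Named numeric vector over [variable_categories()], unrounded USD
#'   per year.
#' @export
variable_costs <- function(ledger, acc, tam, arm = acc$arm, visit_share = 1,
                           options = list()) {
  opts <- engine_options(options)
  items <- annualize(items_in_usd(ledger), ledger$params, opts$annualization)
  out <- stats::setNames(numeric(length(variable_categories())),
                         variable_categories())
  # ledger-item contributions
  for (i in seq_len(nrow(items))) {
    cat <- items$category[i]
    if (!cat %in% variable_categories()) next
    out[[cat]] <- out[[cat]] +
      item_annual_contribution(items[i, ], arm, acc, visit_share)
  }
  # wage-weighted activity time
  m <- tam[tam$arm == arm & tam$activity != "total", , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("variable_costs: no activity means for arm '", arm, "'", call. = FALSE)
  }
  sal <- ledger_salaries(ledger)
  tam_cost <- personnel_cost_per_visit(
    stats::setNames(m$mean_minutes, m$activity), sal, ledger$params)
  out[["personnel_clinical"]] <- out[["personnel_clinical"]] +
    tam_cost * acc$annual_visits
  # per-visit testing commodities
  lab_per_visit <- unit_price(ledger, "determine_rapid_test")
  if (arm == "intervention" && opts$hivst_kits_per_visit > 0) {
    kit <- opts$hivst_kit_price %||%
      mean(c(unit_price(ledger, "oraquick_hivst"),
             unit_price(ledger, "atomo_hivst")))
    lab_per_visit <- lab_per_visit + opts$hivst_kits_per_visit * kit
  }
  out[["laboratory"]] <- out[["laboratory"]] + lab_per_visit * acc$annual_visits
  # drugs: ex-works price fallback when no drug item is in the ledger
  if (!any(items$category == "prep_drugs")) {
    out[["prep_drugs"]] <- unit_price(ledger, "prep_30day") *
      acc$prep_client_months
  }
  out
}

engine_options <- function(options) {
  defaults <- list(hivst_kits_per_visit = 2, hivst_kit_price = NULL,
                   annualization = "annuity")
  bad <- setdiff(names(options), names(defaults))
  if (length(bad)) stop("unknown engine option: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  utils::modifyList(defaults, options, keep.null = TRUE)
}

#' Allocate fixed category totals across arms by visit share
#'
#' Splits each fixed category total in proportion to the visits accrued in
#' each arm. The two arm amounts always sum to the category total to the
#' cent; any residual cent from rounding is assigned to the larger arm.
#'
#' @param totals Named numeric vector of annual category totals.
#' @param accruals List with `soc` and `intervention` [accrual()]s.
#' @return `data.frame` with `category`, `soc`, `intervention` (USD,
#'   rounded to cents).
#' @export
#' @examples
#' acc <- generate_accruals()
#' allocate_fixed(c(capital = 1000), acc)
allocate_fixed <- function(totals, accruals) {
  vs <- accruals$soc$annual_visits
  vi <- accruals$intervention$annual_visits
  if (vs + vi <= 0) stop("allocate_fixed: zero total visits", call. = FALSE)
  share <- vs / (vs + vi)
  soc <- round_cents(totals * share)
  int <- round_cents(totals) - soc
  # keep both halves individually faithful; push any residual cent to the
  # larger arm
  int2 <- round_cents(totals * (1 - share))
  resid <- round_cents(totals) - (soc + int2)
  if (share >= 0.5) soc <- soc + resid else int2 <- int2 + resid
  data.frame(category = names(totals), soc = as.numeric(soc),
             intervention = as.numeric(int2), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fixed cost totals for one arm
#'
#' Annualizes and sums the five fixed categories. Arm-tagged ledger items
#' contribute to their arm directly; untagged items are allocated by the
#' arm's share of total visits.
#'
#' @inheritParams variable_costs
#' @param accruals List with `soc` and `intervention` [accrual()]s (for the
#'   visit share).
#' @return Named numeric vector over [fixed_categories()], unrounded USD
#'   per year.
#' @export
fixed_costs <- function(ledger, accruals, arm, options = list()) {
  opts <- engine_options(options)
  items <- annualize(items_in_usd(ledger), ledger$params, opts$annualization)
  vs <- accruals$soc$annual_visits
  vi <- accruals$intervention$annual_visits
  if (vs + vi <= 0) stop("fixed_costs: zero total visits", call. = FALSE)
  share <- if (arm == "soc") vs / (vs + vi) else vi / (vs + vi)
  acc <- accruals[[arm]]
  out <- stats::setNames(numeric(length(fixed_categories())),
                         fixed_categories())
  for (i in seq_len(nrow(items))) {
    cat <- items$category[i]
    if (!cat %in% fixed_categories()) next
    out[[cat]] <- out[[cat]] + item_annual_contribution(items[i, ], arm, acc, share)
  }
  out
}

#' Unit cost per client-month
#'
#' The headline statistic: total annual delivery cost divided by the
#' PrEP client-months dispensed in the year.
#'
#' @param grand_total Annual total cost (USD).
#' @param prep_client_months Positive client-month count.
#' @return Unrounded USD per client-month; round with [round_cents()] for
#'   display.
#' @export
#' @examples
#' round_cents(unit_cost_per_client_month(23284.74, 913)) # 25.50
unit_cost_per_client_month <- function(grand_total, prep_client_months) {
  if (length(prep_client_months) != 1L || prep_client_months <= 0) {
    stop("unit_cost_per_client_month: `prep_client_months` must be positive",
         call. = FALSE)
  }
  grand_total / prep_client_months
}

#' Category shares of total cost
#'
#' Each category's fraction of the grand total. Display as whole percents
#' with `round_half_up(100 * shares)`.
#'
#' @param category_totals Named numeric vector of category totals.
#' @param grand_total Positive total; defaults to `sum(category_totals)`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
cost_shares <- function(category_totals, grand_total = sum(category_totals)) {
  if (grand_total <= 0) stop("cost_shares: zero total cost", call. = FALSE)
  category_totals / grand_total
}

#' Build a per-arm annual cost report
#'
#' Runs the full micro-costing arithmetic for one arm: variable costs
#' accrued against the arm's visits and client-months
#' ([variable_costs()]), fixed costs annualized and attributed
#' ([fixed_costs()]), category totals rounded half-even to cents,
#' subtotals, the grand total, per client-month unit costs and category
#' shares.
#'
#' @inheritParams fixed_costs
#' @param tam Per-arm mean activity minutes (see [activity_means()]).
#' @param scenario_tag Label recorded on the report; defaults to the
#'   ledger's active tag.
#' @return A `prep_arm_report` object.
#' @export
#' @examples
#' led <- load_ledger(system.file("extdata", "trial_2019.yaml",
#'                                package = "prepcost"))
#' rep <- build_arm_report(led, generate_accruals(), "soc",
#'                         reference_activity_means())
#' rep
build_arm_report <- function(ledger, accruals, arm, tam,
                             scenario_tag = ledger$scenario_tag,
                             options = list()) {
  arm <- match.arg(arm, arms())
  acc <- accruals[[arm]]
  if (is.null(acc)) stop("build_arm_report: no accrual for arm ", arm,
                         call. = FALSE)
  vc <- variable_costs(ledger, acc, tam, arm,
                       visit_share = acc$annual_visits /
                         (accruals$soc$annual_visits +
                          accruals$intervention$annual_visits),
                       options = options)
  fc <- fixed_costs(ledger, accruals, arm, options = options)
  cat_tot <- round_cents(c(vc, fc))[names(cost_categories())]
  var_sub <- sum(cat_tot[variable_categories()])
  fix_sub <- sum(cat_tot[fixed_categories()])
  grand <- var_sub + fix_sub
  if (grand <= 0) stop("build_arm_report: zero total cost", call. = FALSE)
  months <- acc$prep_client_months
  structure(list(
    arm = arm, scenario_tag = scenario_tag,
    category_totals = cat_tot,
    variable_subtotal = var_sub, fixed_subtotal = fix_sub,
    grand_total = grand,
    unit_costs = round_cents(cat_tot / months),
    unit_cost_total = unit_cost_per_client_month(grand, months),
    shares = cost_shares(cat_tot, grand),
    prep_client_months = months, annual_visits = acc$annual_visits
  ), class = "prep_arm_report")
}

#' @export
print.prep_arm_report <- function(x, ...) {
  cat(sprintf("<prep_arm_report> %s arm, scenario '%s' (%d visits, %d client-months)\n",
              x$arm, x$scenario_tag, x$annual_visits, x$prep_client_months))
  df <- report_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

# Report as a display data.frame in canonical row order.
report_table <- function(report) {
  cats <- names(cost_categories())
  df <- data.frame(
    category = unname(category_labels[cats]),
    cost_class = unname(cost_categories()[cats]),
    total_annual_cost = sprintf("%.2f", report$category_totals[cats]),
    per_client_month = sprintf("%.2f", report$unit_costs[cats]),
    pct_of_total = sprintf("%d%%", round_half_up(100 * report$shares[cats])),
    stringsAsFactors = FALSE
  )
  rbind(
    df[df$cost_class == "variable", ],
    data.frame(category = "Sub-total (variable)", cost_class = "",
               total_annual_cost = sprintf("%.2f", report$variable_subtotal),
               per_client_month = sprintf("%.2f", round_cents(
                 report$variable_subtotal / report$prep_client_months)),
               pct_of_total = sprintf("%d%%", round_half_up(
                 100 * report$variable_subtotal / report$grand_total))),
    df[df$cost_class == "fixed", ],
    data.frame(category = "Sub-total (fixed)", cost_class = "",
               total_annual_cost = sprintf("%.2f", report$fixed_subtotal),
               per_client_month = sprintf("%.2f", round_cents(
                 report$fixed_subtotal / report$prep_client_months)),
               pct_of_total = sprintf("%d%%", round_half_up(
                 100 * report$fixed_subtotal / report$grand_total))),
    data.frame(category = "Total costs", cost_class = "",
               total_annual_cost = sprintf("%.2f", report$grand_total),
               per_client_month = sprintf("%.2f",
                                          round_cents(report$unit_cost_total)),
               pct_of_total = "100%")
  )
}
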