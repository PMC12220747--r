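# Shared fixtures and independent oracles for the test suite.

fixture_path <- function(name) {
  system.file("extdata", name, package = "prepcost")
}

trial_ledger <- function() load_ledger(fixture_path("trial_2019.yaml"))
moh_ledger <- function() load_ledger(fixture_path("moh_2019.yaml"))
moh_creatinine_ledger <- function() {
  load_ledger(fixture_path("moh_creatinine_2019.yaml"))
}

study_accruals <- function() generate_accruals()

# Independent brute-force re-derivation of a per-arm grand total:
# item-by-item loop with scalar arithmetic, no engine code reused.
brute_force_total <- function(ledger, accruals, arm, tam) {
  p <- ledger$params
  acc <- accruals[[arm]]
  total_visits <- accruals$soc$annual_visits + accruals$intervention$annual_visits
  share <- acc$annual_visits / total_visits
  cats <- stats::setNames(numeric(length(cost_categories())),
                          names(cost_categories()))
  for (i in seq_len(nrow(ledger$items))) {
    it <- as.list(ledger$items[i, ])
    amt <- it$amount
    if (it$currency == "KES") amt <- round(amt / p$exchange_rate_kes_per_usd, 2)
    if (!is.na(it$base_year) && it$base_year < 2019) {
      amt <- amt * (1 + p$inflation_rate)^(2019 - it$base_year)
    }
    if (it$basis == "one_off") {
      r <- p$discount_rate
      n <- it$useful_life_years
      fac <- if (r == 0) n else (1 - (1 + r)^(-n)) / r
      amt <- amt / fac
    }
    mult <- 1
    if (it$basis == "per_visit") mult <- acc$annual_visits
    if (it$basis == "per_client_month") mult <- acc$prep_client_months
    if (!is.na(it$arm)) {
      if (it$arm == arm) cats[[it$category]] <- cats[[it$category]] + amt * mult
    } else if (it$basis %in% c("per_visit", "per_client_month")) {
      cats[[it$category]] <- cats[[it$category]] + amt * mult
    } else {
      cats[[it$category]] <- cats[[it$category]] + amt * mult * share
    }
  }
  # wage-weighted activity time, one activity at a time
  sal <- ledger$salaries[ledger$salaries$scenario_tag == ledger$scenario_tag, ]
  map <- activity_cadre_map()
  wage_cost <- 0
  for (a in names(map)) {
    mm <- tam$mean_minutes[tam$arm == arm & tam$activity == a]
    w <- sal$annual_salary[sal$cadre == map[[a]]] / p$annual_work_hours
    wage_cost <- wage_cost + mm / 60 * w
  }
  cats[["personnel_clinical"]] <- cats[["personnel_clinical"]] +
    wage_cost * acc$annual_visits
  price_of <- function(nm) {
    ledger$unit_prices$price[ledger$unit_prices$item == nm]
  }
  lab <- price_of("determine_rapid_test")
  if (arm == "intervention") {
    lab <- lab + 2 * (price_of("oraquick_hivst") + price_of("atomo_hivst")) / 2
  }
  cats[["laboratory"]] <- cats[["laboratory"]] + lab * acc$annual_visits
  if (!any(ledger$items$category == "prep_drugs")) {
    cats[["prep_drugs"]] <- price_of("prep_30day") * acc$prep_client_months
  }
  sum(round(cats, 2))
}

# Minimal hand-built observation log: one visit with explicit clock times.
tiny_log <- function() {
  data.frame(
    visit_id = "v1", arm = "soc", visit_type = "enrollment",
    activity = c("counselling_hiv_testing", "clinical_examination",
                 "waiting", "laboratory_testing", "prep_dispensing"),
    cadre = c("hiv_testing_counsellor", "clinical_officer", NA,
              "nurse", "pharmacy_technologist"),
    start_time = c("09:00:00", "09:33:00", "09:53:00", "10:08:00", "10:13:00"),
    end_time   = c("09:33:00", "09:53:00", "10:08:00", "10:13:00", "10:34:00"),
    stringsAsFactors = FALSE
  )
}
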