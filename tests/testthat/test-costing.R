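test_that("annuity factor matches its closed form and the zero-rate limit", {
  expect_equal(annuity_factor(0, 5), 5)
  expect_equal(annuity_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_equal(annuity_factor(0.03, 5), 4.579707, tolerance = 1e-6)
  # continuity as the rate vanishes
  for (n in 1:5) {
    expect_lt(abs(annuity_factor(1e-12, n) - n), 1e-6)
  }
  expect_error(annuity_factor(0.03, 0), ">= 1")
  expect_error(annuity_factor(1.5, 5), "rate")
})

test_that("annualization spreads one-off costs and passes recurring through", {
  p <- economic_params()
  it <- rbind(
    cost_item("cap", "capital", 100, basis = "one_off", useful_life_years = 5L),
    cost_item("train", "startup_training", 100, basis = "one_off",
              useful_life_years = 1L),
    cost_item("oh", "overhead", 500, basis = "per_year")
  )
  ann <- annualize(it, p)
  expect_equal(round_cents(ann$annual_amount[1]), 21.84)
  expect_equal(ann$annual_amount[3], 500)
  # a one-year life with no discounting returns the amount unchanged
  p0 <- economic_params(discount_rate = 0)
  expect_equal(annualize(it, p0)$annual_amount[2], 100)
  # the annualized amount is never below straight-line when discounting
  sl <- annualize(it, p, convention = "straight_line")
  expect_true(all(ann$annual_amount >= sl$annual_amount - 1e-12))
})

test_that("variable costs accrue against visits and client-months", {
  led <- trial_ledger()
  acc <- study_accruals()
  tam <- reference_activity_means()
  vc_soc <- variable_costs(led, acc$soc, tam, "soc")
  # drug spend is the delivered per-client-month price times months
  expect_equal(round_cents(vc_soc[["prep_drugs"]]), 6547.27)
  expect_equal(round_cents(vc_soc[["personnel_clinical"]]), 7539.81)
  # a bare ledger with only the rapid test accrues price times visits
  bare <- led
  bare$items <- bare$items[0, ]
  acc10 <- generate_accruals(10, 10)
  vc <- variable_costs(bare, acc10$soc, tam, "soc")
  expect_equal(round_cents(vc[["laboratory"]]), 8.30)
  # drug fallback: ex-works price per client-month
  expect_equal(vc[["prep_drugs"]], 6.75 * acc10$soc$prep_client_months)
  # intervention visits additionally carry two self-test kits at the mean
  # of the oral-fluid and blood-based prices
  vci <- variable_costs(bare, acc10$intervention, tam, "intervention")
  expect_equal(round_cents(vci[["laboratory"]]),
               round_cents((0.83 + 2 * (4.27 + 6.17) / 2) * 10))
})

test_that("fixed allocation splits by visit share and conserves totals", {
  acc <- study_accruals()
  al <- allocate_fixed(c(capital = 1000), acc)
  expect_equal(al$soc, 472.05)
  expect_equal(al$intervention, 527.95)
  # conservation to the cent, residual cent to the larger arm
  for (total in c(1000, 33.335, 0.01, 777.77, 123456.789)) {
    al <- allocate_fixed(c(x = total), acc)
    expect_equal(al$soc + al$intervention, round_cents(total))
  }
  # equal visits split exactly in half
  eq <- generate_accruals(100, 100)
  al <- allocate_fixed(c(x = 500), eq)
  expect_equal(al$soc, 250)
  expect_equal(al$intervention, 250)
  # degenerate: one arm holds (nearly) all visits
  skew <- generate_accruals(1000000, 1)
  al <- allocate_fixed(c(x = 100), skew)
  expect_equal(al$soc, 100)
})

test_that("unit costs divide totals by client-months", {
  expect_equal(round_cents(unit_cost_per_client_month(23284.74, 913)), 25.50)
  expect_equal(round_cents(unit_cost_per_client_month(36144.35, 2039)), 17.73)
  expect_equal(unit_cost_per_client_month(100, 100), 1.00)
  expect_error(unit_cost_per_client_month(100, 0), "positive")
})

test_that("cost shares are fractions of the grand total", {
  expect_equal(round_half_up(100 * cost_shares(
    c(personnel_clinical = 7539.81), 23284.74)[[1]]), 32)
  expect_equal(round_half_up(100 * cost_shares(
    c(prep_drugs = 14486.20), 36144.35)[[1]]), 40)
  expect_equal(cost_shares(c(a = 42))[["a"]], 1)
  expect_error(cost_shares(c(a = 0)), "zero total")
})

test_that("per-arm reports reproduce the published annual cost tables", {
  led <- trial_ledger()
  acc <- study_accruals()
  tam <- reference_activity_means()
  soc <- build_arm_report(led, acc, "soc", tam)
  int <- build_arm_report(led, acc, "intervention", tam)
  expect_equal(soc$grand_total, 23284.74, tolerance = 0.05 / 23284.74)
  expect_equal(int$grand_total, 36144.35, tolerance = 0.05 / 36144.35)
  expect_equal(round_cents(soc$unit_cost_total), 25.50)
  expect_equal(round_cents(int$unit_cost_total), 17.73)
  expect_equal(soc$category_totals[["laboratory"]], 1812.91)
  expect_equal(int$category_totals[["laboratory"]], 5773.97)
  expect_equal(soc$variable_subtotal + soc$fixed_subtotal, soc$grand_total)
  # all-zero ledger errors rather than reporting undefined shares
  zero <- led
  zero$items <- zero$items[0, ]
  zero$unit_prices$price <- 1e-9
  zero_tam <- tam
  zero_tam$mean_minutes <- rep(1e-9, nrow(tam))
  expect_error(suppressWarnings(
    build_arm_report(zero, acc, "soc", zero_tam)), "zero total")
})

test_that("report arithmetic matches an item-by-item brute-force oracle", {
  acc <- study_accruals()
  tam <- reference_activity_means()
  for (led in list(trial_ledger(), moh_creatinine_ledger(),
                   generate_ledger("trial", jitter = 0.1, seed = 17))) {
    for (a in arms()) {
      rep <- build_arm_report(led, acc, a, tam)
      expect_equal(rep$grand_total, brute_force_total(led, acc, a, tam),
                   tolerance = 1e-9)
    }
  }
})

test_that("unit cost strictly decreases as client-months grow", {
  led <- trial_ledger()
  tam <- reference_activity_means()
  months <- c(500, 913, 1500, 2500, 4000)
  units <- vapply(months, function(m) {
    acc <- generate_accruals(soc_months = m)
    build_arm_report(led, acc, "soc", tam)$unit_cost_total
  }, numeric(1))
  expect_true(all(diff(units) < 0))
})

test_that("ten category totals sum to the grand total to the cent", {
  acc <- study_accruals()
  tam <- reference_activity_means()
  for (seed in 1:5) {
    led <- generate_ledger("moh", jitter = 0.25, seed = seed)
    r <- build_arm_report(led, acc, "intervention", tam)
    expect_equal(sum(r$category_totals), r$grand_total, tolerance = 1e-12)
    expect_equal(sum(r$shares), 1, tolerance = 1e-12)
    expect_lt(abs(r$unit_cost_total * r$prep_client_months - r$grand_total),
              0.005 * r$prep_client_months)
  }
})
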