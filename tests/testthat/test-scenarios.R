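moh_scn <- function() read_scenario(fixture_path("moh_scenario.yaml"))
creat_scn <- function() read_scenario(fixture_path("creatinine_addon.yaml"))

test_that("the public-clinic scenario swaps salaries and start-up items", {
  led <- apply_scenario(trial_ledger(), moh_scn())
  expect_identical(led$scenario_tag, "moh")
  sal <- ledger_salaries(led)
  expect_equal(sal$annual_salary[sal$cadre == "clinical_officer"], 7290)
  # the transformed ledger coincides with the shipped public-clinic ledger
  ref <- moh_ledger()
  key <- function(items) items[order(items$name, items$arm), ]
  expect_equal(key(led$items), key(ref$items), ignore_attr = TRUE)
  expect_equal(led$unit_prices, ref$unit_prices)
})

test_that("an empty scenario is the identity", {
  led <- trial_ledger()
  led2 <- apply_scenario(led, scenario("noop"))
  expect_equal(led2$items, led$items)
  expect_equal(led2$salaries, led$salaries)
  expect_identical(led2$scenario_tag, led$scenario_tag)
})

test_that("the creatinine add-on prices two tests per client-year", {
  led <- apply_scenario(moh_ledger(), creat_scn())
  kit <- led$items[led$items$name == "creatinine_tests", ]
  expect_equal(kit$category, "laboratory")
  expect_equal(kit$amount, 2.51 * 2 / 12, tolerance = 1e-6)
  # and coincides with the shipped with-creatinine ledger
  ref <- moh_creatinine_ledger()
  key <- function(items) items[order(items$name, items$arm), ]
  expect_equal(key(led$items), key(ref$items), ignore_attr = TRUE)
})

test_that("scenario application is idempotent and add-ons commute with swaps", {
  led <- trial_ledger()
  once <- apply_scenario(led, moh_scn())
  twice <- apply_scenario(once, moh_scn())
  expect_equal(twice$items, once$items)
  ab <- apply_scenario(apply_scenario(led, moh_scn()), creat_scn())
  ba <- apply_scenario(apply_scenario(led, creat_scn()), moh_scn())
  key <- function(items) items[order(items$name, items$arm), ]
  expect_equal(key(ab$items), key(ba$items), ignore_attr = TRUE)
  expect_identical(ab$scenario_tag, ba$scenario_tag)
})

test_that("scenario validation rejects bad edits", {
  expect_error(apply_scenario(trial_ledger(),
                              scenario("bad", remove_items = "no_such_item")),
               "nonexistent")
  expect_error(scenario("bad", add_items = cost_item("x", "capital", 1,
                                                     basis = "one_off",
                                                     useful_life_years = 1L),
                        remove_items = "x"),
               "disjoint")
  expect_error(apply_scenario(trial_ledger(), scenario("bad",
                                                       salary_table = "nhs")),
               "no salary table")
})

test_that("scenarios never touch accruals or client-month denominators", {
  acc <- study_accruals()
  led <- apply_scenario(trial_ledger(), moh_scn())
  r <- build_arm_report(led, acc, "soc", reference_activity_means())
  expect_equal(r$prep_client_months, 913)
  expect_equal(r$annual_visits, 304)
})

test_that("arm comparisons report cent differences and whole percents", {
  expect_equal(compare_unit_costs(25.50, 17.73, "as_implemented")$abs_difference,
               7.77)
  expect_equal(compare_unit_costs(25.50, 17.73)$pct_difference, 30)
  expect_equal(compare_unit_costs(14.76, 11.94)$abs_difference, 2.82)
  expect_equal(compare_unit_costs(14.76, 11.94)$pct_difference, 19)
  same <- compare_unit_costs(12.34, 12.34)
  expect_equal(same$abs_difference, 0)
  expect_equal(same$pct_difference, 0)
  a <- build_arm_report(trial_ledger(), study_accruals(), "soc",
                        reference_activity_means())
  b <- build_arm_report(moh_ledger(), study_accruals(), "intervention",
                        reference_activity_means())
  expect_error(compare_arms(a, b), "different scenarios")
})

test_that("the scenario matrix reports one row per scenario with unit shares", {
  acc <- study_accruals()
  mat <- scenario_matrix(trial_ledger(), acc,
                         scenarios = list(moh = moh_scn()))
  expect_equal(nrow(mat$comparison), 2L)
  expect_equal(mat$comparison$scenario, c("trial", "moh"))
  # single scenario: single row
  expect_equal(nrow(scenario_matrix(trial_ledger(), acc)$comparison), 1L)
  # shares per scenario/arm sum to 100 within 0.5
  agg <- stats::aggregate(share_pct ~ scenario + arm, data = mat$shares, sum)
  expect_true(all(abs(agg$share_pct - 100) < 0.5))
})

test_that("lowering all salaries weakly lowers both arms' unit costs", {
  acc <- study_accruals()
  tam <- reference_activity_means()
  led <- trial_ledger()
  cheaper <- led
  cheaper$salaries$annual_salary <- cheaper$salaries$annual_salary * 0.5
  for (a in arms()) {
    u_hi <- build_arm_report(led, acc, a, tam)$unit_cost_total
    u_lo <- build_arm_report(cheaper, acc, a, tam)$unit_cost_total
    expect_lte(u_lo, u_hi)
  }
})
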