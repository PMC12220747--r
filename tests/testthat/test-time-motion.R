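test_that("activity durations subtract clock times and exclude waiting", {
  d <- activity_durations(tiny_log())
  expect_equal(d$minutes, c(33, 20, 15, 5, 21))
  expect_equal(d$is_waiting, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # per-visit provider total: 33 + 20 + 5 + 21 = 79, waiting not counted
  tot <- visit_totals(tiny_log())
  expect_equal(tot$minutes, 79)
  # a visit holding only a waiting record totals zero provider minutes
  waiting_only <- tiny_log()[3, ]
  expect_equal(visit_totals(waiting_only)$minutes, 0)
})

test_that("an end time before its start time is rejected, naming the visit", {
  bad <- tiny_log()
  bad$end_time[1] <- "08:59:00"
  expect_error(activity_durations(bad), "end before start in visit v1")
})

test_that("overlapping activities for one provider are rejected", {
  bad <- tiny_log()
  bad$activity[3] <- "counselling_hiv_testing"
  bad$cadre[3] <- "hiv_testing_counsellor"
  bad$start_time[3] <- "09:10:00" # overlaps the 09:00-09:33 counselling slot
  bad$end_time[3] <- "09:20:00"
  expect_error(validate_observation_log(bad), "overlapping")
})

test_that("summaries use interpolated quartiles, n-1 SD and half-up display", {
  # three refill visits with counselling durations 25, 24, 36 minutes
  log <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(visit_id = paste0("v", i), arm = "soc", visit_type = "refill",
               activity = "counselling_hiv_testing",
               cadre = "hiv_testing_counsellor",
               start_time = "09:00:00",
               end_time = sprintf("09:%02d:00", c(25, 24, 36)[i]),
               stringsAsFactors = FALSE)
  }))
  s <- summarize_durations(log, arm = "soc")
  row <- s[s$activity == "counselling_hiv_testing", ]
  expect_equal(row$n, 3L)
  expect_equal(row$median, 25)
  expect_equal(row$q1, 24.5) # type-7 linear interpolation
  expect_equal(row$q3, 30.5)
  expect_equal(row$mean, 85 / 3)
  expect_equal(round_half_up(row$mean), 28)
  expect_equal(row$sd, sd(c(25, 24, 36)))
  # single observation: median = mean = value, degenerate IQR, sd undefined
  s1 <- summarize_durations(log[log$visit_id == "v1", ])
  expect_equal(s1$median[1], s1$mean[1])
  expect_equal(s1$q1[1], s1$q3[1])
  expect_true(is.na(s1$sd[1]))
  expect_error(summarize_durations(log, visit_type = "enrollment"),
               "no observations")
})

test_that("enrollment strata pool both arms", {
  cfg <- synth_config(seed = 11)
  log <- generate_observation_log(cfg)
  pooled <- summarize_durations(log, arm = "soc", visit_type = "enrollment")
  expect_identical(pooled$arm[1], "all")
  n_enr <- length(unique(log$visit_id[log$visit_type == "enrollment"]))
  expect_equal(pooled$n[pooled$activity == "total"], n_enr)
})

test_that("annual projection is the per-visit mean times the visit schedule", {
  expect_equal(project_annual(76, 2), 152)
  expect_equal(project_annual(54, 4), 216)
  expect_equal(project_annual(37.5, 1), 37.5)
  # linear in both arguments
  expect_equal(project_annual(3 * 11, 2), 3 * project_annual(11, 2))
  expect_equal(project_annual(11, 4), 2 * project_annual(11, 2))
  # unrounded per-activity projections sum to the projected total
  m <- c(27.4, 16.8, 3.1, 6.9)
  expect_equal(sum(project_annual(m, 4)), project_annual(sum(m), 4))
  expect_error(project_annual(76, 0), "positive")
  expect_error(project_annual(-1, 2), "positive")
})

test_that("per-visit personnel cost applies each cadre's hourly wage", {
  params <- economic_params()
  sal <- data.frame(cadre = cadres(),
                    annual_salary = c(9365, 10841, 9984, 10085))
  # unit wage: 60 minutes at salary equal to annual hours costs exactly 1
  unit <- data.frame(cadre = "nurse", annual_salary = 2080)
  expect_equal(personnel_cost_per_visit(c(laboratory_testing = 60), unit,
                                        params), 1.00)
  expect_equal(personnel_cost_per_visit(numeric(0), sal, params), 0)
  expect_equal(
    personnel_cost_per_visit(c(clinical_examination = 20), sal, params),
    10841 / 2080 * (20 / 60), tolerance = 1e-10)
  expect_error(
    personnel_cost_per_visit(c(clinical_examination = 5),
                             sal[sal$cadre != "clinical_officer", ], params),
    "clinical_officer")
})

test_that("personnel costing matches a per-minute wage accumulation oracle", {
  cfg <- synth_config(seed = 3, n_soc = 40, n_intervention = 40)
  log <- generate_observation_log(cfg)
  sal <- ledger_salaries(trial_ledger())
  params <- economic_params()
  map <- activity_cadre_map()
  d <- activity_durations(log)
  total_engine <- 0
  total_oracle <- 0
  for (vid in unique(d$visit_id)) {
    sub <- d[d$visit_id == vid & !d$is_waiting, ]
    mins <- tapply(sub$minutes, sub$activity, sum)
    total_engine <- total_engine +
      personnel_cost_per_visit(stats::setNames(as.numeric(mins), names(mins)),
                               sal, params)
    # brute force: every record valued minute by minute
    for (i in seq_len(nrow(sub))) {
      wage_min <- sal$annual_salary[sal$cadre == map[[sub$activity[i]]]] /
        params$annual_work_hours / 60
      total_oracle <- total_oracle + sub$minutes[i] * wage_min
    }
  }
  expect_lt(abs(total_engine - total_oracle), 0.01)
})

test_that("summaries recover generating means within 3 SE at n = 500", {
  cfg <- synth_config(seed = 202, n_soc = 500, n_intervention = 500,
                      n_enrollment_soc = 0, n_enrollment_intervention = 0)
  log <- generate_observation_log(cfg)
  for (a in arms()) {
    s <- summarize_durations(log, arm = a)
    for (act in names(activity_cadre_map())) {
      truth <- cfg$means$mean_minutes[cfg$means$arm == a &
                                        cfg$means$activity == act]
      row <- s[s$activity == act, ]
      se <- row$sd / sqrt(row$n)
      expect_lt(abs(row$mean - truth), 3 * se + 1e-9)
    }
  }
})

test_that("observation logs survive a CSV round trip, case-insensitively", {
  log <- generate_observation_log(synth_config(seed = 5))
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- log
  names(out) <- toupper(names(out))
  utils::write.csv(out, tmp, row.names = FALSE, na = "")
  log2 <- read_observation_log(tmp)
  expect_equal(log2$start_time, log$start_time)
  expect_equal(activity_means(log2), activity_means(log))
  expect_error(read_observation_log(withr::local_tempfile()), "no such file")
})
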