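test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config(seed = 7)
  expect_identical(generate_ledger(cfg), generate_ledger(cfg))
  expect_identical(generate_worker_survey(cfg), generate_worker_survey(cfg))
  l2 <- generate_ledger(synth_config(seed = 8))
  expect_false(identical(generate_ledger(cfg)$amount, l2$amount))
})

test_that("the synthetic ledger reproduces every target margin cell through the pipeline", {
  run <- default_run()
  m <- reference_margins()
  tab <- run$table
  for (panel in c("activity", "input", "stage")) {
    got <- tab[tab$panel == panel, ]
    ref <- m[[panel]]
    expect_lt(max(abs(got$financial - ref$financial)), 0.0105)
    expect_lt(max(abs(got$economic - ref$economic)), 0.0105)
  }
  expect_equal(run$totals[["total"]], 795040.34, tolerance = 1e-6)
})

test_that("different seeds give different line items but identical coded margins", {
  inp_a <- default_inputs()
  inp_b <- generate_inputs(synth_config(seed = 202))
  expect_false(identical(inp_a$ledger$amount, inp_b$ledger$amount))
  tab_a <- default_run()$table
  tab_b <- run_costing(inp_b)$table
  expect_lt(max(abs(tab_a$financial - tab_b$financial)), 0.0105)
  expect_lt(max(abs(tab_a$economic - tab_b$economic)), 0.0105)
})

test_that("worker survey moments converge to the configured gamma moments", {
  cfg <- synth_config(seed = 31, n_pk = 2500)
  ws <- generate_worker_survey(cfg)
  n <- nrow(ws)
  expect_equal(n, 2500 * 40)
  expect_lt(abs(mean(ws$overtime_h) - 4.24), 3 * 2.34 / sqrt(n))
  expect_lt(abs(mean(ws$travel_h) - 19.65), 3 * 10.28 / sqrt(n))
  p1 <- ws$oop_usd[ws$month <= 16]
  expect_lt(abs(mean(p1) - 6.55), 3 * 3.02 / sqrt(length(p1)))
  p3 <- ws$oop_usd[ws$month >= 33]
  expect_lt(abs(mean(p3) - 1.45), 3 * 2.00 / sqrt(length(p3)))
})

test_that("beneficiary time use: women participate about twice as much as men", {
  bt <- default_inputs()$beneficiary_timeuse
  expect_gt(mean(bt$women_h), mean(bt$men_h, na.rm = TRUE))
  n_w <- sum(!is.na(bt$women_h))
  expect_lt(abs(mean(bt$women_h) - 1.8), 3 * 1.66 / sqrt(n_w))
  n_m <- sum(!is.na(bt$men_h))
  expect_lt(abs(mean(bt$men_h, na.rm = TRUE) - 0.96),
            3 * 1.22 / sqrt(n_m))
  # spouse rows exist only for the index-pair surplus over households
  gc <- table(bt$arm[!is.na(bt$men_h) & bt$month == 0])
  expect_equal(unname(gc[c("2", "3", "4")]),
               c(2353, 2398, 2339) - 1260, ignore_attr = TRUE)
})

test_that("infeasible margin targets are rejected with the dimension named", {
  m <- reference_margins()
  m$stage$financial <- c(500000, sum(m$stage$financial) - 500000)
  expect_error(generate_ledger(synth_config(margins = m)), "stage")

  m2 <- reference_margins()
  m2$input$financial[1] <- m2$input$financial[1] + 1e6
  expect_error(synth_config(margins = m2), "inconsistent")
})

test_that("single-activity margins force all entries onto that activity", {
  m <- reference_margins()
  keep <- "community_events"
  m$activity$financial <- ifelse(m$activity$activity == keep,
                                 sum(m$activity$financial), 0)
  m$activity$economic <- ifelse(m$activity$activity == keep,
                                sum(m$activity$economic), 0)
  m$stage$financial <- c(0, sum(m$stage$financial))
  # fold the agriculture-specific inputs (normally pinned to agriculture
  # activities) into general supplies so a one-activity budget is feasible
  inp <- m$input
  ag <- inp$input %in% c("agriculture_supplies", "agriculture_equipment",
                         "fuel_maintenance")
  inp$financial[inp$input == "supplies"] <-
    inp$financial[inp$input == "supplies"] + sum(inp$financial[ag])
  inp$financial[ag] <- 0
  m$input <- inp
  cfg <- synth_config(
    seed = 5, margins = m, dm_charge_usd = 0, startup_planning_usd = 0,
    pk_profile = list(cadre = "PK", fte_share = 1,
                      activity_shares = c(community_events = 1))
  )
  led <- generate_ledger(cfg)
  hints <- unique(led$activity_hint[!is.na(led$activity_hint)])
  expect_equal(hints, keep)
})

test_that("the ledger exercises the capital and tax rules", {
  led <- default_inputs()$ledger
  expect_true(any(led$durable))
  dur <- led[led$durable, ]
  expect_true(all(dur$expected_life_years > 1))
  # sub-threshold durable is expensed, so the equipment margin stays intact
  p <- valuation_params()
  expect_true(all(dur$amount / p$exchange_rate_bdt_per_usd <=
                    p$capital_threshold_usd))
  expect_true(any(led$tax_amount > 0))
  expect_true(all(led$tax_amount <= led$amount + 1e-9))
})

test_that("solved calibration constants are recorded and plausible", {
  cal <- default_inputs()$costing
  expect_gt(cal$time_rate, 0)
  expect_gt(cal$oop_scale, 0.8)
  expect_lt(cal$oop_scale, 1.2)
  expect_gt(cal$wage_scale, 0.8)
  expect_lt(cal$wage_scale, 1.2)
  w <- cal$shared_scope_weights
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))
})
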