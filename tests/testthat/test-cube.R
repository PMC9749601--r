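cube_cell <- function(amount, activity = "training", input = "supplies",
                      stage = "recurrent", arm = "2", nature = "financial") {
  tibble::tibble(activity = activity, input = input, stage = stage,
                 arm = arm, nature = nature, amount = amount)
}

test_that("cube construction: empty, merging, and rejection of negatives", {
  expect_equal(cube_total(build_cube(NULL)), 0)
  merged <- build_cube(dplyr::bind_rows(cube_cell(10), cube_cell(5)))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$amount, 15)
  expect_error(build_cube(cube_cell(-1)), "nonnegative")
  expect_error(build_cube(cube_cell(1, activity = "not_a_code")), "activity")
})

test_that("every margin of the pipeline cube reproduces the grand total", {
  cube <- default_run()$cube
  grand <- cube_total(cube)
  for (dim in c("activity", "input", "stage", "arm", "nature", "typology")) {
    expect_equal(sum(cube_margin(cube, dim)$amount), grand,
                 tolerance = 1e-9)
  }
  expect_true(all(cube$amount >= 0))
})

test_that("cost profiles are shares of total with whole-percent half-up rounding", {
  single <- build_cube(cube_cell(123.45))
  prof <- cost_profile(single, "activity")
  expect_equal(prof$share[prof$activity == "training"], 1)
  expect_equal(prof$percent[prof$activity == "training"], 100)
  expect_error(cost_profile(build_cube(NULL), "input"), "empty")
  expect_equal(round_half_up(c(4.5, 36.5, 67.5)), c(5, 37, 68))
})

test_that("pooled unit costs reproduce the published series from the grand total", {
  roster <- beneficiary_roster()
  total <- 795040.34
  expect_equal(
    round_half_up(unit_cost(total, roster, "households", "total")$value),
    210
  )
  ann <- vapply(denominator_codes(), function(d) {
    unit_cost(total, roster, d, "annual")$value
  }, numeric(1))
  expect_equal(round_half_up(unname(ann), 2),
               c(63.10, 33.64, 21.47, 13.51))
  # homogeneity: doubling every count halves every unit cost
  ann2 <- vapply(denominator_codes(), function(d) {
    unit_cost(total, beneficiary_roster(scale = 2), d, "annual")$value
  }, numeric(1))
  expect_equal(unname(ann2), unname(ann) / 2, tolerance = 1e-9)
  # annual x window years = total
  uc <- unit_cost_table(total, roster)
  ann_hh <- uc$value[uc$denominator == "households" & uc$period == "annual"]
  tot_hh <- uc$value[uc$denominator == "households" & uc$period == "total"]
  expect_equal(ann_hh * 40 / 12, tot_hh, tolerance = 1e-9)
})

test_that("arm unit-cost conversions between denominators match the published figures", {
  roster <- beneficiary_roster()
  # arm totals implied by the published annual household costs
  arm_annual_hh <- c("2" = 36.62, "3" = 65.18, "4" = 87.50)
  cells <- dplyr::bind_rows(lapply(names(arm_annual_hh), function(a) {
    cube_cell(arm_annual_hh[[a]] * 1260 * 40 / 12, arm = a)
  }))
  ac <- arm_unit_costs(build_cube(cells), roster)
  hh <- ac[ac$denominator == "households", ]
  expect_equal(round_half_up(hh$annual, 2), c(36.62, 65.18, 87.50))
  ip <- ac[ac$denominator == "index_pair", ]
  expect_equal(round_half_up(ip$annual[1:2], 2), c(19.61, 34.25))
  # arm 4 sits at 47.1355, published as 47.13: agree to the cent
  expect_equal(ip$annual[3], 47.13, tolerance = 2e-4)
})

test_that("unit costs are ordered across denominator definitions in every scope", {
  run <- default_run()
  ann <- run$unit_costs[run$unit_costs$period == "annual", ]
  ann <- ann[match(denominator_codes(), ann$denominator), ]
  expect_true(all(diff(ann$value) < 0))
  ac <- run$arm_costs
  for (a in arm_codes()) {
    v <- ac$annual[ac$arm == a][match(denominator_codes(),
                                      ac$denominator[ac$arm == a])]
    expect_true(all(diff(v) < 0))
  }
})

test_that("annual household costs rise strictly with arm complexity", {
  ac <- default_run()$arm_costs
  hh <- ac$annual[ac$denominator == "households"]
  expect_true(all(diff(hh) > 0))
})

test_that("roster invariants hold and degenerate scaling is rejected", {
  r <- beneficiary_roster()
  expect_equal(unname(roster_totals(r)),
               c(3780, 7090, 3 * 3703, 3 * 5884))
  r2 <- beneficiary_roster(scale = 2)
  expect_equal(roster_totals(r2), 2 * roster_totals(r))
  expect_error(beneficiary_roster(scale = 0), ">")
})
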