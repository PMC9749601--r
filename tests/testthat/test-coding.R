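test_that("explicit activity hints pass through and stage follows the start-up rule", {
  led <- minimal_ledger(month_index = 2L, activity_hint = "training")
  coded <- assign_codes(led)
  expect_equal(coded$activity, "training")
  expect_equal(coded$stage, "start_up")
  expect_false(coded$needs_allocation)

  # the same activity after the launch window is recurrent
  coded_late <- assign_codes(minimal_ledger(month_index = 9L,
                                            activity_hint = "training"))
  expect_equal(coded_late$stage, "recurrent")

  # recurring activities inside the launch window stay recurrent
  coded_rec <- assign_codes(minimal_ledger(month_index = 2L,
                                           activity_hint = "community_events"))
  expect_equal(coded_rec$stage, "recurrent")
})

test_that("cadre entries without a hint are flagged for time-share allocation", {
  led <- minimal_ledger(activity_hint = NA_character_, cadre = "PK",
                        input_code = "personnel_hired")
  coded <- assign_codes(led)
  expect_true(coded$needs_allocation)
  expect_true(is.na(coded$activity))
  expect_true(is.na(coded$stage))
})

test_that("rule-table lookups resolve unhinted entries; unresolvable entries are rejected by id", {
  led <- minimal_ledger(activity_hint = NA_character_,
                        input_code = "overhead",
                        description = "head office rent share")
  coded <- assign_codes(led)
  expect_equal(coded$activity, "indirect_overhead")
  expect_equal(coded$stage, "recurrent")

  bad <- minimal_ledger(entry_id = "E9999", activity_hint = NA_character_,
                        input_code = "supplies",
                        description = "zzz unmatchable zzz")
  expect_error(assign_codes(bad), "E9999")
})

test_that("allocate_personnel splits a salary pool by FTE share and activity shares", {
  out <- allocate_personnel(100, pk_profile())
  expect_equal(
    out,
    c(home_visits_nutrition_gender = 80, training = 10,
      planning_microplanning = 5, integration_coordination = 5)
  )
  dm <- list(cadre = "DM", fte_share = 0.30,
             activity_shares = c(site_supervision = 1))
  expect_equal(allocate_personnel(1000, dm), c(site_supervision = 300))
  expect_equal(unname(allocate_personnel(0, pk_profile())), rep(0, 4))

  bad <- pk_profile()
  bad$activity_shares[1] <- 0.7
  expect_error(allocate_personnel(100, bad), "sum to 1")
})

test_that("allocate_shared partitions proportionally and conserves money to the cent", {
  expect_equal(
    allocate_shared(300, c(a = 1 / 3, b = 1 / 3, c = 1 / 3)),
    c(a = 100, b = 100, c = 100)
  )
  expect_equal(
    allocate_shared(100, c(nutrition = .60, agriculture = .25, gender = .15)),
    c(nutrition = 60, agriculture = 25, gender = 15)
  )
  penny <- allocate_shared(0.01, c(a = .5, b = .5))
  expect_equal(sum(penny), 0.01)
  expect_true(all(penny %in% c(0, 0.01)))
  expect_error(allocate_shared(10, numeric(0)), "non-empty")
  expect_error(allocate_shared(10, c(a = .4, b = .4)), "sum to 1")
})

test_that("allocate_shared conserves and is homogeneous across random partitions", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    w <- stats::runif(k)
    w <- stats::setNames(w / sum(w), paste0("k", 1:k))
    amt <- round(stats::runif(1, 0, 1e5), 2)
    parts <- allocate_shared(amt, w)
    expect_equal(sum(parts), round(amt, 2), tolerance = 1e-9)
    expect_true(all(parts >= 0))
    # homogeneity up to cent rounding
    parts3 <- allocate_shared(3 * amt, w)
    expect_lt(max(abs(parts3 - 3 * parts)), 0.031)
  }
})

test_that("arm allocation follows component eligibility proportional to households", {
  roster <- beneficiary_roster()
  expect_equal(
    allocate_to_arms(300, "nutrition", roster),
    c("2" = 100, "3" = 100, "4" = 100)
  )
  expect_equal(allocate_to_arms(200, "agriculture", roster),
               c("3" = 100, "4" = 100))
  expect_equal(allocate_to_arms(50, "gender", roster), c("4" = 50))
  expect_equal(sum(allocate_to_arms(123.45, "platform_wide", roster)),
               123.45)
  expect_error(allocate_to_arms(10, "unknown_scope", roster), "scope")
})

test_that("typology mapping: direct components map fully, shared activities take the config weights", {
  expect_equal(
    map_typology("home_visits_agriculture"),
    c(supply = 1, demand = 0, enabling_environment = 0)
  )
  expect_equal(
    map_typology("home_visits_nutrition_gender"),
    c(supply = 0, demand = 0.8, enabling_environment = 0.2)
  )
  shared <- c(supply = .5, demand = .3, enabling_environment = .2)
  expect_equal(map_typology("management", shared), shared)
  for (a in activity_codes()) {
    expect_equal(sum(map_typology(a)), 1)
  }
})
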