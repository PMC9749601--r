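test_that("currency and inflation conversion to 2019 USD", {
  p <- valuation_params()
  expect_equal(to_usd_2019(84770, "BDT", 2019, p), 1000)
  expect_equal(to_usd_2019(100, "USD", 2019, p), 100)

  p95 <- valuation_params(
    inflation_index = c("2017" = 0.95, "2019" = 1)
  )
  expect_equal(to_usd_2019(84770, "BDT", 2017, p95), 1000 / 0.95,
               tolerance = 1e-9)
  expect_error(to_usd_2019(10, "BDT", 1999, p), "inflation index")
  expect_error(to_usd_2019(10, "EUR", 2019, p), "currency")
})

test_that("annuity factor matches the brute-force discounted-sum oracle", {
  for (r in c(0.01, 0.03, 0.05, 0.10)) {
    for (n in c(1, 5, 10, 25)) {
      oracle <- sum((1 + r)^-(1:n))
      expect_equal(annuity_factor(r, n), oracle, tolerance = 1e-9)
    }
  }
  # the constant payment recovering a 1000 price at 3% over 10 years
  p <- valuation_params()
  a <- annualize_capital(1000, p)
  expect_equal(sum(a / 1.03^(1:10)), 1000, tolerance = 1e-9)
  expect_equal(round(a, 2), 117.23)
})

test_that("annuitization limits and monotonicity", {
  # straight-line limit at r -> 0
  p0 <- valuation_params(discount_rate = 0)
  expect_equal(annualize_capital(500, p0), 50)
  # a one-year annuity horizon charges price x (1 + r)
  expect_equal(1000 / annuity_factor(0.03, 1), 1030)
  # increasing in r, decreasing in n
  rs <- c(0.01, 0.03, 0.06, 0.12)
  av <- vapply(rs, function(r) {
    annualize_capital(1000, valuation_params(discount_rate = r))
  }, numeric(1))
  expect_true(all(diff(av) > 0))
  ns <- c(2, 5, 10, 20)
  an <- vapply(ns, function(n) {
    annualize_capital(1000, valuation_params(useful_life_years = n))
  }, numeric(1))
  expect_true(all(diff(an) < 0))
})

test_that("sub-threshold durables signal an expense instead of annuitizing", {
  p <- valuation_params()
  expect_error(annualize_capital(90, p), class = "nutricost_expense")
  expect_equal(capital_charge(90, p), 90)
  # above threshold: annual value times the window in years
  expect_equal(capital_charge(1000, p),
               annualize_capital(1000, p) * 40 / 12)
})

test_that("tax rule: financial keeps all, economic excludes durable tax only", {
  expect_equal(apply_tax_rule(110, 10, durable = TRUE, "economic"), 100)
  expect_equal(apply_tax_rule(110, 10, durable = FALSE, "economic"), 110)
  expect_equal(apply_tax_rule(110, 10, durable = TRUE, "financial"), 110)
})

test_that("worker out-of-pocket valuation matches a month-by-month oracle", {
  prof <- worker_economic_profile(n_workers = 1)
  # oracle: walk the 40 months, applying each stipend period's mean
  oracle <- sum(vapply(0:39, function(m) {
    if (m <= 16) 6.55 else if (m <= 32) 4.31 else 1.45
  }, numeric(1)))
  v <- value_worker_economic(prof, months = 40)
  expect_equal(v$oop_usd, oracle, tolerance = 1e-9)
  expect_equal(v$oop_usd, 190.46, tolerance = 1e-9)
  # the marginal 40th month falls in the third stipend period
  expect_equal(v$oop_usd - value_worker_economic(prof, 39)$oop_usd, 1.45)
})

test_that("worker time valuation is linear and vanishes at rate zero", {
  prof <- worker_economic_profile(n_workers = 1,
                                  time_rate_usd_per_hour = 0.25)
  v <- value_worker_economic(prof, 40)
  expect_equal(v$overtime_usd, (4.24 + 19.65) * 40 * 0.25)
  prof0 <- worker_economic_profile(time_rate_usd_per_hour = 0)
  expect_equal(value_worker_economic(prof0, 40)$overtime_usd, 0)
  prof5 <- worker_economic_profile(n_workers = 5,
                                   time_rate_usd_per_hour = 0.25)
  expect_equal(value_worker_economic(prof5, 40)$overtime_usd,
               5 * v$overtime_usd)
  expect_equal(value_worker_economic(prof, 20)$overtime_usd,
               v$overtime_usd / 2)
})

test_that("beneficiary time valuation follows the wage-chain arithmetic", {
  p <- valuation_params()
  prof <- beneficiary_time_profile(daily_wage_bdt = c(men = 200,
                                                      women = 200))
  counts <- tibble::tibble(arm = "2", n_women = 1, n_men = 0)
  v <- value_beneficiary_time(prof, counts, months = 40, params = p)
  # 1.8 h/month x 40 = 72 h at 200/8 = 25 BDT/h -> 1800 BDT -> USD
  expect_equal(v$value, 1800 / 84.77, tolerance = 1e-9)
  expect_equal(round(v$value, 2), 21.23)
  # zero participation -> zero cost
  prof0 <- beneficiary_time_profile(hours_women = c(0, 0.1),
                                    hours_men = c(0, 0.1))
  expect_equal(value_beneficiary_time(prof0, counts, 40, p)$value, 0)
  # doubling the wage doubles the valuation
  prof2 <- beneficiary_time_profile(daily_wage_bdt = c(men = 400,
                                                       women = 400))
  expect_equal(value_beneficiary_time(prof2, counts, 40, p)$value,
               2 * v$value)
})
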