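test_that("method-of-moments gamma specs reproduce the requested moments", {
  men <- gamma_from_moments(0.96, 1.22)
  expect_equal(men$shape * men$scale, 0.96, tolerance = 1e-12)
  expect_equal(men$shape * men$scale^2, 1.22^2, tolerance = 1e-12)
  expect_equal(men$shape, 0.6192, tolerance = 1e-4)
  expect_equal(men$scale, 1.5504, tolerance = 1e-4)

  women <- gamma_from_moments(1.8, 1.66)
  expect_equal(women$shape, 1.1758, tolerance = 1e-4)
  expect_equal(women$scale, 1.5309, tolerance = 1e-4)
  expect_equal(women$shape * women$scale, 1.8, tolerance = 1e-12)

  exp1 <- gamma_from_moments(1, 1)
  expect_equal(exp1$shape, 1)
  expect_equal(exp1$scale, 1)
  expect_error(gamma_from_moments(0, 1), ">")
  expect_error(gamma_from_moments(1, -1), ">")
})

test_that("gamma sampling matches the specified distribution (KS at alpha = 0.01)", {
  set.seed(7)
  spec <- gamma_from_moments(4.24, 2.34)
  x <- sample_gamma(spec, 1e5)
  ks <- suppressWarnings(
    stats::ks.test(x, stats::pgamma, shape = spec$shape, scale = spec$scale)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("large samples recover every survey parameter's moments within 3 SE", {
  set.seed(11)
  m <- psa_moments()
  n <- 1e5
  for (i in seq_len(nrow(m))) {
    x <- sample_gamma(gamma_from_moments(m$mean[i], m$sd[i]), n)
    se_mean <- m$sd[i] / sqrt(n)
    expect_lt(abs(mean(x) - m$mean[i]), 3 * se_mean)
    # SD consistency at a looser, distribution-free band
    expect_lt(abs(stats::sd(x) - m$sd[i]) / m$sd[i], 0.05)
  }
})

test_that("the PSA is deterministic under a fixed seed and degenerates at one draw", {
  model <- default_model()
  a <- run_psa(model, n_sims = 200, seed = 99)
  b <- run_psa(model, n_sims = 200, seed = 99)
  expect_identical(a$summary, b$summary)
  c <- run_psa(model, n_sims = 200, seed = 100)
  expect_false(isTRUE(all.equal(a$summary$sim_mean, c$summary$sim_mean)))

  one <- run_psa(model, n_sims = 1, seed = 5)
  expect_equal(one$summary$lower, one$summary$sim_mean)
  expect_equal(one$summary$upper, one$summary$sim_mean)
})

test_that("PSA summaries are ordered and bounded below by the financial-only total", {
  model <- default_model()
  res <- run_psa(model, n_sims = 500, seed = 3, keep_draws = TRUE)
  s <- res$summary
  expect_true(all(s$lower <= s$sim_mean + 1e-9))
  expect_true(all(s$sim_mean <= s$upper + 1e-9))
  fin <- default_run()$totals[["financial"]]
  inc <- res$outcomes[, "total_incremental"]
  expect_true(all(inc >= fin))
  # empirical mean within 3 SE of the analytic gamma mean (CLT check on the
  # economic outcome, which is linear in the draws)
  base_mean <- mean(res$outcomes[, "total_economic"])
  se <- stats::sd(res$outcomes[, "total_economic"]) / sqrt(res$n_sims)
  expect_lt(abs(base_mean - s$base_case[s$outcome == "total_economic"]),
            4 * se)
})

test_that("tornado ranks parameters by swing; degenerate spread ranks last", {
  model <- default_model()
  params <- default_psa_parameters()
  params$pk_oop_period2 <- gamma_from_moments(4.31, 1e-6)
  tor <- tornado(model, params)
  expect_setequal(tor$parameter, names(params))
  expect_true(all(diff(tor$swing) <= 1e-12))
  expect_equal(tor$parameter[nrow(tor)], "pk_oop_period2")
  expect_lt(tor$swing[nrow(tor)], 1)

  # widening a parameter's spread (fixed mean) weakly increases its swing
  base <- tornado(model, default_psa_parameters())
  wide <- default_psa_parameters()
  wide$pk_travel_hours <- gamma_from_moments(19.65, 2 * 10.28)
  tor_wide <- tornado(model, wide)
  expect_gte(
    tor_wide$swing[tor_wide$parameter == "pk_travel_hours"],
    base$swing[base$parameter == "pk_travel_hours"]
  )
})

test_that("beneficiary-time parameters dominate worker OOP in the tornado ranking", {
  tor <- tornado(default_model())
  rank_of <- function(p) which(tor$parameter == p)
  benef <- vapply(c("beneficiary_hours_men", "beneficiary_hours_women"),
                  rank_of, numeric(1))
  oop <- vapply(paste0("pk_oop_period", 1:3), rank_of, numeric(1))
  expect_true(max(benef) < min(oop))
})
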