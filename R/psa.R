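#' Gamma distribution from sample moments
#'
#' Method-of-moments parameterization used for all uncertain costing
#' parameters (hours worked and out-of-pocket costs are nonnegative, so a
#' gamma is the natural choice): `shape = (mean/sd)^2`,
#' `scale = sd^2 / mean`, which reproduces the requested mean and variance
#' exactly.
#'
#' @param mean Positive mean.
#' @param sd Positive standard deviation.
#' @return A list of class `gamma_spec` with `mean`, `sd`, `shape`, `scale`.
#' @export
#' @examples
#' gamma_from_moments(1.8, 1.66)
gamma_from_moments <- function(mean, sd) {
  assert_scalar_number(mean, "mean", min = 0, strict = TRUE)
  assert_scalar_number(sd, "sd", min = 0, strict = TRUE)
  structure(
    list(mean = mean, sd = sd, shape = (mean / sd)^2, scale = sd^2 / mean),
    class = "gamma_spec"
  )
}

#' Draw from a gamma spec
#'
#' @param spec A [gamma_from_moments()] spec.
#' @param n Number of draws.
#' @return Numeric vector of `n` gamma draws.
#' @export
sample_gamma <- function(spec, n) {
  stats::rgamma(n, shape = spec$shape, scale = spec$scale)
}

#' Default sensitivity-analysis parameter set
#'
#' Gamma specs for the seven survey parameters in [psa_moments()].
#'
#' @return Named list of `gamma_spec` objects.
#' @export
default_psa_parameters <- function() {
  m <- psa_moments()
  stats::setNames(
    lapply(seq_len(nrow(m)), function(i) gamma_from_moments(m$mean[i],
                                                            m$sd[i])),
    m$parameter
  )
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_sims` independent joint parameter vectors from the gamma specs,
#' pushes each through the deterministic cost model, and summarizes every
#' outcome by its base case (model at the parameter means), simulation mean,
#' and 2.5th/97.5th percentile limits. Identical seeds give identical
#' results.
#'
#' @param model A function mapping a named parameter vector to a named
#'   numeric outcome vector, e.g. from [build_cost_model()].
#' @param n_sims Number of simulations (default 5000).
#' @param seed Integer RNG seed.
#' @param parameters Named list of `gamma_spec`s
#'   (default [default_psa_parameters()]).
#' @param keep_draws Retain the raw parameter and outcome draws.
#' @return A list of class `psa_result` with `summary` (tibble `outcome`,
#'   `base_case`, `sim_mean`, `lower`, `upper`), `n_sims`, `seed`, and
#'   optionally `draws`/`outcomes`.
#' @export
run_psa <- function(model, n_sims = 5000, seed = 1L,
                    parameters = default_psa_parameters(),
                    keep_draws = FALSE) {
  stopifnot(n_sims >= 1)
  set.seed(seed)
  draws <- vapply(parameters, function(sp) sample_gamma(sp, n_sims),
                  numeric(n_sims))
  if (n_sims == 1) draws <- matrix(draws, nrow = 1,
                                   dimnames = list(NULL, names(parameters)))
  base_theta <- vapply(parameters, function(sp) sp$mean, numeric(1))
  base <- model(base_theta)
  outcomes <- matrix(NA_real_, n_sims, length(base),
                     dimnames = list(NULL, names(base)))
  for (i in seq_len(n_sims)) {
    out <- tryCatch(model(draws[i, ]), error = function(e) {
      rlang::abort(sprintf(
        "Cost model failed on draw %d (parameters: %s): %s",
        i, paste(sprintf("%s=%.4g", colnames(draws), draws[i, ]),
                 collapse = ", "),
        conditionMessage(e)
      ))
    })
    outcomes[i, ] <- out
  }
  summary <- tibble::tibble(
    outcome = names(base),
    base_case = unname(base),
    sim_mean = colMeans(outcomes),
    lower = apply(outcomes, 2, stats::quantile, probs = 0.025, names = FALSE),
    upper = apply(outcomes, 2, stats::quantile, probs = 0.975, names = FALSE)
  )
  res <- list(summary = summary, n_sims = n_sims, seed = seed)
  if (keep_draws) {
    res$draws <- draws
    res$outcomes <- outcomes
  }
  structure(res, class = "psa_result")
}

#' One-at-a-time tornado analysis
#'
#' Each parameter is set in turn to a low and a high percentile of its gamma
#' distribution (default 10th/90th, the common spreadsheet-PSA convention)
#' with all others held at their base means; parameters are ranked by the
#' absolute swing they induce in the chosen outcome.
#'
#' @inheritParams run_psa
#' @param probs Length-2 vector of low/high distribution percentiles.
#' @param outcome Name of the model outcome to rank on (default total
#'   incremental cost).
#' @return A tibble of class `tornado_result` with columns `parameter`,
#'   `low`, `high`, `outcome_low`, `outcome_high`, `swing`, sorted by
#'   descending swing.
#' @export
tornado <- function(model, parameters = default_psa_parameters(),
                    probs = c(0.10, 0.90), outcome = "total_incremental") {
  stopifnot(length(probs) == 2, probs[1] < probs[2])
  base_theta <- vapply(parameters, function(sp) sp$mean, numeric(1))
  rows <- lapply(names(parameters), function(p) {
    sp <- parameters[[p]]
    q <- stats::qgamma(probs, shape = sp$shape, scale = sp$scale)
    lo_theta <- hi_theta <- base_theta
    lo_theta[p] <- q[1]
    hi_theta[p] <- q[2]
    lo <- model(lo_theta)[[outcome]]
    hi <- model(hi_theta)[[outcome]]
    tibble::tibble(
      parameter = p, low = q[1], high = q[2],
      outcome_low = lo, outcome_high = hi, swing = abs(hi - lo)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$swing))
  class(out) <- c("tornado_result", class(out))
  out
}

#' Deterministic cost model for sensitivity analysis
#'
#' Builds the closure the PSA propagates parameters through. Financial costs
#' are fixed at the valued ledger total; economic costs are recomputed from
#' the seven parameters: worker unpaid time `n_pk x months x (overtime +
#' travel) x hourly rate`, worker OOP `n_pk x sum(period months x period
#' mean)`, and beneficiary time `months x (women x hours_women x wage_w +
#' men x hours_men x wage_m)`. The calibration scale factors recorded in the
#' run configuration are applied so the base case matches the pipeline.
#'
#' @param financial_total Valued financial cost (2019 USD).
#' @param costing A run configuration, see [costing_config()].
#' @param roster A [beneficiary_roster()].
#' @return A function from a named parameter vector to named outcomes
#'   `total_economic`, `total_incremental`, and annual unit costs for the
#'   four beneficiary denominators.
#' @export
build_cost_model <- function(financial_total, costing, roster) {
  params <- costing$params
  months <- costing$months
  n_pk <- costing$n_pk
  pm <- oop_months_in_window(months)
  gc <- roster_gender_counts(roster)
  n_women <- sum(gc$n_women)
  n_men <- sum(gc$n_men)
  wage_hr <- costing$wages_bdt / params$hours_per_workday /
    params$exchange_rate_bdt_per_usd
  totals <- roster_totals(roster)
  years <- months / 12

  function(theta) {
    worker_time <- n_pk * months *
      (theta[["pk_overtime_hours"]] + theta[["pk_travel_hours"]]) *
      costing$time_rate
    worker_oop <- n_pk * (
      pm[["period1"]] * theta[["pk_oop_period1"]] +
      pm[["period2"]] * theta[["pk_oop_period2"]] +
      pm[["period3"]] * theta[["pk_oop_period3"]]
    ) * costing$oop_scale
    benef <- months * (
      n_women * theta[["beneficiary_hours_women"]] * wage_hr[["women"]] +
      n_men * theta[["beneficiary_hours_men"]] * wage_hr[["men"]]
    ) * costing$wage_scale
    economic <- worker_time + worker_oop + benef
    total <- financial_total + economic
    c(
      total_economic = economic,
      total_incremental = total,
      annual_cost_per_household = total / totals[["households"]] / years,
      annual_cost_per_index_pair = total / totals[["index_pair"]] / years,
      annual_cost_per_index_plus_children =
        total / totals[["index_plus_children"]] / years,
      annual_cost_per_member = total / totals[["all_members"]] / years
    )
  }
}
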