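#' Valuation parameters
#'
#' Assembles the constants used to convert nominal ledger amounts and survey
#' quantities into 2019 USD: the BDT/USD exchange rate, the discount rate and
#' expected useful life for capital annuitization, the capital-expense
#' threshold, an annual inflation index relative to 2019, the 40-month
#' implementation window, and the conventions for converting daily and
#' monthly pay to hourly rates.
#'
#' @param exchange_rate_bdt_per_usd BDT per USD (default 84.77).
#' @param discount_rate Annual discount rate for annuitization (default 3%).
#' @param useful_life_years Expected useful life of capital goods (default 10).
#' @param capital_threshold_usd Durables valued above this (and lasting over a
#'   year) are annuitized; at or below it they are expensed (default 100).
#' @param inflation_index Named numeric, calendar year -> price level relative
#'   to 2019 (2019 must equal 1). Defaults to an identity series over
#'   2016-2020.
#' @param annualization_months Implementation window in months (default 40).
#' @param hours_per_workday Hours assumed when converting daily agricultural
#'   wages to hourly rates (default 8).
#' @param contracted_week_hours Contracted weekly hours for salaried frontline
#'   workers, used to derive an hourly rate from a monthly salary (default 36).
#' @return A list of class `valuation_params`.
#' @export
valuation_params <- function(exchange_rate_bdt_per_usd = 84.77,
                             discount_rate = 0.03,
                             useful_life_years = 10,
                             capital_threshold_usd = 100,
                             inflation_index = NULL,
                             annualization_months = 40,
                             hours_per_workday = 8,
                             contracted_week_hours = 36) {
  if (is.null(inflation_index)) {
    inflation_index <- stats::setNames(rep(1, 5), as.character(2016:2020))
  }
  assert_scalar_number(exchange_rate_bdt_per_usd, "exchange_rate_bdt_per_usd",
                       min = 0, strict = TRUE)
  assert_scalar_number(discount_rate, "discount_rate", min = 0)
  assert_scalar_number(useful_life_years, "useful_life_years",
                       min = 0, strict = TRUE)
  assert_scalar_number(annualization_months, "annualization_months",
                       min = 0, strict = TRUE)
  assert_scalar_number(hours_per_workday, "hours_per_workday",
                       min = 0, strict = TRUE)
  if (is.null(names(inflation_index)) ||
      !"2019" %in% names(inflation_index) ||
      abs(inflation_index[["2019"]] - 1) > 1e-12) {
    rlang::abort("`inflation_index` must be named by year with index 2019 = 1.")
  }
  if (any(inflation_index <= 0)) {
    rlang::abort("`inflation_index` values must be positive.")
  }
  structure(
    list(
      exchange_rate_bdt_per_usd = exchange_rate_bdt_per_usd,
      discount_rate = discount_rate,
      useful_life_years = useful_life_years,
      capital_threshold_usd = capital_threshold_usd,
      inflation_index = inflation_index,
      annualization_months = annualization_months,
      hours_per_workday = hours_per_workday,
      contracted_week_hours = contracted_week_hours
    ),
    class = "valuation_params"
  )
}

#' Calendar year of a programme month
#'
#' Month 0 is October 2016; month 39 is January 2020.
#'
#' @param month_index Integer vector of months since programme start.
#' @return Integer vector of calendar years.
#' @export
month_to_calendar_year <- function(month_index) {
  2016L + (as.integer(month_index) + 9L) %/% 12L
}

#' Convert a nominal amount to 2019 USD
#'
#' BDT amounts are divided by the exchange rate; USD amounts pass through.
#' The result is then deflated/inflated to 2019 price levels by dividing by
#' the inflation index of the expenditure year.
#'
#' @param amount Numeric vector of nominal amounts.
#' @param currency Character vector, `"BDT"` or `"USD"` (recycled).
#' @param calendar_year Integer vector of expenditure years.
#' @param params [valuation_params()].
#' @return Numeric vector in 2019 USD.
#' @export
#' @examples
#' to_usd_2019(84770, "BDT", 2019, valuation_params())
to_usd_2019 <- function(amount, currency, calendar_year, params) {
  bad_cur <- setdiff(unique(currency), c("BDT", "USD"))
  if (length(bad_cur)) {
    rlang::abort(paste0("Unsupported currency: ",
                        paste(bad_cur, collapse = ", ")))
  }
  yr <- as.character(calendar_year)
  idx <- params$inflation_index[yr]
  if (any(is.na(idx))) {
    rlang::abort(paste0(
      "Years missing from the inflation index: ",
      paste(unique(yr[is.na(idx)]), collapse = ", ")
    ))
  }
  usd <- ifelse(currency == "BDT",
                amount / params$exchange_rate_bdt_per_usd, amount)
  unname(usd / idx)
}

#' Annuity factor
#'
#' Present value of a 1-per-year annuity over `n` years at discount rate `r`:
#' `(1 - (1 + r)^-n) / r`, with the straight-line limit `n` at `r = 0`.
#'
#' @param rate Annual discount rate.
#' @param n_years Number of years.
#' @return The annuity factor.
#' @export
annuity_factor <- function(rate, n_years) {
  assert_scalar_number(rate, "rate", min = 0)
  assert_scalar_number(n_years, "n_years", min = 0, strict = TRUE)
  if (rate == 0) n_years else (1 - (1 + rate)^(-n_years)) / rate
}

#' Annuitize a capital purchase
#'
#' Returns the equivalent annual cost `price / AF(r, n)` of a durable good.
#' Durables valued at or below the capital threshold (or lasting a year or
#' less) are *not* capital: the function signals a classed condition
#' (`nutricost_expense`) telling the caller to expense the item at face
#' value instead.
#'
#' @param price Purchase price in 2019 USD.
#' @param params [valuation_params()].
#' @param expected_life_years The item's expected life, used only for the
#'   over-one-year eligibility test; annuitization always uses the standard
#'   `useful_life_years` from `params`.
#' @return Annual cost in 2019 USD.
#' @export
#' @examples
#' annualize_capital(1000, valuation_params())
annualize_capital <- function(price, params,
                              expected_life_years = params$useful_life_years) {
  assert_scalar_number(price, "price", min = 0)
  if (price <= params$capital_threshold_usd || expected_life_years <= 1) {
    stop(errorCondition(
      sprintf(
        "Item priced %.2f USD (life %.1f y) is an expense, do not annuitize.",
        price, expected_life_years
      ),
      class = c("nutricost_expense", "error", "condition")
    ))
  }
  price / annuity_factor(params$discount_rate, params$useful_life_years)
}

#' Charge of a purchase to the implementation period
#'
#' Annuitizable capital contributes `annual value x (months / 12)`; anything
#' below the capital threshold is expensed at face value.
#'
#' @inheritParams annualize_capital
#' @param months Implementation months charged (defaults to the window in
#'   `params`).
#' @return Money in 2019 USD.
#' @export
capital_charge <- function(price, params,
                           expected_life_years = params$useful_life_years,
                           months = params$annualization_months) {
  tryCatch(
    annualize_capital(price, params, expected_life_years) * months / 12,
    nutricost_expense = function(e) price
  )
}

#' Tax treatment of a valued entry
#'
#' Financial costs always keep the full amount (taxes are real expenditure).
#' Economic valuation excludes taxes on durable goods, but keeps
#' value-added tax embedded in small supplies.
#'
#' @param amount Valued amount including tax.
#' @param tax_amount Tax component of `amount`.
#' @param durable Logical, is the item a durable good?
#' @param nature `"financial"` or `"economic"`.
#' @return Money after the tax rule.
#' @export
apply_tax_rule <- function(amount, tax_amount, durable, nature) {
  nature <- match.arg(nature, c("financial", "economic"))
  if (nature == "financial") return(amount)
  ifelse(durable, amount - tax_amount, amount)
}

#' Hourly rate implied by a monthly salary
#'
#' Monthly salary divided by contracted monthly hours
#' (`weekly_hours * 52 / 12`); used to price unpaid overtime of salaried
#' frontline workers.
#'
#' @param monthly_salary Money per month.
#' @param weekly_hours Contracted weekly hours (default 36).
#' @return Money per hour.
#' @export
hourly_rate_from_salary <- function(monthly_salary, weekly_hours = 36) {
  monthly_salary / (weekly_hours * 52 / 12)
}

#' Months of the window falling in each out-of-pocket stipend period
#'
#' The OOP survey distinguishes three periods: months 0-16 (no travel
#' stipend), 17-32 (200 BDT stipend) and 33-39 (500 BDT stipend). Given an
#' analysis window of the first `months` months, returns how many fall in
#' each period.
#'
#' @param months Window length in months (<= 40).
#' @return Named integer vector `c(period1=, period2=, period3=)`.
#' @export
oop_months_in_window <- function(months) {
  c(
    period1 = min(months, 17),
    period2 = min(max(months - 17, 0), 16),
    period3 = min(max(months - 33, 0), 7)
  )
}

#' Frontline-worker economic-cost profile
#'
#' Survey-derived moments for one worker cadre: unpaid overtime and travel
#' hours per month, out-of-pocket spending per month by stipend period (all
#' USD, net of stipends), and the hourly rate used to value unpaid time.
#'
#' @param n_workers Number of workers in the cadre.
#' @param overtime_hours `c(mean, sd)` unpaid work hours/month beyond the
#'   contracted week.
#' @param travel_hours `c(mean, sd)` unreimbursed travel hours/month.
#' @param oop_usd List of `c(mean, sd)` per month for `period1..period3`.
#' @param time_rate_usd_per_hour Hourly valuation rate for unpaid time
#'   (travel hours are valued at the same rate as work hours).
#' @param cadre Cadre label.
#' @return A list of class `worker_profile`.
#' @export
worker_economic_profile <- function(n_workers = 1,
                                    overtime_hours = c(4.24, 2.34),
                                    travel_hours = c(19.65, 10.28),
                                    oop_usd = list(
                                      period1 = c(6.55, 3.02),
                                      period2 = c(4.31, 2.78),
                                      period3 = c(1.45, 2.00)
                                    ),
                                    time_rate_usd_per_hour = 0.25,
                                    cadre = "PK") {
  stopifnot(
    n_workers >= 0, all(overtime_hours >= 0), all(travel_hours >= 0),
    all(unlist(oop_usd) >= 0), time_rate_usd_per_hour >= 0
  )
  structure(
    list(
      cadre = cadre, n_workers = n_workers,
      overtime_hours = overtime_hours, travel_hours = travel_hours,
      oop_usd = oop_usd, time_rate_usd_per_hour = time_rate_usd_per_hour
    ),
    class = "worker_profile"
  )
}

#' Expected economic cost of a worker cadre over an analysis window
#'
#' Overtime value: `n_workers x (overtime + travel hours)/month x months x
#' hourly rate`. OOP: `n_workers x` the sum over stipend periods of (months
#' in window) x (period mean). Both are linear in workers and months.
#'
#' @param profile A [worker_economic_profile()].
#' @param months Window length (<= 40).
#' @return A list with `overtime_usd` and `oop_usd`.
#' @export
value_worker_economic <- function(profile, months = 40) {
  stopifnot(months >= 0, months <= 40)
  hours <- profile$overtime_hours[1] + profile$travel_hours[1]
  overtime_usd <- profile$n_workers * hours * months *
    profile$time_rate_usd_per_hour
  pm <- oop_months_in_window(months)
  means <- vapply(profile$oop_usd, `[`, numeric(1), 1)
  oop_usd <- profile$n_workers * sum(pm * means[names(pm)])
  list(overtime_usd = unname(overtime_usd), oop_usd = unname(oop_usd))
}

#' Beneficiary time-use profile
#'
#' Participation hours per month by gender and the daily agricultural wage
#' rates (BDT) used to value that time. The default wages are synthetic
#' placeholders, not survey values.
#'
#' @param hours_men,hours_women `c(mean, sd)` participation hours per month.
#' @param daily_wage_bdt Named `c(men=, women=)` daily wages in BDT.
#' @return A list of class `beneficiary_profile`.
#' @export
beneficiary_time_profile <- function(hours_men = c(0.96, 1.22),
                                     hours_women = c(1.8, 1.66),
                                     daily_wage_bdt = c(men = 300,
                                                        women = 250)) {
  stopifnot(all(hours_men >= 0), all(hours_women >= 0),
            all(daily_wage_bdt > 0))
  structure(
    list(hours_men = hours_men, hours_women = hours_women,
         daily_wage_bdt = daily_wage_bdt),
    class = "beneficiary_profile"
  )
}

#' Opportunity cost of beneficiary participation time, by arm
#'
#' Per person: expected hours/month x months x hourly wage (daily wage /
#' hours per workday, converted to USD). Summed over the index women and men
#' in each arm.
#'
#' @param profile A [beneficiary_time_profile()].
#' @param counts Tibble with columns `arm`, `n_women`, `n_men`.
#' @param months Window length in months.
#' @param params [valuation_params()].
#' @return Tibble with columns `arm`, `value` (2019 USD).
#' @export
value_beneficiary_time <- function(profile, counts, months = 40,
                                   params = valuation_params()) {
  stopifnot(all(counts$n_women >= 0), all(counts$n_men >= 0), months >= 0)
  hr <- profile$daily_wage_bdt / params$hours_per_workday /
    params$exchange_rate_bdt_per_usd
  tibble::tibble(
    arm = counts$arm,
    value = months * (
      counts$n_women * profile$hours_women[1] * hr[["women"]] +
      counts$n_men * profile$hours_men[1] * hr[["men"]]
    )
  )
}
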