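#' Reference budget margins of the costed programme
#'
#' The published 40-month incremental budget of the TRAIN agriculture-nutrition
#' programme (Bangladesh, 2016-2020) in 2019 USD, disaggregated by activity,
#' input, and stage, each split into financial (implementer expenditure) and
#' economic (opportunity-cost) components. These margins are the calibration
#' surface for the synthetic-data generator and the default targets its
#' ledgers reproduce.
#'
#' The three printed margin totals differ from one another by one cent
#' (column sums 598,578.90 financial / 196,461.44 economic against printed
#' totals 598,578.91 / 196,461.43); the cells are stored verbatim and all
#' conservation checks carry a one-cent tolerance.
#'
#' @return A list of three tibbles (`activity`, `input`, `stage`), each with a
#'   category column plus `financial` and `economic` amounts in 2019 USD.
#' @export
#' @examples
#' m <- reference_margins()
#' sum(m$activity$financial) + sum(m$activity$economic)
reference_margins <- function() {
  list(
    activity = tibble::tibble(
      activity = activity_codes(),
      financial = c(
        32678.56, 1171.23, 1089.92, 74981.41, 10833.70, 4493.32, 72568.92,
        6724.76, 5050.17, 93101.67, 161760.07, 60323.57, 30139.95, 11076.85,
        32584.80
      ),
      economic = c(
        757.08, 0, 0, 17293.66, 0, 0, 2649.77, 0, 0, 0, 128936.16, 33049.53,
        13447.68, 327.56, 0
      )
    ),
    input = tibble::tibble(
      input = input_codes(),
      financial = c(
        362654.50, 0, 56250.25, 0, 2196.27, 5.81, 49150.36, 19.69, 81937.52,
        46364.50
      ),
      economic = c(19014.29, 162335.76, 0, 0, 0, 0, 0, 0, 15111.39, 0)
    ),
    stage = tibble::tibble(
      stage = stage_codes(),
      financial = c(37950.02, 560628.89),
      economic = c(0, 196461.43)
    )
  )
}

#' Survey moments for the sensitivity-analysis parameters
#'
#' Means and standard deviations of the seven micro-costing survey quantities
#' that drive economic costs: frontline-worker (PK) unpaid overtime and travel
#' hours per month, PK out-of-pocket (OOP) spending per month in three stipend
#' periods (months 0-16, 17-32, 33-39 since programme start), and beneficiary
#' participation hours per month for men and women. All are modelled as gamma
#' distributed (nonnegative hours and costs).
#'
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @seealso [gamma_from_moments()], [default_psa_parameters()]
#' @export
psa_moments <- function() {
  tibble::tibble(
    parameter = c(
      "pk_overtime_hours", "pk_travel_hours",
      "pk_oop_period1", "pk_oop_period2", "pk_oop_period3",
      "beneficiary_hours_men", "beneficiary_hours_women"
    ),
    mean = c(4.24, 19.65, 6.55, 4.31, 1.45, 0.96, 1.8),
    sd = c(2.34, 10.28, 3.02, 2.78, 2.00, 1.22, 1.66)
  )
}
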