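#' Run configuration for the costing pipeline
#'
#' Bundles everything [run_costing()] needs beyond the data: valuation
#' parameters, the coding ruleset, cadre time-allocation profiles, the three
#' economic-cost calibration constants, the allocation shares for economic
#' costs and shared component scopes, and the analysis window.
#'
#' @param params [valuation_params()].
#' @param rules Coding ruleset, see [default_coding_rules()].
#' @param profiles Named list of cadre time-allocation profiles.
#' @param time_rate Hourly rate (2019 USD) valuing unpaid worker time;
#'   travel hours are valued at the same rate.
#' @param oop_scale,wage_scale Calibration scale factors applied to surveyed
#'   out-of-pocket amounts and beneficiary wage valuations (1 = none).
#' @param economic_activity_shares Named shares allocating economic costs
#'   across activities (must sum to 1).
#' @param shared_scope_weights Named `(nutrition, agriculture, gender)`
#'   weights splitting shared activities across programme components for the
#'   arm allocation rule.
#' @param nutrition_gender_split Sub-split of the combined nutrition/gender
#'   home-visit activity.
#' @param typology_shared_weights Typology weights for shared activities.
#' @param wages_bdt Daily agricultural wages `c(men=, women=)` in BDT.
#' @param months Implementation window in months.
#' @param n_pk Frontline workforce size (used by the sensitivity-analysis
#'   model).
#' @param seed Seed recorded for provenance.
#' @return A list of class `costing_config`.
#' @export
costing_config <- function(params = valuation_params(),
                           rules = default_coding_rules(),
                           profiles = list(PK = default_pk_profile(),
                                           DM = default_dm_profile()),
                           time_rate = 0.25,
                           oop_scale = 1,
                           wage_scale = 1,
                           economic_activity_shares = NULL,
                           shared_scope_weights = c(nutrition = 0.6,
                                                    agriculture = 0.3,
                                                    gender = 0.1),
                           nutrition_gender_split = c(nutrition = 0.8,
                                                      gender = 0.2),
                           typology_shared_weights =
                             default_shared_typology_weights(),
                           wages_bdt = c(men = 300, women = 250),
                           months = 40,
                           n_pk = 80,
                           seed = NULL) {
  if (is.null(economic_activity_shares)) {
    e <- reference_margins()$activity
    economic_activity_shares <- stats::setNames(
      e$economic / sum(e$economic), e$activity
    )
  }
  if (abs(sum(economic_activity_shares) - 1) > 1e-6) {
    rlang::abort("`economic_activity_shares` must sum to 1.")
  }
  if (abs(sum(shared_scope_weights) - 1) > 1e-6) {
    rlang::abort("`shared_scope_weights` must sum to 1.")
  }
  for (p in profiles) validate_time_profile(p)
  structure(
    list(
      params = params, rules = rules, profiles = profiles,
      time_rate = time_rate, oop_scale = oop_scale, wage_scale = wage_scale,
      economic_activity_shares = economic_activity_shares,
      shared_scope_weights = shared_scope_weights,
      nutrition_gender_split = nutrition_gender_split,
      typology_shared_weights = typology_shared_weights,
      wages_bdt = wages_bdt, months = months, n_pk = n_pk, seed = seed
    ),
    class = "costing_config"
  )
}

#' Validate an expenditure ledger
#'
#' Checks the schema (all fourteen standard columns), coerces types,
#' normalizes empty strings to NA, and enforces the ledger invariants:
#' nonnegative amounts, tax within the amount, months inside the 40-month
#' window, known input/activity/scope/currency/payer codes, and durables
#' carrying a positive price and an expected life.
#'
#' @param ledger A data frame with columns `entry_id`, `month_index`,
#'   `description`, `amount`, `currency`, `input_code`, `activity_hint`,
#'   `cadre`, `component_scope`, `durable`, `unit_price`,
#'   `expected_life_years`, `tax_amount`, `payer`.
#' @return The validated ledger as a tibble; aborts with the offending
#'   column/entries named otherwise.
#' @export
validate_ledger <- function(ledger) {
  required <- c(
    "entry_id", "month_index", "description", "amount", "currency",
    "input_code", "activity_hint", "cadre", "component_scope", "durable",
    "unit_price", "expected_life_years", "tax_amount", "payer"
  )
  missing <- setdiff(required, names(ledger))
  if (length(missing)) {
    rlang::abort(paste0("Ledger is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  l <- tibble::as_tibble(ledger)[, required]
  for (col in c("activity_hint", "cadre", "component_scope")) {
    l[[col]] <- as.character(l[[col]])
    l[[col]][!is.na(l[[col]]) & l[[col]] == ""] <- NA_character_
  }
  l$durable <- as.logical(l$durable)
  l$durable[is.na(l$durable)] <- FALSE
  l$month_index <- as.integer(l$month_index)
  for (col in c("amount", "unit_price", "expected_life_years",
                "tax_amount")) {
    l[[col]] <- as.numeric(l[[col]])
  }
  l$tax_amount[is.na(l$tax_amount)] <- 0
  if (nrow(l) == 0) return(l)

  problems <- character()
  flag <- function(cond, msg) {
    if (any(cond)) {
      problems <<- c(problems, sprintf(
        "%s (entries: %s)", msg,
        paste(utils::head(l$entry_id[cond], 5), collapse = ", ")
      ))
    }
  }
  flag(is.na(l$amount) | l$amount < 0, "`amount` must be nonnegative")
  flag(l$tax_amount < 0 | l$tax_amount > l$amount + 1e-9,
       "`tax_amount` must lie in [0, amount]")
  flag(is.na(l$month_index) | l$month_index < 0 | l$month_index > 39,
       "`month_index` must lie in the 40-month window (0-39)")
  flag(!l$currency %in% c("BDT", "USD"), "`currency` must be BDT or USD")
  flag(!l$input_code %in% input_codes(), "`input_code` is not a valid code")
  flag(!is.na(l$activity_hint) & !l$activity_hint %in% activity_codes(),
       "`activity_hint` is not a valid activity code")
  flag(
    !is.na(l$component_scope) &
      !l$component_scope %in% c("nutrition", "agriculture", "gender",
                                "platform_wide"),
    "`component_scope` is not a valid scope"
  )
  flag(!l$payer %in% c("BRAC", "worker", "beneficiary"),
       "`payer` must be BRAC, worker or beneficiary")
  flag(l$durable & (is.na(l$expected_life_years) |
                      l$expected_life_years <= 0),
       "durable entries must carry a positive `expected_life_years`")
  flag(l$durable & (is.na(l$unit_price) | l$unit_price <= 0),
       "durable entries must carry a positive `unit_price`")
  if (length(problems)) {
    rlang::abort(paste0("Invalid ledger:\n- ",
                        paste(problems, collapse = "\n- ")))
  }
  l
}

#' Run the full costing pipeline
#'
#' Codes and values the ledger, allocates cadre salary pools by time share,
#' adds survey-based economic costs (worker unpaid time and OOP, beneficiary
#' participation time), allocates every cell across treatment arms through
#' the component-scope rule, attaches typology weights, and assembles the
#' cost cube with its unit-cost and cost-profile reports.
#'
#' @param ledger A ledger tibble, or a `costing_inputs` bundle from
#'   [generate_inputs()] (in which case the remaining arguments default to
#'   the bundle's components).
#' @param costing A [costing_config()].
#' @param roster A [beneficiary_roster()].
#' @param worker_survey,beneficiary_timeuse Optional survey tibbles (see
#'   [generate_worker_survey()], [generate_beneficiary_timeuse()]); when
#'   NULL the corresponding economic costs are omitted and the run is
#'   financial-only.
#' @return A list of class `costing_result`: `cube`, `totals`, `table`
#'   (margin report), `unit_costs`, `arm_costs`, `profiles`, `calibration`,
#'   `months`.
#' @export
run_costing <- function(ledger, costing = NULL, roster = NULL,
                        worker_survey = NULL, beneficiary_timeuse = NULL) {
  if (inherits(ledger, "costing_inputs")) {
    inputs <- ledger
    ledger <- inputs$ledger
    costing <- costing %||% inputs$costing
    roster <- roster %||% inputs$roster
    worker_survey <- worker_survey %||% inputs$worker_survey
    beneficiary_timeuse <- beneficiary_timeuse %||% inputs$beneficiary_timeuse
  }
  if (is.null(costing) || is.null(roster)) {
    rlang::abort("`costing` and `roster` are required.")
  }
  params <- costing$params
  months <- costing$months
  ledger <- validate_ledger(ledger)
  if (nrow(ledger) == 0) {
    rlang::warn("Empty ledger: producing a zero-cost financial report.")
  }

  cells <- NULL
  if (nrow(ledger) > 0) {
    coded <- assign_codes(ledger, costing$rules)
    year <- month_to_calendar_year(coded$month_index)
    usd <- to_usd_2019(coded$amount, coded$currency, year, params)
    charge <- usd
    for (i in which(coded$durable)) {
      charge[i] <- capital_charge(usd[i], params,
                                  expected_life_years =
                                    coded$expected_life_years[i],
                                  months = months)
    }

    direct <- coded[!coded$needs_allocation, ]
    fin <- tibble::tibble(
      activity = direct$activity, input = direct$input_code,
      stage = direct$stage, scope = direct$component_scope,
      amount = charge[!coded$needs_allocation], nature = "financial"
    )
    alloc_rows <- which(coded$needs_allocation)
    alloc <- lapply(alloc_rows, function(i) {
      prof <- costing$profiles[[coded$cadre[i]]]
      if (is.null(prof)) {
        rlang::abort(sprintf(
          "No time-allocation profile for cadre '%s' (entry %s).",
          coded$cadre[i], coded$entry_id[i]
        ))
      }
      amounts <- allocate_personnel(charge[i], prof)
      tibble::tibble(
        activity = names(amounts), input = coded$input_code[i],
        stage = classify_stage(names(amounts), coded$month_index[i]),
        scope = NA_character_, amount = unname(amounts),
        nature = "financial"
      )
    })
    cells <- dplyr::bind_rows(fin, dplyr::bind_rows(alloc))
  }

  # Economic costs from micro-costing surveys
  shares <- costing$economic_activity_shares
  econ_cells <- function(value, input) {
    keep <- shares > 0
    tibble::tibble(
      activity = names(shares)[keep], input = input, stage = "recurrent",
      scope = NA_character_, amount = value * unname(shares[keep]),
      nature = "economic"
    )
  }
  if (!is.null(worker_survey) && nrow(worker_survey) > 0) {
    hours <- sum(worker_survey$overtime_h + worker_survey$travel_h)
    cells <- dplyr::bind_rows(
      cells,
      econ_cells(hours * costing$time_rate, "personnel_hired"),
      econ_cells(sum(worker_survey$oop_usd) * costing$oop_scale,
                 "travel_perdiem_allowances")
    )
  }
  if (!is.null(beneficiary_timeuse) && nrow(beneficiary_timeuse) > 0) {
    wage_hr <- costing$wages_bdt / params$hours_per_workday /
      params$exchange_rate_bdt_per_usd
    benef <- (sum(beneficiary_timeuse$women_h) * wage_hr[["women"]] +
                sum(beneficiary_timeuse$men_h, na.rm = TRUE) *
                wage_hr[["men"]]) * costing$wage_scale
    cells <- dplyr::bind_rows(cells,
                              econ_cells(benef, "personnel_beneficiaries"))
  }

  # Arm allocation through the component-scope rule (full precision so
  # cube margins conserve to < $0.01 across hundreds of cells)
  arm_cells <- NULL
  if (!is.null(cells) && nrow(cells) > 0) {
    cells <- cells[cells$amount > 0, ]
    pieces <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      sw <- scope_weights(cells$activity[i], cells$scope[i],
                          costing$shared_scope_weights,
                          costing$nutrition_gender_split)
      sub <- lapply(names(sw)[sw > 0], function(sc) {
        by_arm <- allocate_to_arms(cells$amount[i] * sw[[sc]], sc, roster,
                                   round_cents = FALSE)
        tibble::tibble(arm = names(by_arm), amount = unname(by_arm))
      })
      sub <- dplyr::bind_rows(sub)
      sub$activity <- cells$activity[i]
      sub$input <- cells$input[i]
      sub$stage <- cells$stage[i]
      sub$nature <- cells$nature[i]
      pieces[[i]] <- sub
    }
    arm_cells <- dplyr::bind_rows(pieces)
    tw <- t(vapply(
      arm_cells$activity,
      function(a) map_typology(a, costing$typology_shared_weights,
                               costing$nutrition_gender_split),
      numeric(3)
    ))
    colnames(tw) <- paste0("w_", typology_codes())
    arm_cells <- dplyr::bind_cols(arm_cells, tibble::as_tibble(tw))
  }

  cube <- build_cube(arm_cells)
  nat <- cube_margin(cube, "nature")
  get_nat <- function(x) {
    v <- nat$amount[nat$nature == x]
    if (length(v)) v else 0
  }
  totals <- c(
    financial = get_nat("financial"),
    economic = get_nat("economic"),
    total = cube_total(cube)
  )
  structure(
    list(
      cube = cube, totals = totals, table = margin_report(cube),
      unit_costs = if (totals[["total"]] > 0) {
        unit_cost_table(cube, roster, months = months)
      } else NULL,
      arm_costs = if (nrow(cube) > 0) {
        arm_unit_costs(cube, roster, months = months)
      } else NULL,
      profiles = if (totals[["total"]] > 0) {
        list(
          activity = cost_profile(cube, "activity"),
          input = cost_profile(cube, "input"),
          stage = cost_profile(cube, "stage"),
          nature = cost_profile(cube, "nature"),
          typology = cost_profile(cube, "typology")
        )
      } else NULL,
      calibration = costing[c("time_rate", "oop_scale", "wage_scale")],
      months = months
    ),
    class = "costing_result"
  )
}

#' @export
print.costing_result <- function(x, ...) {
  cat("Programme costing result (2019 USD)\n")
  cat(sprintf("  Financial cost: %15s\n",
              formatC(x$totals[["financial"]], format = "f", digits = 2,
                      big.mark = ",")))
  cat(sprintf("  Economic cost:  %15s\n",
              formatC(x$totals[["economic"]], format = "f", digits = 2,
                      big.mark = ",")))
  cat(sprintf("  Total:          %15s\n",
              formatC(x$totals[["total"]], format = "f", digits = 2,
                      big.mark = ",")))
  if (!is.null(x$unit_costs)) {
    ann <- x$unit_costs[x$unit_costs$period == "annual", ]
    cat(sprintf("  Annual cost per household: %.2f (window %.1f months)\n",
                ann$value[ann$denominator == "households"], x$months))
  }
  invisible(x)
}
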