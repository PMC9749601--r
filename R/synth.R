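#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: the reference budget
#' margins the coded, valued ledger must reproduce, the survey moments for
#' worker and beneficiary micro-costing draws, the roster, the frontline
#' workforce size, the synthetic daily wages, and the arm-level annual
#' household cost series the component budgets are constructed to match.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param margins Target margins as in [reference_margins()].
#' @param roster_scale Multiplier on the beneficiary roster.
#' @param n_pk Number of nutrition frontline workers (PKs).
#' @param months Implementation window in months.
#' @param wages_bdt Synthetic daily agricultural wages `c(men=, women=)` in
#'   BDT (declared placeholders, not survey values).
#' @param arm_annual_cost_per_household Named target annual cost per
#'   household by arm used to solve the shared-activity component budgets.
#' @param dm_charge_usd District-manager salary charged to the programme
#'   (at their programme FTE share).
#' @param startup_planning_usd Planning amount placed in the start-up
#'   window; the start-up training amount is solved from the stage margin.
#' @param params [valuation_params()].
#' @param pk_profile,dm_profile Time-allocation profiles for the PK and DM
#'   cadres.
#' @param nutrition_gender_split Sub-split of the combined nutrition/gender
#'   home-visit activity.
#' @param typology_shared_weights Typology weights for shared activities.
#' @param worker_moments,beneficiary_moments Gamma moments (subsets of
#'   [psa_moments()]).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         margins = reference_margins(),
                         roster_scale = 1,
                         n_pk = 80,
                         months = 40,
                         wages_bdt = c(men = 300, women = 250),
                         arm_annual_cost_per_household =
                           c("2" = 36.62, "3" = 65.18, "4" = 87.50),
                         dm_charge_usd = 20000,
                         startup_planning_usd = 20000,
                         params = valuation_params(),
                         pk_profile = default_pk_profile(),
                         dm_profile = default_dm_profile(),
                         nutrition_gender_split = c(nutrition = 0.8,
                                                    gender = 0.2),
                         typology_shared_weights =
                           default_shared_typology_weights(),
                         worker_moments = NULL,
                         beneficiary_moments = NULL) {
  moments <- psa_moments()
  if (is.null(worker_moments)) {
    worker_moments <- moments[startsWith(moments$parameter, "pk_"), ]
  }
  if (is.null(beneficiary_moments)) {
    beneficiary_moments <- moments[startsWith(moments$parameter,
                                              "beneficiary_"), ]
  }
  validate_margins(margins)
  validate_time_profile(pk_profile)
  validate_time_profile(dm_profile)
  structure(
    list(
      seed = as.integer(seed), margins = margins,
      roster_scale = roster_scale, n_pk = n_pk, months = months,
      wages_bdt = wages_bdt,
      arm_annual_cost_per_household = arm_annual_cost_per_household,
      dm_charge_usd = dm_charge_usd,
      startup_planning_usd = startup_planning_usd,
      params = params, pk_profile = pk_profile, dm_profile = dm_profile,
      nutrition_gender_split = nutrition_gender_split,
      typology_shared_weights = typology_shared_weights,
      worker_moments = worker_moments,
      beneficiary_moments = beneficiary_moments
    ),
    class = "synth_config"
  )
}

#' @rdname synth_config
#' @export
default_pk_profile <- function() {
  list(cadre = "PK", fte_share = 1, activity_shares = c(
    home_visits_nutrition_gender = 0.80, training = 0.10,
    planning_microplanning = 0.05, integration_coordination = 0.05
  ))
}

#' @rdname synth_config
#' @export
default_dm_profile <- function() {
  list(cadre = "DM", fte_share = 0.30,
       activity_shares = c(site_supervision = 1))
}

# Margins are internally consistent when every dimension carries the same
# grand totals (to a few cents of print rounding).
validate_margins <- function(margins, tol = 0.05) {
  tot <- vapply(margins, function(m) sum(m$financial) + sum(m$economic),
                numeric(1))
  if (max(tot) - min(tot) > tol) {
    off <- names(tot)[which.max(abs(tot - stats::median(tot)))]
    rlang::abort(sprintf(
      "Margin dimension '%s' is inconsistent with the others (totals: %s).",
      off, paste(sprintf("%s=%.2f", names(tot), tot), collapse = ", ")
    ))
  }
  invisible(margins)
}

#' @rdname synth_config
#' @param config A `synth_config`.
#' @export
generate_roster <- function(config = synth_config()) {
  beneficiary_roster(scale = config$roster_scale)
}

#' Synthetic frontline-worker micro-costing survey
#'
#' One record per worker-month: unpaid overtime hours, unreimbursed travel
#' hours, and out-of-pocket spending (USD, net of stipends) drawn from the
#' configured gamma moments, with the OOP mean switching across the three
#' stipend periods. Deterministic given the config seed; sample moments
#' converge to the configured moments as the workforce grows.
#'
#' @param config A [synth_config()].
#' @return A tibble `worker`, `month`, `overtime_h`, `travel_h`, `oop_usd`.
#' @export
generate_worker_survey <- function(config = synth_config()) {
  set.seed(derive_seed(config$seed, "worker_survey"))
  wm <- config$worker_moments
  spec <- function(p) {
    i <- match(p, wm$parameter)
    gamma_from_moments(wm$mean[i], wm$sd[i])
  }
  grid <- tidyr::expand_grid(worker = seq_len(config$n_pk),
                             month = 0:(config$months - 1))
  n <- nrow(grid)
  period <- ifelse(grid$month <= 16, "pk_oop_period1",
                   ifelse(grid$month <= 32, "pk_oop_period2",
                          "pk_oop_period3"))
  oop <- numeric(n)
  for (p in unique(period)) {
    sel <- period == p
    oop[sel] <- sample_gamma(spec(p), sum(sel))
  }
  grid$overtime_h <- sample_gamma(spec("pk_overtime_hours"), n)
  grid$travel_h <- sample_gamma(spec("pk_travel_hours"), n)
  grid$oop_usd <- oop
  grid
}

#' Synthetic beneficiary participation time
#'
#' One record per household-month with participation hours for the index
#' woman and (where present) her spouse, drawn from the configured gamma
#' moments; women's expected participation is roughly double men's. Spouse
#' rows exist only for the households contributing an index male to the
#' roster's index-pair count.
#'
#' @param config A [synth_config()].
#' @return A tibble `arm`, `household`, `month`, `women_h`, `men_h` (NA for
#'   households without an index male).
#' @export
generate_beneficiary_timeuse <- function(config = synth_config()) {
  set.seed(derive_seed(config$seed, "beneficiary_timeuse"))
  bm <- config$beneficiary_moments
  spec <- function(p) {
    i <- match(p, bm$parameter)
    gamma_from_moments(bm$mean[i], bm$sd[i])
  }
  roster <- generate_roster(config)
  gc <- roster_gender_counts(roster)
  grid <- dplyr::bind_rows(lapply(seq_len(nrow(roster)), function(i) {
    tidyr::expand_grid(
      arm = roster$arm[i],
      household = seq_len(roster$households[i]),
      month = 0:(config$months - 1)
    )
  }))
  n <- nrow(grid)
  grid$women_h <- sample_gamma(spec("beneficiary_hours_women"), n)
  has_spouse <- grid$household <= gc$n_men[match(grid$arm, gc$arm)]
  men <- rep(NA_real_, n)
  men[has_spouse] <- sample_gamma(spec("beneficiary_hours_men"),
                                  sum(has_spouse))
  grid$men_h <- men
  grid
}

# Solve the component-scope weight vector for shared activities so that the
# arm-allocation rule reproduces the configured arm-level annual household
# cost series. Component-specific activities contribute fixed scope amounts;
# the remaining (shared) cost takes a common (nutrition, agriculture,
# gender) weight vector obtained linearly from the component budget targets.
solve_shared_scope_weights <- function(config) {
  m <- config$margins$activity
  tot <- stats::setNames(m$financial + m$economic, m$activity)
  grand <- sum(tot)
  roster <- generate_roster(config)
  hh <- stats::setNames(roster$households, roster$arm)
  years <- config$months / 12
  a <- config$arm_annual_cost_per_household
  t_raw <- c(
    nutrition = a[["2"]] * sum(hh) * years,
    agriculture = (a[["3"]] - a[["2"]]) * (hh[["3"]] + hh[["4"]]) * years,
    gender = (a[["4"]] - a[["3"]]) * hh[["4"]] * years
  )
  if (any(t_raw < 0)) {
    rlang::abort("Arm cost targets must be nondecreasing from arm 2 to 4.")
  }
  targets <- t_raw * grand / sum(t_raw)
  split <- config$nutrition_gender_split
  hv_ng <- tot[["home_visits_nutrition_gender"]]
  pinned <- c(
    nutrition = unname(split[["nutrition"]]) * hv_ng,
    agriculture = sum(tot[agriculture_scope_activities()]),
    gender = unname(split[["gender"]]) * hv_ng
  )
  shared <- grand - sum(pinned)
  w <- (targets - pinned) / shared
  if (any(w < -1e-9)) {
    rlang::abort(paste0(
      "Arm cost targets are infeasible: component-specific activities ",
      "already exceed the implied budget for ",
      paste(names(w)[w < -1e-9], collapse = ", ")
    ))
  }
  w <- pmax(w, 0)
  w / sum(w)
}

#' Synthetic expenditure ledger
#'
#' Generates line items whose coded, valued financial aggregates reproduce
#' the configured target margins to within one cent. Construction: personnel
#' pools for the PK and DM cadres are placed first (the PK pool is implied
#' by the hourly time-valuation rate at the expected survey hours, times the
#' contracted 36-hour week); small agriculture inputs are pinned to their
#' natural activities (including a sub-threshold durable to exercise the
#' capital rule and taxed supplies to exercise the tax rule); the remaining
#' activity x input cells follow an independence table of the reduced
#' margins. Start-up portions of the one-time activities are dated in months
#' 0-5, everything else later; cell amounts are split into lognormally
#' jittered line items rescaled to conserve each cell exactly.
#'
#' @param config A [synth_config()].
#' @return A ledger tibble with the standard columns (see
#'   [validate_ledger()]).
#' @export
generate_ledger <- function(config = synth_config()) {
  set.seed(derive_seed(config$seed, "ledger"))
  m <- config$margins
  params <- config$params
  months <- config$months
  fx <- params$exchange_rate_bdt_per_usd
  act_fin <- stats::setNames(m$activity$financial, m$activity$activity)
  inp_fin <- stats::setNames(m$input$financial, m$input$input)
  eco <- stats::setNames(m$input$economic, m$input$input)

  # PK salary pool implied by the time-valuation rate at expected hours
  wm <- config$worker_moments
  exp_hours <- config$n_pk * months *
    sum(wm$mean[wm$parameter %in% c("pk_overtime_hours", "pk_travel_hours")])
  rate0 <- if (exp_hours > 0) eco[["personnel_hired"]] / exp_hours else 0
  monthly_hours <- params$contracted_week_hours * 52 / 12
  pk_pool <- rate0 * monthly_hours * config$n_pk * months
  pk_alloc <- allocate_personnel(pk_pool, config$pk_profile)
  dm_charge <- config$dm_charge_usd

  placed_act <- stats::setNames(numeric(length(act_fin)), names(act_fin))
  placed_act[names(pk_alloc)] <- placed_act[names(pk_alloc)] + pk_alloc
  placed_act[["site_supervision"]] <- placed_act[["site_supervision"]] +
    dm_charge

  # Pin minor agriculture inputs to their natural activities
  pins <- tibble::tibble(
    activity = c("home_visits_agriculture", "distribution_of_inputs",
                 "distribution_of_inputs"),
    input = c("agriculture_equipment", "agriculture_supplies",
              "fuel_maintenance"),
    amount = c(inp_fin[["agriculture_equipment"]],
               inp_fin[["agriculture_supplies"]],
               inp_fin[["fuel_maintenance"]]),
    durable = c(inp_fin[["agriculture_equipment"]] > 0, FALSE, FALSE)
  )
  pins <- pins[pins$amount > 0, ]
  for (i in seq_len(nrow(pins))) {
    placed_act[[pins$activity[i]]] <- placed_act[[pins$activity[i]]] +
      pins$amount[i]
  }
  placed_inp <- stats::setNames(numeric(length(inp_fin)), names(inp_fin))
  placed_inp[["personnel_hired"]] <- pk_pool + dm_charge
  for (i in seq_len(nrow(pins))) {
    placed_inp[[pins$input[i]]] <- placed_inp[[pins$input[i]]] +
      pins$amount[i]
  }

  a1 <- act_fin - placed_act
  i1 <- inp_fin - placed_inp
  if (any(a1 < -0.005)) {
    rlang::abort(sprintf(
      "Infeasible target margins in dimension 'activity': %s over-committed.",
      paste(names(a1)[a1 < -0.005], collapse = ", ")
    ))
  }
  if (any(i1 < -0.005)) {
    rlang::abort(sprintf(
      "Infeasible target margins in dimension 'input': %s over-committed.",
      paste(names(i1)[i1 < -0.005], collapse = ", ")
    ))
  }
  a1 <- pmax(a1, 0)
  i1 <- pmax(i1, 0)
  joint <- outer(a1, i1) / sum(i1)

  # Start-up composition: full installation and materials development, a
  # configured planning slice, and a training remainder solved from the
  # stage margin.
  su_total <- m$stage$financial[m$stage$stage == "start_up"]
  su <- c(
    programme_installation = unname(a1[["programme_installation"]]),
    materials_development = unname(a1[["materials_development"]]),
    planning_microplanning = min(config$startup_planning_usd,
                                 unname(a1[["planning_microplanning"]]))
  )
  su[["training"]] <- su_total - sum(su)
  if (su[["training"]] < -0.005 || su[["training"]] > a1[["training"]]) {
    rlang::abort(
      "Infeasible target margins in dimension 'stage': start-up total cannot be composed from one-time activities."
    )
  }
  su <- pmax(su, 0)

  cells <- list()
  for (a in names(a1)) {
    for (i in names(i1)) {
      amt <- joint[a, i]
      if (amt < 0.005) next
      f <- if (a %in% names(su) && a1[[a]] > 0) su[[a]] / a1[[a]] else 0
      if (f > 0) {
        cells[[length(cells) + 1]] <- list(
          activity = a, input = i, amount = amt * f, stage = "start_up",
          durable = FALSE
        )
      }
      if (f < 1) {
        cells[[length(cells) + 1]] <- list(
          activity = a, input = i, amount = amt * (1 - f),
          stage = "recurrent", durable = FALSE
        )
      }
    }
  }
  for (i in seq_len(nrow(pins))) {
    cells[[length(cells) + 1]] <- list(
      activity = pins$activity[i], input = pins$input[i],
      amount = pins$amount[i], stage = "recurrent", durable = pins$durable[i]
    )
  }

  rows <- list()
  add_row <- function(usd, month, activity_hint, input, cadre = NA_character_,
                      scope = NA_character_, durable = FALSE,
                      life = NA_real_, tax_frac = 0, description) {
    year <- month_to_calendar_year(month)
    nominal <- usd * fx * params$inflation_index[[as.character(year)]]
    rows[[length(rows) + 1]] <<- tibble::tibble(
      month_index = month, description = description, amount = nominal,
      currency = "BDT", input_code = input, activity_hint = activity_hint,
      cadre = cadre, component_scope = scope, durable = durable,
      unit_price = if (durable) nominal else NA_real_,
      expected_life_years = if (durable) life else NA_real_,
      tax_amount = tax_frac * nominal, payer = "BRAC"
    )
  }

  for (cell in cells) {
    n_items <- min(6L, max(1L, ceiling(cell$amount / 10000)))
    jit <- stats::rlnorm(n_items, 0, 0.4)
    amts <- cell$amount * jit / sum(jit)
    pool <- if (cell$stage == "start_up") {
      0:5
    } else if (cell$activity %in% one_time_activities()) {
      6:(months - 1)
    } else {
      0:(months - 1)
    }
    mo <- sample(pool, n_items, replace = TRUE)
    scope <- if (cell$activity %in% agriculture_scope_activities()) {
      "agriculture"
    } else {
      NA_character_
    }
    hint <- cell$activity
    # leave overhead expenditure uncoded to exercise the input-lookup rule
    if (cell$activity == "indirect_overhead" && cell$input == "overhead") {
      hint <- NA_character_
    }
    for (k in seq_len(n_items)) {
      add_row(
        usd = amts[k], month = mo[k], activity_hint = hint,
        input = cell$input, scope = scope,
        durable = cell$durable && k == 1, life = 5,
        tax_frac = if (cell$input == "supplies") 0.05 else 0,
        description = sprintf("%s - %s (item %d)",
                              gsub("_", " ", cell$activity),
                              gsub("_", " ", cell$input), k)
      )
    }
  }

  # Cadre salary pools, flagged for time-share allocation downstream
  if (pk_pool > 0) {
    n_chunks <- 8L
    jit <- stats::rlnorm(n_chunks, 0, 0.2)
    amts <- pk_pool * jit / sum(jit)
    mo <- sort(sample(6:(months - 1), n_chunks, replace = TRUE))
    for (k in seq_len(n_chunks)) {
      add_row(amts[k], mo[k], NA_character_, "personnel_hired",
              cadre = "PK",
              description = sprintf("PK frontline worker salaries (batch %d)",
                                    k))
    }
  }
  if (dm_charge > 0) {
    add_row(dm_charge / config$dm_profile$fte_share,
            sample(6:(months - 1), 1), NA_character_, "personnel_hired",
            cadre = "DM", description = "District manager salaries")
  }

  ledger <- dplyr::bind_rows(rows)
  ledger$entry_id <- sprintf("E%04d", seq_len(nrow(ledger)))
  validate_ledger(ledger[, c(
    "entry_id", "month_index", "description", "amount", "currency",
    "input_code", "activity_hint", "cadre", "component_scope", "durable",
    "unit_price", "expected_life_years", "tax_amount", "payer"
  )])
}

#' Generate the full synthetic input bundle
#'
#' Produces everything one pipeline run needs: ledger, worker survey,
#' beneficiary time use, roster, and the run configuration with the three
#' calibration constants solved so the valued economic aggregates land on
#' the configured margins: the hourly time-valuation rate (printed economic
#' personnel cell / realized survey hours), the OOP scale, and the
#' beneficiary wage scale. The solved constants are recorded in the
#' returned configuration for provenance.
#'
#' @param config A [synth_config()].
#' @return A list of class `costing_inputs` with elements `ledger`,
#'   `worker_survey`, `beneficiary_timeuse`, `roster`, `costing` (a
#'   [costing_config()]), and `synth` (the generating config).
#' @export
generate_inputs <- function(config = synth_config()) {
  roster <- generate_roster(config)
  ws <- generate_worker_survey(config)
  bt <- generate_beneficiary_timeuse(config)
  ledger <- generate_ledger(config)
  eco <- stats::setNames(config$margins$input$economic,
                         config$margins$input$input)

  hours <- sum(ws$overtime_h + ws$travel_h)
  time_rate <- if (hours > 0) eco[["personnel_hired"]] / hours else 0
  oop_total <- sum(ws$oop_usd)
  oop_scale <- if (oop_total > 0) {
    eco[["travel_perdiem_allowances"]] / oop_total
  } else 0
  wage_hr <- config$wages_bdt / config$params$hours_per_workday /
    config$params$exchange_rate_bdt_per_usd
  benef_raw <- sum(bt$women_h) * wage_hr[["women"]] +
    sum(bt$men_h, na.rm = TRUE) * wage_hr[["men"]]
  wage_scale <- if (benef_raw > 0) {
    eco[["personnel_beneficiaries"]] / benef_raw
  } else 0

  eco_act <- stats::setNames(config$margins$activity$economic,
                             config$margins$activity$activity)
  shares <- if (sum(eco_act) > 0) eco_act / sum(eco_act) else eco_act

  costing <- costing_config(
    params = config$params,
    profiles = list(PK = config$pk_profile, DM = config$dm_profile),
    time_rate = time_rate, oop_scale = oop_scale, wage_scale = wage_scale,
    economic_activity_shares = shares,
    shared_scope_weights = solve_shared_scope_weights(config),
    nutrition_gender_split = config$nutrition_gender_split,
    typology_shared_weights = config$typology_shared_weights,
    wages_bdt = config$wages_bdt,
    months = config$months, n_pk = config$n_pk, seed = config$seed
  )
  structure(
    list(ledger = ledger, worker_survey = ws, beneficiary_timeuse = bt,
         roster = roster, costing = costing, synth = config),
    class = "costing_inputs"
  )
}
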