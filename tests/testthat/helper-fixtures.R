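# Shared fixtures: the default synthetic study (generated once per test run)
# and small helpers used across files.

.fixture_env <- new.env(parent = emptyenv())

default_inputs <- function() {
  if (is.null(.fixture_env$inputs)) {
    .fixture_env$inputs <- generate_inputs(synth_config(seed = 101))
  }
  .fixture_env$inputs
}

default_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_costing(default_inputs())
  }
  .fixture_env$run
}

default_model <- function() {
  if (is.null(.fixture_env$model)) {
    run <- default_run()
    inp <- default_inputs()
    .fixture_env$model <- build_cost_model(
      run$totals[["financial"]], inp$costing, inp$roster
    )
  }
  .fixture_env$model
}

pk_profile <- function() {
  list(cadre = "PK", fte_share = 1, activity_shares = c(
    home_visits_nutrition_gender = 0.80, training = 0.10,
    planning_microplanning = 0.05, integration_coordination = 0.05
  ))
}

minimal_ledger <- function(...) {
  defaults <- list(
    entry_id = "E0001", month_index = 10L, description = "test item",
    amount = 8477, currency = "BDT", input_code = "supplies",
    activity_hint = "training", cadre = NA_character_,
    component_scope = NA_character_, durable = FALSE,
    unit_price = NA_real_, expected_life_years = NA_real_,
    tax_amount = 0, payer = "BRAC"
  )
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}
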