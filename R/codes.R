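#' Standardized cost-category code sets
#'
#' Closed enumerations used throughout the costing pipeline, following the
#' standardized multisectoral-nutrition costing categories (SEEMS-Nutrition
#' style): 15 programme activities, 10 resource inputs, two implementation
#' stages, three nutrition-sensitive value-chain typologies, and the three
#' additive treatment arms.
#'
#' @return A character vector of valid codes.
#' @name code-sets
NULL

#' @rdname code-sets
#' @export
activity_codes <- function() {
  c(
    "planning_microplanning", "programme_installation", "awareness_raising",
    "training", "materials_development", "management", "monitoring_evaluation",
    "procurement", "distribution_of_inputs", "site_supervision",
    "home_visits_nutrition_gender", "home_visits_agriculture",
    "community_events", "integration_coordination", "indirect_overhead"
  )
}

#' @rdname code-sets
#' @export
input_codes <- function() {
  c(
    "personnel_hired", "personnel_beneficiaries", "supplies", "equipment",
    "agriculture_supplies", "agriculture_equipment", "contracted_services",
    "fuel_maintenance", "travel_perdiem_allowances", "overhead"
  )
}

#' @rdname code-sets
#' @export
stage_codes <- function() c("start_up", "recurrent")

#' @rdname code-sets
#' @export
typology_codes <- function() c("supply", "demand", "enabling_environment")

#' @rdname code-sets
#' @export
arm_codes <- function() c("2", "3", "4")

#' One-time activities eligible for start-up classification
#'
#' A cost cell is classified `start_up` only when it falls in the 6-month
#' launch window (months 0-5) *and* belongs to one of these one-time
#' activities (planning, programme installation, materials development,
#' initial training). Recurring activities incurred during the launch window
#' remain recurrent.
#'
#' @return Character vector of activity codes.
#' @export
one_time_activities <- function() {
  c(
    "planning_microplanning", "programme_installation",
    "materials_development", "training"
  )
}

# Activities whose component scope is fixed rather than shared.
agriculture_scope_activities <- function() {
  c("home_visits_agriculture", "distribution_of_inputs")
}
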