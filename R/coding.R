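#' Default coding ruleset for ledger entries
#'
#' Resolves ledger entries that lack an explicit activity hint. Rules are
#' applied in order: (1) an explicit `activity_hint` passes through; (2)
#' entries carrying a worker `cadre` but no hint are flagged for time-share
#' allocation via [allocate_personnel()]; (3) an input-to-activity lookup
#' (e.g. overhead expenditure codes to the indirect/overhead activity); (4)
#' case-insensitive keyword rules on the free-text description. Entries no
#' rule resolves are rejected, never silently defaulted.
#'
#' The ruleset is an ordinary list and is intended to be edited or replaced
#' wholesale (e.g. loaded from YAML) rather than hard-coded into analyses.
#'
#' @return A list with elements `version`, `input_activity` (named character
#'   map input code -> activity code) and `keywords` (data frame with
#'   `pattern`, `activity`).
#' @export
default_coding_rules <- function() {
  list(
    version = "1.0",
    input_activity = c(
      overhead = "indirect_overhead",
      fuel_maintenance = "distribution_of_inputs"
    ),
    keywords = data.frame(
      pattern = c("audit", "monitor", "training|workshop", "supervis"),
      activity = c(
        "monitoring_evaluation", "monitoring_evaluation", "training",
        "site_supervision"
      ),
      stringsAsFactors = FALSE
    )
  )
}

#' Classify a cost as start-up or recurrent
#'
#' `start_up` requires both the 6-month launch window (months 0-5) and a
#' one-time activity ([one_time_activities()]); recurring activities in the
#' launch window, and anything after month 5, are `recurrent`.
#'
#' @param activity Character vector of activity codes.
#' @param month_index Integer vector, months since programme start (0-based).
#' @return Character vector of stage codes.
#' @export
classify_stage <- function(activity, month_index) {
  ifelse(
    month_index <= 5 & activity %in% one_time_activities(),
    "start_up", "recurrent"
  )
}

#' Code ledger entries to standardized activity and stage categories
#'
#' @param entries A ledger tibble as validated by [validate_ledger()].
#' @param rules A coding ruleset, see [default_coding_rules()].
#' @return `entries` with three added columns: `activity` (NA for entries
#'   flagged for personnel allocation), `stage` (likewise NA until
#'   allocation), and `needs_allocation` (TRUE for cadre-tagged entries whose
#'   activity split comes from a time-allocation profile).
#' @export
assign_codes <- function(entries, rules = default_coding_rules()) {
  n <- nrow(entries)
  activity <- as.character(entries$activity_hint)
  needs_allocation <- is.na(activity) & !is.na(entries$cadre)

  unresolved <- which(is.na(activity) & !needs_allocation)
  if (length(unresolved)) {
    mapped <- unname(rules$input_activity[entries$input_code[unresolved]])
    activity[unresolved] <- mapped
  }
  unresolved <- which(is.na(activity) & !needs_allocation)
  if (length(unresolved) && nrow(rules$keywords)) {
    for (i in unresolved) {
      hit <- which(vapply(
        rules$keywords$pattern,
        function(p) grepl(p, entries$description[i], ignore.case = TRUE),
        logical(1)
      ))
      if (length(hit)) activity[i] <- rules$keywords$activity[hit[1]]
    }
  }
  unresolved <- which(is.na(activity) & !needs_allocation)
  if (length(unresolved)) {
    rlang::abort(paste0(
      "Unresolvable ledger entries (no activity hint, cadre, or matching ",
      "rule): ", paste(entries$entry_id[unresolved], collapse = ", ")
    ))
  }

  bad <- which(!is.na(activity) & !(activity %in% activity_codes()))
  if (length(bad)) {
    rlang::abort(paste0(
      "Unknown activity codes for entries: ",
      paste(entries$entry_id[bad], collapse = ", ")
    ))
  }

  entries$activity <- activity
  entries$needs_allocation <- needs_allocation
  entries$stage <- ifelse(
    needs_allocation, NA_character_,
    classify_stage(activity, entries$month_index)
  )
  entries
}

#' Validate a personnel time-allocation profile
#'
#' @param profile A list with `cadre`, `fte_share` (fraction of paid time on
#'   the programme) and `activity_shares` (named fractions over activities,
#'   summing to 1).
#' @return The profile, invisibly; errors otherwise.
#' @export
validate_time_profile <- function(profile) {
  shares <- profile$activity_shares
  if (is.null(shares) || is.null(names(shares))) {
    rlang::abort("`activity_shares` must be a named numeric vector.")
  }
  if (any(shares < 0) || any(shares > 1)) {
    rlang::abort("Activity shares must lie in [0, 1].")
  }
  if (abs(sum(shares) - 1) > 1e-9) {
    rlang::abort(sprintf(
      "Activity shares must sum to 1 (got %.12g).", sum(shares)
    ))
  }
  bad <- setdiff(names(shares), activity_codes())
  if (length(bad)) {
    rlang::abort(paste0("Unknown activities in profile: ",
                        paste(bad, collapse = ", ")))
  }
  fte <- profile$fte_share
  if (!is.numeric(fte) || length(fte) != 1 || fte < 0 || fte > 1) {
    rlang::abort("`fte_share` must be a single number in [0, 1].")
  }
  invisible(profile)
}

#' Allocate a salary pool across activities by time shares
#'
#' Splits `salary_pool * fte_share` across activities according to the
#' profile's activity shares, e.g. a nutrition frontline worker spending 80%
#' of time on home counselling, 10% on training, 5% on planning and 5% on
#' coordination.
#'
#' @param salary_pool Nonnegative money amount.
#' @param profile Time-allocation profile, see [validate_time_profile()].
#' @return Named numeric vector (activity -> money) summing to
#'   `salary_pool * fte_share`.
#' @export
#' @examples
#' pk <- list(cadre = "PK", fte_share = 1, activity_shares = c(
#'   home_visits_nutrition_gender = 0.80, training = 0.10,
#'   planning_microplanning = 0.05, integration_coordination = 0.05
#' ))
#' allocate_personnel(100, pk)
allocate_personnel <- function(salary_pool, profile) {
  assert_scalar_number(salary_pool, "salary_pool", min = 0)
  validate_time_profile(profile)
  salary_pool * profile$fte_share * profile$activity_shares
}

#' Partition a shared cost proportionally, conserving money
#'
#' Proportional split of a shared input or capital cost across related
#' categories. With `round_cents = TRUE` (default) parts are whole cents and
#' a largest-remainder correction guarantees they sum to the rounded input
#' exactly; with `round_cents = FALSE` the split is exact proportional
#' arithmetic (used internally where many splits are summed and sub-cent
#' conservation matters).
#'
#' @param amount Money to split.
#' @param weights Named nonnegative weights summing to 1 (+/- 1e-9).
#' @param round_cents Round each part to whole cents with conservation.
#' @return Named numeric vector summing to `amount` (to the cent).
#' @export
#' @examples
#' allocate_shared(100, c(nutrition = .60, agriculture = .25, gender = .15))
allocate_shared <- function(amount, weights, round_cents = TRUE) {
  assert_scalar_number(amount, "amount", min = 0)
  if (round_cents) {
    largest_remainder_split(amount, weights)
  } else {
    if (length(weights) == 0) rlang::abort("`weights` must be non-empty.")
    if (any(weights < 0)) rlang::abort("`weights` must be nonnegative.")
    if (abs(sum(weights) - 1) > 1e-9) {
      rlang::abort("`weights` must sum to 1.")
    }
    amount * weights
  }
}

#' Allocate a cost cell across treatment arms
#'
#' Costs follow component eligibility under the additive trial design:
#' nutrition and platform-wide components serve arms 2-4, agriculture serves
#' arms 3-4, gender serves arm 4 only. Within the eligible arm set the cost
#' splits proportionally to household counts.
#'
#' @param cell_amount Money to allocate.
#' @param component_scope One of `"nutrition"`, `"agriculture"`, `"gender"`,
#'   `"platform_wide"`.
#' @param roster A [beneficiary_roster()].
#' @param round_cents See [allocate_shared()].
#' @return Named numeric vector over the eligible arms, conserving
#'   `cell_amount`.
#' @export
allocate_to_arms <- function(cell_amount, component_scope, roster,
                             round_cents = TRUE) {
  eligible <- switch(component_scope,
    nutrition = ,
    platform_wide = c("2", "3", "4"),
    agriculture = c("3", "4"),
    gender = "4",
    rlang::abort(sprintf("Unknown component scope '%s'.", component_scope))
  )
  hh <- roster$households[match(eligible, roster$arm)]
  if (any(is.na(hh)) || sum(hh) <= 0) {
    rlang::abort("Roster lacks household counts for the eligible arms.")
  }
  w <- stats::setNames(hh / sum(hh), eligible)
  allocate_shared(cell_amount, w, round_cents = round_cents)
}

#' Default typology weights for shared activities
#'
#' Management, monitoring, supervision, planning, overhead and other shared
#' activities span all three value-chain pathways; these default weights
#' reflect the package's reference cost structure (roughly a quarter supply,
#' a third demand, the rest enabling environment) and are a configuration
#' parameter, not an estimate.
#'
#' @return Named numeric vector over [typology_codes()].
#' @export
default_shared_typology_weights <- function() {
  c(supply = 0.21, demand = 0.345, enabling_environment = 0.445)
}

#' Map an activity to nutrition-sensitive value-chain typology weights
#'
#' Component-specific activities map directly: agricultural extension and
#' input distribution to the supply side; nutrition home counselling to the
#' demand side; gender activities to the enabling environment; awareness
#' raising to demand. The combined nutrition/gender home-visit activity is
#' split by `nutrition_gender_split`. All other (shared) activities receive
#' `component_weights`.
#'
#' @param activity A single activity code.
#' @param component_weights Named weights over [typology_codes()] for shared
#'   activities, summing to 1.
#' @param nutrition_gender_split Named fractions `c(nutrition=, gender=)`
#'   splitting the combined home-visit activity (nutrition -> demand,
#'   gender -> enabling environment).
#' @return Named numeric vector over the three typologies, summing to 1.
#' @export
map_typology <- function(activity,
                         component_weights = default_shared_typology_weights(),
                         nutrition_gender_split = c(nutrition = 0.8,
                                                    gender = 0.2)) {
  if (!activity %in% activity_codes()) {
    rlang::abort(sprintf("Unknown activity code '%s'.", activity))
  }
  zero <- stats::setNames(numeric(3), typology_codes())
  if (activity %in% agriculture_scope_activities()) {
    zero[["supply"]] <- 1
    return(zero)
  }
  if (activity == "awareness_raising") {
    zero[["demand"]] <- 1
    return(zero)
  }
  if (activity == "home_visits_nutrition_gender") {
    if (abs(sum(nutrition_gender_split) - 1) > 1e-9) {
      rlang::abort("`nutrition_gender_split` must sum to 1.")
    }
    zero[["demand"]] <- unname(nutrition_gender_split[["nutrition"]])
    zero[["enabling_environment"]] <- unname(nutrition_gender_split[["gender"]])
    return(zero)
  }
  w <- component_weights[typology_codes()]
  if (any(is.na(w)) || abs(sum(w) - 1) > 1e-9) {
    rlang::abort("`component_weights` must cover all typologies and sum to 1.")
  }
  stats::setNames(as.numeric(w), typology_codes())
}

# Component-scope weights for a cost cell: explicit scope wins; agriculture
# activities are fixed; the combined nutrition/gender activity splits by the
# configured sub-split; every other activity is shared and takes the solved
# shared-scope weight vector.
scope_weights <- function(activity, scope, shared_scope_weights,
                          nutrition_gender_split = c(nutrition = 0.8,
                                                     gender = 0.2)) {
  if (!is.na(scope)) {
    return(stats::setNames(1, scope))
  }
  if (activity %in% agriculture_scope_activities()) {
    return(c(agriculture = 1))
  }
  if (activity == "home_visits_nutrition_gender") {
    return(c(
      nutrition = unname(nutrition_gender_split[["nutrition"]]),
      gender = unname(nutrition_gender_split[["gender"]])
    ))
  }
  shared_scope_weights
}
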