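#' Beneficiary roster by treatment arm
#'
#' Household and beneficiary counts for the three treatment arms under the
#' four denominator definitions used for unit costs: households; the index
#' female plus her spouse; index adults plus children; and all household
#' members. Defaults are the trial's enrolment counts (1,260 households per
#' arm; 2,353/2,398/2,339 index pairs; 3,703 index-plus-children and 5,884
#' all-members per arm). Pooled totals are computed as sums over arms via
#' [roster_totals()].
#'
#' @param scale Positive multiplier applied to every count (for stress
#'   tests); counts are rounded to whole persons.
#' @return A tibble of class `nutricost_roster` with columns `arm`,
#'   `households`, `index_pair`, `index_plus_children`, `all_members`.
#' @export
#' @examples
#' beneficiary_roster()
#' roster_totals(beneficiary_roster())
beneficiary_roster <- function(scale = 1) {
  assert_scalar_number(scale, "scale", min = 0, strict = TRUE)
  r <- tibble::tibble(
    arm = arm_codes(),
    households = round(1260 * scale),
    index_pair = round(c(2353, 2398, 2339) * scale),
    index_plus_children = round(3703 * scale),
    all_members = round(5884 * scale)
  )
  counts <- as.matrix(r[, denominator_codes()])
  if (any(apply(counts, 1, function(x) any(diff(x) <= 0)))) {
    rlang::abort(
      "Roster counts must be strictly increasing across denominators."
    )
  }
  class(r) <- c("nutricost_roster", class(r))
  r
}

#' @rdname beneficiary_roster
#' @export
denominator_codes <- function() {
  c("households", "index_pair", "index_plus_children", "all_members")
}

#' Pooled beneficiary counts
#'
#' @param roster A [beneficiary_roster()].
#' @return Named numeric vector of pooled counts over arms, one per
#'   denominator definition.
#' @export
roster_totals <- function(roster) {
  vapply(denominator_codes(), function(d) sum(roster[[d]]), numeric(1))
}

# Index women (one per household) and spouses per arm, used to value
# beneficiary participation time.
roster_gender_counts <- function(roster) {
  tibble::tibble(
    arm = roster$arm,
    n_women = roster$households,
    n_men = roster$index_pair - roster$households
  )
}
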