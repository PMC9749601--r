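#' Build a cost cube from valued cost cells
#'
#' The cost cube is the central container of the pipeline: a set of valued
#' cells keyed by activity x input x stage x arm x nature (financial or
#' economic), each carrying typology weights that sum to 1. Cells sharing a
#' key are merged by summation (typology weights combined amount-weighted so
#' typology margins are preserved). Margins over any dimension sum to the
#' grand total.
#'
#' @param cells A tibble with columns `activity`, `input`, `stage`, `arm`,
#'   `nature`, `amount` and typology weight columns `w_supply`, `w_demand`,
#'   `w_enabling_environment`. Missing weight columns default to the shared
#'   typology weights.
#' @return A tibble of class `cost_cube`.
#' @export
build_cube <- function(cells) {
  wcols <- paste0("w_", typology_codes())
  if (is.null(cells) || nrow(cells) == 0) {
    empty <- tibble::tibble(
      activity = character(), input = character(), stage = character(),
      arm = character(), nature = character(), amount = numeric()
    )
    for (w in wcols) empty[[w]] <- numeric()
    class(empty) <- c("cost_cube", class(empty))
    return(empty)
  }
  cells <- tibble::as_tibble(cells)
  for (i in seq_along(wcols)) {
    if (!wcols[i] %in% names(cells)) {
      cells[[wcols[i]]] <- unname(default_shared_typology_weights()[i])
    }
  }
  check <- list(
    activity = activity_codes(), input = input_codes(),
    stage = stage_codes(), arm = arm_codes(),
    nature = c("financial", "economic")
  )
  for (nm in names(check)) {
    bad <- setdiff(unique(cells[[nm]]), check[[nm]])
    if (length(bad)) {
      rlang::abort(sprintf("Invalid %s code(s): %s", nm,
                           paste(bad, collapse = ", ")))
    }
  }
  if (any(cells$amount < 0)) {
    rlang::abort("Cost cells must be nonnegative.")
  }
  wsum <- rowSums(cells[, wcols])
  if (any(abs(wsum - 1) > 1e-6)) {
    rlang::abort("Typology weights must sum to 1 in every cell.")
  }
  out <- cells |>
    dplyr::group_by(.data$activity, .data$input, .data$stage, .data$arm,
                    .data$nature) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(wcols),
                    ~ if (sum(.data$amount) > 0) {
                        sum(.x * .data$amount) / sum(.data$amount)
                      } else mean(.x)),
      amount = sum(.data$amount),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("activity", "input", "stage", "arm",
                                  "nature", "amount", wcols)))
  class(out) <- c("cost_cube", class(out))
  out
}

#' @rdname build_cube
#' @param cube A `cost_cube`.
#' @export
cube_total <- function(cube) sum(cube$amount)

#' Margin of a cost cube over one dimension
#'
#' @param cube A `cost_cube`.
#' @param dimension One of `"activity"`, `"input"`, `"stage"`, `"arm"`,
#'   `"nature"`, `"typology"`. The typology margin weights each cell's amount
#'   by its typology shares.
#' @return A tibble with the category column and `amount`.
#' @export
cube_margin <- function(cube, dimension) {
  dimension <- match.arg(
    dimension,
    c("activity", "input", "stage", "arm", "nature", "typology")
  )
  if (dimension == "typology") {
    return(tibble::tibble(
      typology = typology_codes(),
      amount = vapply(
        typology_codes(),
        function(tc) sum(cube$amount * cube[[paste0("w_", tc)]]),
        numeric(1)
      )
    ))
  }
  cube |>
    dplyr::group_by(dplyr::across(dplyr::all_of(dimension))) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
}

#' Cost profile: category shares of total cost
#'
#' The cost profile is each disaggregated category's share of total
#' programme cost; `percent` applies whole-number half-up rounding as in
#' conventional costing reports.
#'
#' @inheritParams cube_margin
#' @return A tibble with the category column, `amount`, `share`, `percent`.
#' @export
cost_profile <- function(cube, dimension) {
  total <- cube_total(cube)
  if (nrow(cube) == 0 || total <= 0) {
    rlang::abort("Cannot profile an empty or zero-total cube.")
  }
  m <- cube_margin(cube, dimension)
  m$share <- m$amount / total
  m$percent <- round_half_up(100 * m$share)
  m
}

#' Unit cost per beneficiary
#'
#' Total cost divided by a pooled beneficiary denominator; `period =
#' "annual"` further divides by the implementation window in years
#' (`months / 12`).
#'
#' @param x A `cost_cube` or a single numeric total cost in 2019 USD.
#' @param roster A [beneficiary_roster()].
#' @param denominator One of [denominator_codes()].
#' @param period `"total"` or `"annual"`.
#' @param months Implementation window in months (default 40).
#' @return A one-row tibble `scope`, `denominator`, `period`, `value`.
#' @export
unit_cost <- function(x, roster, denominator = "households",
                      period = c("annual", "total"), months = 40) {
  period <- match.arg(period)
  denominator <- match.arg(denominator, denominator_codes())
  total <- if (inherits(x, "cost_cube")) cube_total(x) else x
  count <- roster_totals(roster)[[denominator]]
  if (count <= 0) rlang::abort("Denominator count must be positive.")
  value <- total / count
  if (period == "annual") value <- value / (months / 12)
  tibble::tibble(
    scope = "pooled", denominator = denominator, period = period,
    value = value
  )
}

#' @rdname unit_cost
#' @export
unit_cost_table <- function(x, roster, months = 40) {
  dplyr::bind_rows(lapply(denominator_codes(), function(d) {
    dplyr::bind_rows(
      unit_cost(x, roster, d, "total", months),
      unit_cost(x, roster, d, "annual", months)
    )
  }))
}

#' Unit costs by treatment arm
#'
#' Requires an arm-resolved cube. For each arm, total and annual cost per
#' denominator unit using that arm's own counts.
#'
#' @param cube A `cost_cube` with cells allocated to arms.
#' @param roster A [beneficiary_roster()].
#' @param months Implementation window in months.
#' @return A tibble `arm`, `denominator`, `total`, `annual`.
#' @export
arm_unit_costs <- function(cube, roster, months = 40) {
  m <- cube_margin(cube, "arm")
  missing_arms <- setdiff(arm_codes(), m$arm)
  if (length(missing_arms)) {
    rlang::abort(paste0("Cube lacks cells for arm(s): ",
                        paste(missing_arms, collapse = ", ")))
  }
  tidyr::expand_grid(arm = arm_codes(), denominator = denominator_codes()) |>
    dplyr::mutate(
      total = m$amount[match(.data$arm, m$arm)] /
        unname(mapply(function(a, d) roster[[d]][match(a, roster$arm)],
                      .data$arm, .data$denominator)),
      annual = .data$total / (months / 12)
    )
}

#' Margin report in the style of a programme costing summary table
#'
#' Three panels (input, stage, activity), each with financial, economic and
#' total 2019-USD costs and the whole-percent cost profile.
#'
#' @param cube A `cost_cube`.
#' @return A tibble `panel`, `category`, `financial`, `economic`, `total`,
#'   `percent`.
#' @export
margin_report <- function(cube) {
  grand <- cube_total(cube)
  one_panel <- function(dim, levels) {
    m <- cube |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(dim, "nature")))) |>
      dplyr::summarise(amount = sum(.data$amount), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "nature", values_from = "amount",
                         values_fill = 0)
    for (col in c("financial", "economic")) {
      if (!col %in% names(m)) m[[col]] <- 0
    }
    m <- m[match(levels, m[[dim]]), ]
    m[[dim]] <- levels
    m$financial[is.na(m$financial)] <- 0
    m$economic[is.na(m$economic)] <- 0
    tibble::tibble(
      panel = dim, category = m[[dim]],
      financial = m$financial, economic = m$economic,
      total = m$financial + m$economic,
      percent = if (grand > 0) {
        round_half_up(100 * (m$financial + m$economic) / grand)
      } else 0
    )
  }
  dplyr::bind_rows(
    one_panel("input", input_codes()),
    one_panel("stage", stage_codes()),
    one_panel("activity", activity_codes())
  )
}
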