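# File-based entry points tying the pipeline stages into reproducible runs.
# Data go to files, log messages to stderr; money is serialized as 2-decimal
# strings in CSV and at full precision in JSON.

money_fmt <- function(x) formatC(x, format = "f", digits = 2)

write_report_pair <- function(df, stem, out_dir, money_cols) {
  csv <- df
  for (col in intersect(money_cols, names(csv))) {
    csv[[col]] <- money_fmt(csv[[col]])
  }
  csv_path <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(csv, csv_path, row.names = FALSE)
  json_path <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  c(csv_path, json_path)
}

write_manifest <- function(out_dir, inputs = character(), outputs, seed = NULL,
                           config_hash = NULL) {
  manifest <- list(
    artifact = "nutricost",
    version = as.character(utils::packageVersion("nutricost")),
    created_utc = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ"),
    seed = seed,
    config_hash = config_hash,
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else NULL,
    outputs = basename(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

hash_config <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_to_list(config), tmp)
  unname(tools::md5sum(tmp))
}

# costing_config <-> plain list (for YAML round trips)
config_to_list <- function(costing) {
  out <- unclass(costing)
  out$params <- unclass(out$params)
  out$params$inflation_index <- as.list(out$params$inflation_index)
  for (f in c("economic_activity_shares", "shared_scope_weights",
              "nutrition_gender_split", "typology_shared_weights",
              "wages_bdt")) {
    out[[f]] <- as.list(out[[f]])
  }
  out$profiles <- lapply(out$profiles, function(p) {
    p$activity_shares <- as.list(p$activity_shares)
    p
  })
  out$rules$input_activity <- as.list(out$rules$input_activity)
  out$rules$keywords <- as.list(as.data.frame(out$rules$keywords))
  out
}

config_from_list <- function(lst) {
  unmap <- function(x) {
    if (is.null(x)) return(NULL)
    stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  params <- do.call(valuation_params, c(
    lst$params[setdiff(names(lst$params), "inflation_index")],
    list(inflation_index = unmap(lst$params$inflation_index))
  ))
  profiles <- lapply(lst$profiles, function(p) {
    p$activity_shares <- unmap(p$activity_shares)
    p
  })
  rules <- lst$rules %||% default_coding_rules()
  if (!is.null(rules$input_activity)) {
    rules$input_activity <- stats::setNames(
      vapply(rules$input_activity, as.character, character(1)),
      names(rules$input_activity)
    )
  }
  if (!is.null(rules$keywords)) {
    rules$keywords <- as.data.frame(lapply(rules$keywords, unlist),
                                    stringsAsFactors = FALSE)
  }
  costing_config(
    params = params, rules = rules, profiles = profiles,
    time_rate = lst$time_rate, oop_scale = lst$oop_scale,
    wage_scale = lst$wage_scale,
    economic_activity_shares = unmap(lst$economic_activity_shares),
    shared_scope_weights = unmap(lst$shared_scope_weights),
    nutrition_gender_split = unmap(lst$nutrition_gender_split),
    typology_shared_weights = unmap(lst$typology_shared_weights),
    wages_bdt = unmap(lst$wages_bdt),
    months = lst$months, n_pk = lst$n_pk, seed = lst$seed
  )
}

#' Read a ledger CSV
#'
#' @param path Path to a UTF-8 ledger CSV with the standard header (see
#'   [validate_ledger()]).
#' @return A validated ledger tibble.
#' @export
read_ledger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(entry_id = "character"))
  validate_ledger(df)
}

#' Full costing run from files
#'
#' Reads a ledger CSV (plus optional survey CSVs and a YAML run
#' configuration), executes [run_costing()], and writes `table1`
#' (margin report), `unit_costs` and `arm_costs` as CSV + JSON pairs with a
#' run manifest recording input digests, seed and configuration hash.
#'
#' @param ledger_path Ledger CSV path.
#' @param out_dir Output directory (created if needed).
#' @param config_path Optional YAML configuration (defaults to
#'   [costing_config()] defaults).
#' @param worker_survey_path,beneficiary_timeuse_path Optional survey CSVs;
#'   omitted surveys make the run financial-only.
#' @param roster_path Optional roster CSV (`arm` + the four denominator
#'   columns); defaults to [beneficiary_roster()].
#' @param quiet Suppress progress messages.
#' @return The [run_costing()] result, invisibly.
#' @export
costing_run <- function(ledger_path, out_dir, config_path = NULL,
                        worker_survey_path = NULL,
                        beneficiary_timeuse_path = NULL,
                        roster_path = NULL, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  costing <- if (is.null(config_path)) {
    costing_config()
  } else {
    config_from_list(yaml::read_yaml(config_path))
  }
  ledger <- read_ledger_csv(ledger_path)
  say(sprintf("Read %d ledger entries from %s", nrow(ledger), ledger_path))
  roster <- if (is.null(roster_path)) {
    beneficiary_roster()
  } else {
    r <- utils::read.csv(roster_path, stringsAsFactors = FALSE)
    r$arm <- as.character(r$arm)
    class(r) <- c("nutricost_roster", class(tibble::as_tibble(r)))
    tibble::as_tibble(r)
  }
  ws <- if (is.null(worker_survey_path)) NULL else {
    utils::read.csv(worker_survey_path, stringsAsFactors = FALSE)
  }
  bt <- if (is.null(beneficiary_timeuse_path)) NULL else {
    utils::read.csv(beneficiary_timeuse_path, stringsAsFactors = FALSE)
  }
  res <- run_costing(ledger, costing, roster, ws, bt)
  outputs <- c(
    write_report_pair(res$table, "table1", out_dir,
                      c("financial", "economic", "total")),
    if (!is.null(res$unit_costs)) {
      write_report_pair(res$unit_costs, "unit_costs", out_dir, "value")
    },
    if (!is.null(res$arm_costs)) {
      write_report_pair(res$arm_costs, "arm_costs", out_dir,
                        c("total", "annual"))
    }
  )
  inputs <- c(ledger_path, config_path, worker_survey_path,
              beneficiary_timeuse_path, roster_path)
  write_manifest(out_dir, inputs = inputs[!vapply(inputs, is.null,
                                                  logical(1))],
                 outputs = outputs, seed = costing$seed,
                 config_hash = hash_config(costing))
  say(sprintf("Wrote %d report files to %s", length(outputs), out_dir))
  invisible(res)
}

#' Write a synthetic input bundle to disk
#'
#' Materializes [generate_inputs()] as plain-text files — `ledger.csv`,
#' `worker_survey.csv`, `beneficiary_timeuse.csv`, `roster.csv`,
#' `costing.yaml` — that round-trip through [costing_run()].
#'
#' @param out_dir Output directory.
#' @param config A [synth_config()].
#' @param quiet Suppress progress messages.
#' @return The generated `costing_inputs` bundle, invisibly.
#' @export
costing_synth <- function(out_dir, config = synth_config(), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- generate_inputs(config)
  paths <- c(
    ledger = file.path(out_dir, "ledger.csv"),
    worker_survey = file.path(out_dir, "worker_survey.csv"),
    beneficiary_timeuse = file.path(out_dir, "beneficiary_timeuse.csv"),
    roster = file.path(out_dir, "roster.csv")
  )
  utils::write.csv(inputs$ledger, paths[["ledger"]], row.names = FALSE,
                   na = "")
  utils::write.csv(inputs$worker_survey, paths[["worker_survey"]],
                   row.names = FALSE)
  utils::write.csv(inputs$beneficiary_timeuse,
                   paths[["beneficiary_timeuse"]], row.names = FALSE)
  utils::write.csv(inputs$roster, paths[["roster"]], row.names = FALSE)
  config_path <- file.path(out_dir, "costing.yaml")
  yaml::write_yaml(config_to_list(inputs$costing), config_path,
                   precision = 15)
  write_manifest(out_dir, outputs = c(paths, config_path),
                 seed = config$seed, config_hash = hash_config(inputs$costing))
  if (!quiet) {
    message(sprintf("Wrote synthetic inputs (%d ledger entries) to %s",
                    nrow(inputs$ledger), out_dir))
  }
  invisible(inputs)
}

#' Probabilistic sensitivity analysis run
#'
#' Builds the cost model from a pipeline run (by default a fresh synthetic
#' run at the given seed), executes the Monte Carlo PSA and the tornado
#' analysis, and writes `psa.csv` and `tornado.csv` (with the seed recorded
#' in every file and the manifest).
#'
#' @param out_dir Output directory.
#' @param n_sims Number of simulations (default 5000).
#' @param seed Integer seed for both the synthetic inputs and the PSA.
#' @param inputs Optional `costing_inputs` bundle to analyse instead of a
#'   synthetic default.
#' @param quiet Suppress progress messages.
#' @return A list with `psa` and `tornado` results, invisibly.
#' @export
costing_psa <- function(out_dir, n_sims = 5000, seed = 1L, inputs = NULL,
                        quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputs)) inputs <- generate_inputs(synth_config(seed = seed))
  res <- run_costing(inputs)
  model <- build_cost_model(res$totals[["financial"]], inputs$costing,
                            inputs$roster)
  psa <- run_psa(model, n_sims = n_sims, seed = seed)
  tor <- tornado(model)
  psa_df <- psa$summary
  psa_df$n_sims <- n_sims
  psa_df$seed <- seed
  tor_df <- tor
  tor_df$seed <- seed
  outputs <- c(
    write_report_pair(psa_df, "psa", out_dir,
                      c("base_case", "sim_mean", "lower", "upper")),
    write_report_pair(tor_df, "tornado", out_dir,
                      c("outcome_low", "outcome_high", "swing"))
  )
  write_manifest(out_dir, outputs = outputs, seed = seed,
                 config_hash = hash_config(inputs$costing))
  if (!quiet) {
    message(sprintf("PSA (%d simulations, seed %d) written to %s",
                    n_sims, seed, out_dir))
  }
  invisible(list(psa = psa, tornado = tor))
}
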