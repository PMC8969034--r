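# Parameter-file layout: one JSON config (schema_version 1) holding scalars
# and the treatment map, referencing three CSV tables (dot decimals, header
# row) that sit next to it:
#   transition_matrix.csv  p0..p9, one row per origin EDSS 0-9
#   life_table.csv         age, q_male, q_female, ex_male, ex_female
#   valuation.csv          one row per EDSS 0-9, see state_valuation()
# Numbers are written with full (17 significant digit) precision so that a
# load -> write -> load round trip is exact.

PARAMS_SCHEMA_VERSION <- 1L

fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

write_numeric_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    out[[j]] <- if (is.numeric(out[[j]])) fmt_num(out[[j]]) else as.character(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a parameter set to its on-disk layout
#'
#' Serialises a [parameter_set()] as a JSON config plus three CSV tables in
#' `dir`. The layout is symmetric with [load_parameter_set()]; synthetic and
#' externally supplied inputs are interchangeable through it.
#'
#' @param params a `parameter_set`.
#' @param dir directory to write into (created if missing).
#' @return the path of the written config file, invisibly usable with
#'   [load_parameter_set()].
#' @export
write_parameter_set <- function(params, dir) {
  stopifnot(inherits(params, "parameter_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  tm <- as.data.frame(params$natural_history$transition_matrix)
  names(tm) <- paste0("p", EDSS_STATES)
  write_numeric_csv(tm, file.path(dir, "transition_matrix.csv"))
  write_numeric_csv(params$mortality$life_table, file.path(dir, "life_table.csv"))
  write_numeric_csv(params$valuation$table, file.path(dir, "valuation.csv"))

  cfg <- list(
    schema_version = PARAMS_SCHEMA_VERSION,
    files = list(
      transition_matrix = "transition_matrix.csv",
      life_table = "life_table.csv",
      valuation = "valuation.csv"
    ),
    baseline = params$baseline[c("edss_distribution", "start_age", "male_fraction", "cohort_size")],
    arr_by_edss = params$natural_history$arr_by_edss,
    treatments = lapply(unname(params$treatments), function(tr) {
      tr[c("name", "hr_progression", "rr_relapse",
           "annual_drug_cost_year1", "annual_drug_cost_subsequent")]
    }),
    mortality = list(ms_hazard_ratio = params$mortality$ms_hazard_ratio),
    economics = unclass(params$economics)
  )
  path <- file.path(dir, "parameters.json")
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

read_table_file <- function(dir, rel, what, problems) {
  path <- file.path(dir, rel)
  if (!file.exists(path)) {
    problems$add(sprintf("%s: referenced file '%s' not found", what, rel))
    return(NULL)
  }
  utils::read.csv(path, check.names = FALSE)
}

#' Load and validate a parameter set from disk
#'
#' Reads the JSON config written by [write_parameter_set()] (or assembled by
#' hand to the same schema), resolves its CSV table references relative to
#' the config's directory, and validates every model invariant. All schema
#' and invariant violations are collected and reported in one error, not
#' just the first.
#'
#' @param path path to the JSON config file.
#' @return a validated [parameter_set()].
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file '%s' does not exist", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dir <- dirname(path)

  bag <- new.env(parent = emptyenv())
  bag$msgs <- character()
  problems <- list(add = function(msg) bag$msgs <- c(bag$msgs, msg))

  sv <- cfg$schema_version
  if (is.null(sv)) problems$add("config: missing field 'schema_version'")
  else if (!identical(as.integer(sv), PARAMS_SCHEMA_VERSION)) {
    problems$add(sprintf("config: unsupported schema_version %s (expected %d)", sv, PARAMS_SCHEMA_VERSION))
  }
  for (f in c("files", "baseline", "arr_by_edss", "treatments", "mortality", "economics")) {
    if (is.null(cfg[[f]])) problems$add(sprintf("config: missing field '%s'", f))
  }
  if (length(bag$msgs)) stop_on_violations(bag$msgs)

  for (f in c("transition_matrix", "life_table", "valuation")) {
    if (is.null(cfg$files[[f]])) problems$add(sprintf("config$files: missing entry '%s'", f))
  }
  for (f in c("edss_distribution", "start_age", "male_fraction", "cohort_size")) {
    if (is.null(cfg$baseline[[f]])) problems$add(sprintf("config$baseline: missing field '%s'", f))
  }
  if (is.null(cfg$mortality$ms_hazard_ratio)) problems$add("config$mortality: missing field 'ms_hazard_ratio'")
  econ_fields <- c("discount_rate_costs", "discount_rate_effects", "annual_relapse_cost",
                   "retirement_age", "horizon_years", "discontinuation_edss_threshold")
  for (f in econ_fields) {
    if (is.null(cfg$economics[[f]])) problems$add(sprintf("config$economics: missing field '%s'", f))
  }
  if (length(bag$msgs)) stop_on_violations(bag$msgs)

  tm_df <- read_table_file(dir, cfg$files$transition_matrix, "transition_matrix", problems)
  lt_df <- read_table_file(dir, cfg$files$life_table, "life_table", problems)
  val_df <- read_table_file(dir, cfg$files$valuation, "valuation", problems)
  if (length(bag$msgs)) stop_on_violations(bag$msgs)

  tm_cols <- paste0("p", EDSS_STATES)
  if (!all(tm_cols %in% names(tm_df))) {
    problems$add(sprintf("transition_matrix file: expected columns %s", paste(tm_cols, collapse = ", ")))
    stop_on_violations(bag$msgs)
  }

  treatments_df <- cfg$treatments
  tr_fields <- c("name", "hr_progression", "rr_relapse",
                 "annual_drug_cost_year1", "annual_drug_cost_subsequent")
  if (is.data.frame(treatments_df)) {
    miss <- setdiff(tr_fields, names(treatments_df))
    if (length(miss)) {
      problems$add(sprintf("config$treatments: missing field(s) %s", paste(miss, collapse = ", ")))
      stop_on_violations(bag$msgs)
    }
    treatments <- lapply(seq_len(nrow(treatments_df)), function(i) {
      do.call(new_treatment_effect, as.list(treatments_df[i, tr_fields]))
    })
  } else {
    treatments <- lapply(treatments_df, function(tr) {
      miss <- setdiff(tr_fields, names(tr))
      if (length(miss)) {
        problems$add(sprintf("config$treatments: missing field(s) %s", paste(miss, collapse = ", ")))
        return(NULL)
      }
      do.call(new_treatment_effect, tr[tr_fields])
    })
    if (length(bag$msgs)) stop_on_violations(bag$msgs)
  }
  names(treatments) <- vapply(treatments, `[[`, "", "name")

  x <- new_parameter_set(
    baseline = new_baseline_cohort(cfg$baseline$edss_distribution,
                                   cfg$baseline$start_age,
                                   cfg$baseline$male_fraction,
                                   cfg$baseline$cohort_size),
    natural_history = new_natural_history(as.matrix(tm_df[, tm_cols]), cfg$arr_by_edss),
    treatments = treatments,
    mortality = new_mortality_model(lt_df, cfg$mortality$ms_hazard_ratio),
    valuation = new_state_valuation(val_df),
    economics = do.call(new_economic_settings, cfg$economics[econ_fields])
  )
  stop_on_violations(validate_parameter_set(x))
  x$natural_history$transition_matrix <- renormalize_rows(x$natural_history$transition_matrix)
  x
}
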