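# Four-scenario comparison bundle and on-disk report writers.

#' Run and compare the built-in treatment-sequencing scenarios
#'
#' Runs each scenario (by default the four built-in ones against the chosen
#' comparator), computes the outcome and cost reports, and tabulates them
#' side by side with delta columns against the reference scenario
#' (by convention the immediate-OMB scenario, the first in the list).
#'
#' @param params a [parameter_set()].
#' @param comparator `"DMF"` or `"GA"`; ignored if `scenarios` is given.
#' @param scenarios named list of [scenario_spec()] objects (default:
#'   [builtin_scenarios()] at the parameter set's horizon).
#' @param reference index or name of the reference scenario for deltas
#'   (default the first).
#' @return an object of class `cca_comparison`: traces, per-scenario
#'   `outcome_report` and `cost_report` objects, an `outcomes` table
#'   (metric x scenario with `delta_` columns), a `costs` table, a cost
#'   `shares` table, and matrices `mean_edss_by_year` (year x scenario)
#'   and `years_in_band` (band x scenario).
#' @export
cca_compare <- function(params, comparator = c("DMF", "GA"),
                        scenarios = NULL, reference = 1L) {
  stopifnot(inherits(params, "parameter_set"))
  comparator <- match.arg(comparator)
  if (is.null(scenarios)) {
    scenarios <- builtin_scenarios(comparator, params$economics$horizon_years)
  }
  traces <- lapply(scenarios, function(s) run_scenario(params, s))
  outs <- lapply(traces, outcome_report, params = params)
  costs <- lapply(traces, cost_report, params = params)
  ref <- if (is.character(reference)) match(reference, names(scenarios)) else as.integer(reference)
  if (is.na(ref) || ref < 1L || ref > length(scenarios)) stop("invalid reference scenario")

  outcome_row <- function(o) {
    c(mild_pct = 100 * unname(o$band_shares["mild"]),
      walking_aid_pct = 100 * unname(o$band_shares["walking_aid"]),
      wheelchair_pct = 100 * unname(o$band_shares["wheelchair"]),
      bedridden_pct = 100 * unname(o$band_shares["bedridden"]),
      immobile_pct = 100 * unname(o$band_shares["immobile"]),
      mean_edss = unname(o$mean_edss_by_year[length(o$mean_edss_by_year)]),
      dalys = o$daly, yld = o$yld, yll = o$yll,
      relapses = o$total_relapses,
      informal_care_days = o$informal_care_days,
      employed_pct = 100 * o$employed,
      fulltime_pct = 100 * o$fulltime,
      invalidity_pct = 100 * o$invalidity)
  }
  om <- vapply(outs, outcome_row, outcome_row(outs[[1L]]))
  outcomes <- data.frame(metric = rownames(om), om, check.names = FALSE,
                         row.names = NULL)
  for (j in seq_along(scenarios)) {
    if (j == ref) next
    outcomes[[paste0("delta_", names(scenarios)[j])]] <- om[, j] - om[, ref]
  }

  cost_row <- function(cr) {
    c(cr$direct,
      sum_direct = cr$direct_subtotal,
      cr$indirect,
      sum_indirect = cr$indirect_subtotal,
      sum_direct_indirect = cr$direct_plus_indirect,
      relapse_costs = cr$relapse_costs,
      total = cr$total)
  }
  cm <- vapply(costs, cost_row, cost_row(costs[[1L]]))
  cost_tab <- data.frame(category = rownames(cm), cm, check.names = FALSE,
                         row.names = NULL)
  for (j in seq_along(scenarios)) {
    if (j == ref) next
    cost_tab[[paste0("delta_pct_", names(scenarios)[j])]] <-
      100 * (cm[, j] - cm[, ref]) / ifelse(cm[, ref] != 0, cm[, ref], NA)
  }

  share_row <- function(cr) {
    c(cr$shares$direct,
      sum_direct = cr$shares$direct_subtotal,
      cr$shares$indirect,
      sum_indirect = cr$shares$indirect_subtotal,
      relapse_costs = cr$shares$relapse)
  }
  sm <- vapply(costs, share_row, share_row(costs[[1L]]))
  shares <- data.frame(category = rownames(sm), sm, check.names = FALSE,
                       row.names = NULL)

  mean_edss_by_year <- vapply(outs, `[[`, outs[[1L]]$mean_edss_by_year,
                              "mean_edss_by_year")
  rownames(mean_edss_by_year) <- 0:(nrow(mean_edss_by_year) - 1L)
  yib <- vapply(outs, `[[`, outs[[1L]]$years_in_band, "years_in_band")

  structure(
    list(scenarios = scenarios, reference = names(scenarios)[ref],
         traces = traces, outcome_reports = outs, cost_reports = costs,
         outcomes = outcomes, costs = cost_tab, shares = shares,
         mean_edss_by_year = mean_edss_by_year, years_in_band = yib,
         comparator = comparator),
    class = "cca_comparison"
  )
}

#' @export
print.cca_comparison <- function(x, ...) {
  cat(sprintf("<cca_comparison> %d scenarios (reference: %s)\n",
              length(x$scenarios), x$reference))
  for (s in x$scenarios) cat("  - ", s$label, "\n", sep = "")
  cat("\nOutcomes (absolute values per scenario):\n")
  print(format_num_df(x$outcomes), row.names = FALSE)
  invisible(x)
}

#' @export
summary.cca_comparison <- function(object, ...) {
  cat(sprintf("Cost-consequence comparison vs %s, reference scenario %s\n\n",
              object$comparator, object$reference))
  cat("Outcomes:\n")
  print(format_num_df(object$outcomes), row.names = FALSE)
  cat("\nDiscounted costs per patient:\n")
  print(format_num_df(object$costs), row.names = FALSE)
  cat("\nCost shares (% of subtotal / of direct+indirect):\n")
  print(format_num_df(object$shares), row.names = FALSE)
  invisible(object)
}

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], 2)
  }
  df
}

#' Plot mean EDSS trajectories of a comparison
#'
#' One line per scenario, the shape of the mean-EDSS-over-time figure of a
#' treatment-sequencing comparison.
#'
#' @param x a `cca_comparison`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cca_comparison <- function(x, ...) {
  m <- x$mean_edss_by_year
  graphics::matplot(as.integer(rownames(m)), m, type = "b", pch = 16, lty = 1,
                    xlab = "Year", ylab = "Mean EDSS (survivors)", ...)
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   pch = 16, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a comparison bundle to disk
#'
#' Writes, under `dir`: per-scenario tidy traces and per-cycle summaries,
#' the outcome, cost and share tables, the mean-EDSS-by-year and
#' years-in-band series, and a JSON run manifest (package version, an MD5
#' hash over the serialised parameter inputs, scenario labels, file list).
#' Identical inputs produce byte-identical numeric outputs.
#'
#' @param comparison a [cca_compare()] result.
#' @param dir output directory (created if missing).
#' @param params the parameter set the comparison was run with (hashed into
#'   the manifest; optional).
#' @param format `"csv"`, `"json"`, or both.
#' @return invisibly, the manifest as a list.
#' @export
write_cca <- function(comparison, dir, params = NULL, format = c("csv", "json")) {
  stopifnot(inherits(comparison, "cca_comparison"))
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  emit <- function(obj, stem) {
    if ("csv" %in% format) {
      f <- file.path(dir, paste0(stem, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE)
      files <<- c(files, basename(f))
    }
    if ("json" %in% format) {
      f <- file.path(dir, paste0(stem, ".json"))
      jsonlite::write_json(obj, f, dataframe = "rows", digits = NA, pretty = TRUE)
      files <<- c(files, basename(f))
    }
  }
  safe_stem <- function(nm) gsub("[^A-Za-z0-9]+", "_", nm)
  for (nm in names(comparison$traces)) {
    tr <- comparison$traces[[nm]]
    emit(as.data.frame(tr), paste0("trace_", safe_stem(nm)))
    emit(trace_summary(tr), paste0("summary_", safe_stem(nm)))
  }
  emit(comparison$outcomes, "outcomes")
  emit(comparison$costs, "costs")
  emit(comparison$shares, "cost_shares")
  emit(data.frame(year = as.integer(rownames(comparison$mean_edss_by_year)),
                  comparison$mean_edss_by_year, check.names = FALSE),
       "mean_edss_by_year")
  emit(data.frame(band = rownames(comparison$years_in_band),
                  comparison$years_in_band, check.names = FALSE),
       "years_in_band")

  param_hash <- NA_character_
  if (!is.null(params)) {
    tmp <- tempfile("params")
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    write_parameter_set(params, tmp)
    hashes <- tools::md5sum(sort(list.files(tmp, full.names = TRUE)))
    param_hash <- unname(tools::md5sum(textConnection2file(paste(hashes, collapse = ""))))
  }
  manifest <- list(
    package = "mscca",
    version = as.character(utils::packageVersion("mscca")),
    reference = comparison$reference,
    comparator = comparison$comparator,
    scenarios = vapply(comparison$scenarios, `[[`, "", "label"),
    parameter_hash = param_hash,
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# hash helper: md5 of a string via a temp file (tools::md5sum is file-based)
textConnection2file <- function(txt) {
  f <- tempfile("hash")
  writeLines(txt, f)
  f
}

#' Run a sensitivity analysis and write tornado files
#'
#' Convenience wrapper around [univariate_sensitivity()] that writes the
#' tornado table as CSV and plot-ready JSON.
#'
#' @param params a [parameter_set()].
#' @param dir output directory.
#' @param reference,comparator [scenario_spec()] objects; default the
#'   immediate-OMB and no-switch built-ins against `comparator_name`.
#' @param comparator_name `"DMF"` or `"GA"` used for the default scenarios.
#' @param factors factor names (default [sensitivity_factors()]); an empty
#'   vector yields an empty table.
#' @param metric metric function, see [univariate_sensitivity()].
#' @return the `tornado` data frame, invisibly.
#' @export
run_sensitivity <- function(params, dir, reference = NULL, comparator = NULL,
                            comparator_name = c("DMF", "GA"),
                            factors = sensitivity_factors(),
                            metric = incremental_total_cost) {
  comparator_name <- match.arg(comparator_name)
  if (is.null(reference) || is.null(comparator)) {
    sc <- builtin_scenarios(comparator_name, params$economics$horizon_years)
    if (is.null(reference)) reference <- sc[[1L]]
    if (is.null(comparator)) comparator <- sc[[length(sc)]]
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (length(factors) == 0L) {
    tor <- data.frame(factor = character(), low = numeric(), base = numeric(),
                      high = numeric(), range = numeric(), clamped = logical())
    class(tor) <- c("tornado", "data.frame")
  } else {
    tor <- univariate_sensitivity(params, reference, comparator,
                                  metric = metric, factors = factors)
  }
  utils::write.csv(tor, file.path(dir, "tornado.csv"), row.names = FALSE)
  jsonlite::write_json(tor, file.path(dir, "tornado.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(tor)
}
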