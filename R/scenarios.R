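# Treatment-sequencing scenarios: ordered (treatment, duration) segments
# over the simulation horizon. Switches happen exactly at cycle boundaries.

#' Define a treatment-sequencing scenario
#'
#' @param label human-readable scenario name.
#' @param segments data frame with columns `treatment` (character) and
#'   `duration` (positive integer years), applied in order; or a list of
#'   `list(treatment, duration)` pairs.
#' @param horizon total horizon in years; segment durations must sum to it.
#' @return an object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("late switch", data.frame(
#'   treatment = c("DMF", "OMB"), duration = c(5, 5)), horizon = 10)
scenario_spec <- function(label, segments, horizon) {
  if (!is.data.frame(segments)) {
    segments <- data.frame(
      treatment = vapply(segments, function(s) as.character(s$treatment %||% s[[1]]), ""),
      duration = vapply(segments, function(s) as.numeric(s$duration %||% s[[2]]), 0)
    )
  }
  stopifnot(all(c("treatment", "duration") %in% names(segments)))
  dur <- segments$duration
  if (any(!is.finite(dur)) || any(dur <= 0) || any(dur != round(dur))) {
    stop("segment durations must be positive whole years")
  }
  horizon <- as.integer(horizon)
  if (sum(dur) != horizon) {
    stop(sprintf("segment durations sum to %g, not the %d-year horizon", sum(dur), horizon))
  }
  structure(
    list(label = as.character(label),
         segments = data.frame(treatment = as.character(segments$treatment),
                               duration = as.integer(dur)),
         horizon = horizon),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  seq_txt <- paste(sprintf("%s x %dy", x$segments$treatment, x$segments$duration),
                   collapse = " -> ")
  cat(sprintf("<scenario_spec> %s: %s (horizon %d y)\n", x$label, seq_txt, x$horizon))
  invisible(x)
}

#' The four built-in treatment-sequencing scenarios
#'
#' The comparison grid of the analysis: immediate high-efficacy treatment
#' (OMB for the whole horizon, "10/0"), an early switch after 1 year on the
#' comparator ("1/9"), a late switch after 5 years ("5/5"), and the
#' comparator for the whole horizon ("0/10"). The x/y tag gives years of OMB
#' before / comparator years. For horizons other than 10 the switch times
#' stay at 1 and 5 years.
#'
#' @param comparator the standard DMT arm, `"DMF"` or `"GA"`.
#' @param horizon horizon in years (default 10; must exceed 5).
#' @return named list of four [scenario_spec()] objects, names
#'   `"10/0"`, `"1/9"`, `"5/5"`, `"0/10"`.
#' @export
builtin_scenarios <- function(comparator = c("DMF", "GA"), horizon = 10) {
  comparator <- match.arg(comparator)
  horizon <- as.integer(horizon)
  if (horizon <= 5L) stop("built-in scenarios need a horizon of more than 5 years")
  seg <- function(trt, dur) data.frame(treatment = trt, duration = dur)
  out <- list(
    scenario_spec(sprintf("Base-Scenario (%d/0): OMB", horizon),
                  seg("OMB", horizon), horizon),
    scenario_spec(sprintf("Scenario A (1/%d): %s then OMB", horizon - 1L, comparator),
                  seg(c(comparator, "OMB"), c(1L, horizon - 1L)), horizon),
    scenario_spec(sprintf("Scenario B (5/%d): %s then OMB", horizon - 5L, comparator),
                  seg(c(comparator, "OMB"), c(5L, horizon - 5L)), horizon),
    scenario_spec(sprintf("Base-Scenario (0/%d): %s", horizon, comparator),
                  seg(comparator, horizon), horizon)
  )
  names(out) <- c(sprintf("%d/0", horizon), sprintf("1/%d", horizon - 1L),
                  sprintf("5/%d", horizon - 5L), sprintf("0/%d", horizon))
  out
}

#' Treatment in force during a given cycle
#'
#' Segment boundaries are half-open `[start, end)`: with segments DMF x 1y
#' then OMB x 9y, cycle 0 is on DMF and cycles 1-9 on OMB.
#'
#' @param spec a [scenario_spec()].
#' @param cycle zero-based cycle index, `0 <= cycle < horizon`.
#' @return the treatment name active during `[cycle, cycle + 1)`.
#' @export
active_treatment <- function(spec, cycle) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(cycle) != 1L || is.na(cycle) || cycle < 0 || cycle >= spec$horizon) {
    stop(sprintf("cycle must lie in [0, %d)", spec$horizon))
  }
  ends <- cumsum(spec$segments$duration)
  spec$segments$treatment[which(cycle < ends)[1L]]
}

# Start cycle of the contiguous run of the active treatment containing each
# cycle 0..horizon-1; used to price a drug's first year ("year 1" tier)
# after a switch.
treatment_run_starts <- function(spec) {
  active <- vapply(seq_len(spec$horizon) - 1L, function(t) active_treatment(spec, t), "")
  starts <- integer(spec$horizon)
  for (t in seq_len(spec$horizon)) {
    starts[t] <- if (t > 1L && active[t] == active[t - 1L]) starts[t - 1L] else t - 1L
  }
  list(active = active, run_start = starts)
}
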