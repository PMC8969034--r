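# One-way (tornado) sensitivity analysis: each factor is scaled by 0.9 and
# 1.1 in turn, everything else held at base, and both scenarios of the
# comparison are rerun.

#' The default sensitivity factor list
#'
#' The nine factors of the base-case tornado: the OMB acquisition cost in
#' year 1, in year 2, and from year 2 onwards (the price schedule has two
#' tiers, so the latter two both act on the subsequent-year price), the
#' 6-CDP hazard ratio of OMB, cohort size, age, gender (male fraction),
#' the discount rates (costs and effects jointly), and the annual relapse
#' cost.
#'
#' @return character vector of factor names accepted by
#'   [univariate_sensitivity()].
#' @export
sensitivity_factors <- function() {
  c("omb_cost_year1", "omb_cost_year2", "omb_cost_subsequent",
    "hr_6cdp", "cohort_size", "age", "gender", "discount_rates",
    "relapse_cost")
}

# Returns the perturbed parameter set; clamping (e.g. a male fraction
# pushed above 1) is recorded in attr(, "clamped").
perturb_parameter_set <- function(params, factor, mult) {
  clamped <- FALSE
  p <- params
  switch(factor,
    omb_cost_year1 = {
      p$treatments$OMB$annual_drug_cost_year1 <-
        p$treatments$OMB$annual_drug_cost_year1 * mult
    },
    omb_cost_year2 = ,
    omb_cost_subsequent = {
      p$treatments$OMB$annual_drug_cost_subsequent <-
        p$treatments$OMB$annual_drug_cost_subsequent * mult
    },
    hr_6cdp = {
      # the factor list is intervention-centric (like the OMB price tiers),
      # so this moves the intervention's progression hazard ratio
      p$treatments$OMB$hr_progression <- p$treatments$OMB$hr_progression * mult
    },
    cohort_size = {
      p$baseline$cohort_size <- p$baseline$cohort_size * mult
    },
    age = {
      p$baseline$start_age <- p$baseline$start_age * mult
    },
    gender = {
      mf <- p$baseline$male_fraction * mult
      if (mf > 1 || mf < 0) {
        clamped <- TRUE
        mf <- min(1, max(0, mf))
      }
      p$baseline$male_fraction <- mf
    },
    discount_rates = {
      p$economics$discount_rate_costs <- p$economics$discount_rate_costs * mult
      p$economics$discount_rate_effects <- p$economics$discount_rate_effects * mult
    },
    relapse_cost = {
      p$economics$annual_relapse_cost <- p$economics$annual_relapse_cost * mult
    },
    stop(sprintf("unknown sensitivity factor '%s'", factor))
  )
  attr(p, "clamped") <- clamped
  p
}

#' Incremental discounted total cost between two scenarios
#'
#' The default tornado metric: total societal cost (direct + indirect +
#' relapse, discounted) of the comparator scenario minus that of the
#' reference scenario.
#'
#' @param params a [parameter_set()].
#' @param reference,comparator [scenario_spec()] objects.
#' @return currency per patient (comparator minus reference).
#' @export
incremental_total_cost <- function(params, reference, comparator) {
  cost_report(run_scenario(params, comparator), params)$total -
    cost_report(run_scenario(params, reference), params)$total
}

#' One-way sensitivity analysis (tornado)
#'
#' Recomputes a scenario-comparison metric with each factor scaled to 90%
#' and 110% of its base value, all other inputs held at base, and returns
#' the results ordered by descending range. Deterministic: the model has
#' no stochastic component, so perturbing and restoring a factor
#' reproduces the base value exactly.
#'
#' @param params a [parameter_set()].
#' @param reference,comparator [scenario_spec()] objects defining the
#'   comparison (reference defaults to the immediate-OMB convention of the
#'   reports).
#' @param metric function `(params, reference, comparator) -> numeric`;
#'   default [incremental_total_cost()].
#' @param factors character vector of factor names (default
#'   [sensitivity_factors()]).
#' @return an object of classes `tornado` and `data.frame` with columns
#'   `factor`, `low`, `base`, `high`, `range`, sorted by `range`
#'   descending; rows where clamping occurred carry `clamped = TRUE`.
#' @export
univariate_sensitivity <- function(params, reference, comparator,
                                   metric = incremental_total_cost,
                                   factors = sensitivity_factors()) {
  stopifnot(inherits(params, "parameter_set"))
  base <- metric(params, reference, comparator)
  rows <- lapply(factors, function(f) {
    lo_p <- perturb_parameter_set(params, f, 0.9)
    hi_p <- perturb_parameter_set(params, f, 1.1)
    clamped <- isTRUE(attr(lo_p, "clamped")) || isTRUE(attr(hi_p, "clamped"))
    if (clamped) {
      warning(sprintf("sensitivity factor '%s': perturbation clamped to a valid range", f))
    }
    data.frame(factor = f,
               low = metric(lo_p, reference, comparator),
               base = base,
               high = metric(hi_p, reference, comparator),
               clamped = clamped)
  })
  out <- do.call(rbind, rows)
  out$range <- abs(out$high - out$low)
  out <- out[order(-out$range), c("factor", "low", "base", "high", "range", "clamped")]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the low to the high metric value per factor,
#' widest at the top, with the base value as a vertical reference line.
#'
#' @param x a `tornado` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tornado <- function(x, ...) {
  n <- nrow(x)
  ord <- rev(seq_len(n))  # widest on top
  xlim <- range(c(x$low, x$high, x$base))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Metric value", ylab = "", ...)
  graphics::axis(2, at = ord, labels = x$factor, las = 1, cex.axis = 0.7)
  graphics::segments(x$low, ord, x$high, ord, lwd = 8, col = "steelblue")
  graphics::abline(v = x$base[1], lty = 2)
  invisible(x)
}
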