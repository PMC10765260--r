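#' Incremental cost-effectiveness comparison
#'
#' Compares an intervention against a comparator evaluated on identical
#' engine settings. Incrementals are intervention minus comparator; the ICERs
#' (cost per life-year and per QALY gained) are reported only when the effect
#' difference is positive, otherwise they are `NA` and flagged (`dominant`
#' when the intervention is cheaper and at least as effective, `dominated`
#' when it is costlier and no more effective).
#'
#' @param intervention,comparator `cohort_trace` objects (or their
#'   [trace_totals()] lists).
#' @param labels Character length-2 strategy labels.
#' @return A `ce_result`: list with a per-strategy `summary` data frame,
#'   incrementals `d_cost`, `d_ly`, `d_qaly`, `icer_ly`, `icer_qaly`, and a
#'   `status` of `"icer"`, `"dominant"` or `"dominated"`.
#' @export
compare_strategies <- function(intervention, comparator,
                               labels = c("olaparib", "no olaparib")) {
  tot <- function(x) if (inherits(x, "cohort_trace")) trace_totals(x) else x
  a <- tot(intervention)
  b <- tot(comparator)
  d_cost <- a$cost - b$cost
  d_ly <- a$ly - b$ly
  d_qaly <- a$qaly - b$qaly
  status <- if (d_qaly > 0 && d_cost <= 0) {
    "dominant"
  } else if (d_qaly <= 0 && d_cost >= 0 && !(d_qaly == 0 && d_cost == 0)) {
    "dominated"
  } else {
    "icer"
  }
  icer_ly <- if (d_ly > 0) d_cost / d_ly else NA_real_
  icer_qaly <- if (d_qaly > 0) d_cost / d_qaly else NA_real_
  structure(list(
    summary = data.frame(
      strategy = labels,
      cost = c(a$cost, b$cost),
      ly = c(a$ly, b$ly),
      qaly = c(a$qaly, b$qaly)
    ),
    d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
    icer_ly = icer_ly, icer_qaly = icer_qaly, status = status
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness result (discounted)\n")
  s <- x$summary
  s$cost <- format(round(s$cost), big.mark = ",")
  s$ly <- round(s$ly, 2)
  s$qaly <- round(s$qaly, 2)
  print(s, row.names = FALSE)
  cat(sprintf("  incremental: $%s, %.2f LY, %.2f QALY\n",
              format(round(x$d_cost), big.mark = ","), x$d_ly, x$d_qaly))
  if (x$status == "icer") {
    cat(sprintf("  ICER: $%s per LY, $%s per QALY\n",
                format(round(x$icer_ly), big.mark = ","),
                format(round(x$icer_qaly), big.mark = ",")))
  } else {
    cat("  intervention is", x$status, "\n")
  }
  invisible(x)
}

#' Base-case sensitivity ranges
#'
#' The one-way sensitivity ranges and probabilistic distribution families for
#' every varied input: published ranges where available, otherwise +/-25% of
#' the base-case value. Costs are gamma-distributed, utilities (and the
#' post-recurrence death rate) beta, the hazard ratio log-normal with its 95%
#' CI as the range, and the on-treatment utility multiplier a beta rescaled
#' to its range. The discount rate is varied +/-25% in one-way analysis only
#' (no distribution); the post-year-4 recurrence probabilities and life-table
#' mortality are never varied.
#'
#' @return A data frame with columns `parameter`, `base`, `low`, `high`,
#'   `distribution`.
#' @export
default_sa_ranges <- function() {
  data.frame(
    parameter = c("utility_no_recurrence", "utility_metastatic",
                  "olaparib_utility_multiplier", "monthly_drug_cost",
                  "oncologist_visit_cost", "imaging_cost",
                  "monthly_metastatic_cost", "hazard_ratio",
                  "monthly_metastatic_death_rate", "annual_discount_rate"),
    base = c(0.98, 0.55, 0.9, 14523, 867, 540, 23599, 0.61, 0.052, 0.03),
    low = c(0.735, 0.413, 0.80, 10892, 650, 405, 17699, 0.48, 0.039, 0.0225),
    high = c(1, 0.688, 1, 18154, 1084, 675, 29499, 0.77, 0.065, 0.0375),
    distribution = c("beta", "beta", "beta_scaled", "gamma", "gamma", "gamma",
                     "gamma", "lognormal", "beta", NA)
  )
}

# evaluate the ICER per QALY with one named parameter set to `value`.
# `base` is a list(olaparib=, no_olaparib=) of model_params; varying the
# hazard ratio rebuilds the treated schedule from the comparator's rates.
.icer_at <- function(base, lt, parameter, value) {
  po <- unclass(base$olaparib)
  pn <- unclass(base$no_olaparib)
  if (parameter == "hazard_ratio") {
    po$schedule <- treated_schedule_from_placebo(pn$schedule, value)
  } else if (parameter %in% c("olaparib_utility_multiplier",
                              "monthly_drug_cost")) {
    po[[parameter]] <- value
  } else if (parameter %in% names(po) && parameter != "schedule") {
    po[[parameter]] <- value
    pn[[parameter]] <- value
  } else {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  po <- structure(po, class = "model_params")
  pn <- structure(pn, class = "model_params")
  compare_strategies(run_cohort(po, lt), run_cohort(pn, lt))$icer_qaly
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs both strategies with each parameter set to its low and high bound,
#' all other inputs at base case, and records the ICER per QALY at each
#' bound. Varying `hazard_ratio` rebuilds the olaparib arm's recurrence
#' schedule from the comparator's calibrated rates times the hazard ratio.
#' Entries are sorted by bar width (|ICER high - ICER low|), widest first.
#'
#' @param base List with elements `olaparib` and `no_olaparib`, each a
#'   [model_params()] (see [base_case_params()]).
#' @param lt A [life_table()].
#' @param ranges Data frame with columns `parameter`, `low`, `high`
#'   (defaults to [default_sa_ranges()]).
#' @return A `tornado` data frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `width`.
#' @export
one_way_sa <- function(base, lt, ranges = default_sa_ranges()) {
  stopifnot(all(c("parameter", "low", "high") %in% names(ranges)))
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    p <- ranges$parameter[i]
    data.frame(parameter = p, low = ranges$low[i], high = ranges$high[i],
               icer_low = .icer_at(base, lt, p, ranges$low[i]),
               icer_high = .icer_at(base, lt, p, ranges$high[i]))
  })
  out <- do.call(rbind, out)
  out$width <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Threshold analysis: parameter value yielding a target ICER
#'
#' Finds, by bisection, the value of one parameter at which the ICER per QALY
#' equals a willingness-to-pay threshold, holding all other inputs at base
#' case. Requires the ICER to cross the threshold over `bounds`.
#'
#' @param parameter Parameter name (as in [default_sa_ranges()]).
#' @param wtp Willingness-to-pay threshold, dollars per QALY.
#' @param bounds Length-2 numeric search interval for the parameter.
#' @param base,lt As in [one_way_sa()].
#' @param tol_icer Stop when |ICER - wtp| is below this (dollars).
#' @param tol_x Stop when the parameter interval is below this.
#' @return The crossing parameter value.
#' @export
threshold_search <- function(parameter, wtp, bounds, base, lt,
                             tol_icer = 1, tol_x = 1e-6) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2], wtp > 0)
  f <- function(v) .icer_at(base, lt, parameter, v) - wtp
  flo <- f(bounds[1])
  fhi <- f(bounds[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop("ICER does not cross $", format(wtp, big.mark = ","), " for `",
         parameter, "` over the given bounds", call. = FALSE)
  }
  lo <- bounds[1]
  hi <- bounds[2]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol_icer || (hi - lo) < tol_x) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Write a tornado table to CSV
#'
#' @param tornado A `tornado` data frame from [one_way_sa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado), path, row.names = FALSE)
  invisible(path)
}
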