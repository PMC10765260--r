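#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: each draw samples every distributed input
#' independently, rebuilds the olaparib arm's recurrence schedule as the
#' comparator's calibrated rates times the drawn hazard ratio (the
#' comparator's rates themselves stay fixed), runs both strategies, and
#' records the incremental cost, life-years and QALYs. The
#' cost-effectiveness acceptability curve (CEAC) reports, at each
#' willingness-to-pay value, the fraction of draws in which each strategy has
#' the higher net monetary benefit (`wtp * dQALY - dCost > 0` prefers
#' olaparib; ties count for the comparator).
#'
#' @param base List with `olaparib` and `no_olaparib` [model_params()]
#'   (see [base_case_params()]).
#' @param lt A [life_table()].
#' @param specs Named list of `distribution_spec` objects; names must be
#'   parameters understood by the engine (defaults to [default_psa_specs()]).
#' @param n Number of draws (default 10000).
#' @param seed Integer seed; fixed seed makes the analysis bit-reproducible.
#' @param wtp_grid Willingness-to-pay grid for the CEAC, dollars per QALY
#'   (default $0-300,000 in $5,000 steps).
#' @return A `psa_result`: list with `draws` (data frame: draw, the sampled
#'   parameters, `d_cost`, `d_ly`, `d_qaly`), `ceac` (data frame: `wtp`,
#'   `prop_olaparib`, `prop_no_olaparib`), `quadrants` (counts of the CE
#'   plane quadrants), `n`, `seed`.
#' @export
run_psa <- function(base, lt, specs = default_psa_specs(),
                    n = 10000, seed = 1,
                    wtp_grid = seq(0, 300000, by = 5000)) {
  stopifnot(n >= 1, length(names(specs)) == length(specs))
  for (s in specs) {
    if (!inherits(s, "distribution_spec")) {
      stop("`specs` must be distribution_spec objects", call. = FALSE)
    }
  }
  known <- c(names(unclass(base$olaparib)), "hazard_ratio")
  bad <- setdiff(names(specs), known)
  if (length(bad)) stop("unknown parameter in specs: ", bad[1], call. = FALSE)

  set.seed(seed)
  draws <- as.data.frame(lapply(specs, draw_distribution, n = n))

  po0 <- unclass(base$olaparib)
  pn0 <- unclass(base$no_olaparib)
  placebo_sched <- pn0$schedule
  shared <- setdiff(names(specs),
                    c("hazard_ratio", "olaparib_utility_multiplier",
                      "monthly_drug_cost"))

  d_cost <- d_ly <- d_qaly <- numeric(n)
  for (i in seq_len(n)) {
    po <- po0
    pn <- pn0
    for (nm in shared) {
      po[[nm]] <- draws[[nm]][i]
      pn[[nm]] <- draws[[nm]][i]
    }
    for (nm in intersect(c("olaparib_utility_multiplier",
                           "monthly_drug_cost"), names(specs))) {
      po[[nm]] <- draws[[nm]][i]
    }
    if ("hazard_ratio" %in% names(specs)) {
      po$schedule <- treated_schedule_from_placebo(placebo_sched,
                                                   draws$hazard_ratio[i])
    }
    ta <- run_cohort(structure(po, class = "model_params"), lt)$totals
    tb <- run_cohort(structure(pn, class = "model_params"), lt)$totals
    d_cost[i] <- ta$cost - tb$cost
    d_ly[i] <- ta$ly - tb$ly
    d_qaly[i] <- ta$qaly - tb$qaly
  }

  prop_ola <- vapply(wtp_grid, function(w) mean(w * d_qaly - d_cost > 0),
                     numeric(1))
  ceac <- data.frame(wtp = wtp_grid, prop_olaparib = prop_ola,
                     prop_no_olaparib = 1 - prop_ola)
  quadrants <- c(
    more_costly_more_effective = sum(d_cost > 0 & d_qaly > 0),
    more_costly_less_effective = sum(d_cost > 0 & d_qaly <= 0),
    less_costly_more_effective = sum(d_cost <= 0 & d_qaly > 0),
    less_costly_less_effective = sum(d_cost <= 0 & d_qaly <= 0)
  )
  structure(list(
    draws = cbind(data.frame(draw = seq_len(n)), draws,
                  data.frame(d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly)),
    ceac = ceac, quadrants = quadrants, n = n, seed = seed
  ), class = "psa_result")
}

#' Willingness-to-pay at which the CEAC crosses a given probability
#'
#' Linear interpolation on the CEAC grid; returns the smallest WTP at which
#' the probability that olaparib is preferred reaches `level`.
#'
#' @param psa A `psa_result`.
#' @param level Probability level in (0, 1).
#' @return WTP in dollars per QALY (`NA` if never reached).
#' @export
ceac_crossing <- function(psa, level) {
  stopifnot(inherits(psa, "psa_result"), level > 0, level < 1)
  x <- psa$ceac$wtp
  y <- psa$ceac$prop_olaparib
  i <- which(y >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(x[1])
  x[i - 1] + (x[i] - x[i - 1]) * (level - y[i - 1]) / (y[i] - y[i - 1])
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %d)\n",
              x$n, x$seed))
  q <- x$quadrants
  cat(sprintf("  CE-plane quadrants: %.1f%% more costly & more effective\n",
              100 * q[["more_costly_more_effective"]] / x$n))
  at <- function(w) x$ceac$prop_olaparib[match(w, x$ceac$wtp)]
  for (w in c(100000, 150000)) {
    p <- at(w)
    if (!is.na(p)) {
      cat(sprintf("  P(olaparib preferred) at $%s/QALY: %.1f%%\n",
                  format(w, big.mark = ","), 100 * p))
    }
  }
  for (lv in c(0.5, 0.8)) {
    cr <- ceac_crossing(x, lv)
    if (!is.na(cr)) {
      cat(sprintf("  CEAC reaches %.0f%% at ~$%s/QALY\n", 100 * lv,
                  format(round(cr, -3), big.mark = ",")))
    }
  }
  invisible(x)
}

#' Write PSA draws and CEAC to CSV
#'
#' @param psa A `psa_result`.
#' @param draws_path,ceac_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_psa <- function(psa, draws_path = NULL, ceac_path = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (!is.null(draws_path)) {
    utils::write.csv(psa$draws[, c("draw", "d_cost", "d_qaly")],
                     draws_path, row.names = FALSE)
  }
  if (!is.null(ceac_path)) {
    utils::write.csv(psa$ceac, ceac_path, row.names = FALSE)
  }
  invisible(c(draws_path, ceac_path))
}
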