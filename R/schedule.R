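#' Metastatic-recurrence schedule
#'
#' Monthly rates of distant (metastatic) recurrence by model year. Years 1-4
#' carry one constant monthly rate each (calibrated to trial survival);
#' beyond the trial window the risk falls: years 5-9 and years >= 10 use fixed
#' annual probabilities (defaults 0.0156 and 0.0078) taken from published
#' recurrence cohorts with similar tumour features, converted internally to
#' constant monthly rates. The post-year-4 values are identical in both arms:
#' the model assumes no treatment effect on recurrence after month 48.
#'
#' @param monthly_rates_y1_4 Numeric length-4 vector of non-negative monthly
#'   recurrence rates for model years 1-4.
#' @param annual_prob_y5_9 Annual recurrence probability for years 5-9.
#' @param annual_prob_y10p Annual recurrence probability for years >= 10.
#' @return An object of class `recurrence_schedule`.
#' @export
recurrence_schedule <- function(monthly_rates_y1_4,
                                annual_prob_y5_9 = 0.0156,
                                annual_prob_y10p = 0.0078) {
  r <- as.numeric(monthly_rates_y1_4)
  if (length(r) != 4L || any(!is.finite(r)) || any(r < 0)) {
    stop("`monthly_rates_y1_4` must be 4 non-negative rates", call. = FALSE)
  }
  for (p in c(annual_prob_y5_9, annual_prob_y10p)) {
    if (!is.finite(p) || p < 0 || p >= 1) {
      stop("annual probabilities must be in [0, 1)", call. = FALSE)
    }
  }
  structure(list(
    monthly_rates_y1_4 = r,
    annual_prob_y5_9 = annual_prob_y5_9,
    annual_prob_y10p = annual_prob_y10p,
    monthly_rate_y5_9 = prob_to_rate(annual_prob_y5_9, 12),
    monthly_rate_y10p = prob_to_rate(annual_prob_y10p, 12)
  ), class = "recurrence_schedule")
}

#' Monthly recurrence rate in force during given model months
#'
#' Model year `y` spans months `12(y-1)+1` to `12y`.
#'
#' @param schedule A [recurrence_schedule()].
#' @param month Positive integer month index (vectorised).
#' @return Monthly recurrence rate(s).
#' @export
schedule_rate <- function(schedule, month) {
  stopifnot(inherits(schedule, "recurrence_schedule"))
  if (any(month < 1)) stop("`month` must be >= 1", call. = FALSE)
  year <- (month - 1) %/% 12 + 1
  out <- numeric(length(month))
  early <- year <= 4
  out[early] <- schedule$monthly_rates_y1_4[year[early]]
  out[year >= 5 & year <= 9] <- schedule$monthly_rate_y5_9
  out[year >= 10] <- schedule$monthly_rate_y10p
  out
}

#' Treated-arm schedule from the placebo schedule and a hazard ratio
#'
#' Applies the treatment hazard ratio to the placebo arm's calibrated monthly
#' recurrence rates for years 1-4; years >= 5 are copied unchanged (no
#' treatment effect beyond month 48). This is the construction used whenever
#' the hazard ratio is varied (one-way and probabilistic sensitivity
#' analysis).
#'
#' @param placebo A placebo-arm [recurrence_schedule()].
#' @param hr Positive hazard ratio (number or [hazard_ratio()]).
#' @return A [recurrence_schedule()] for the treated arm.
#' @export
treated_schedule_from_placebo <- function(placebo, hr) {
  stopifnot(inherits(placebo, "recurrence_schedule"))
  recurrence_schedule(
    apply_hazard_ratio(placebo$monthly_rates_y1_4, hr),
    annual_prob_y5_9 = placebo$annual_prob_y5_9,
    annual_prob_y10p = placebo$annual_prob_y10p
  )
}

#' @export
print.recurrence_schedule <- function(x, ...) {
  cat("Metastatic-recurrence schedule (monthly rates)\n")
  cat(sprintf("  years 1-4 : %s\n",
              paste(formatC(x$monthly_rates_y1_4, format = "f", digits = 6),
                    collapse = " ")))
  cat(sprintf("  years 5-9 : %.6f (annual prob %.4f)\n",
              x$monthly_rate_y5_9, x$annual_prob_y5_9))
  cat(sprintf("  years >=10: %.6f (annual prob %.4f)\n",
              x$monthly_rate_y10p, x$annual_prob_y10p))
  invisible(x)
}
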