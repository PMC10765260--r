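#' Synthetic Gompertz-Makeham life table
#'
#' Generates a life table from a Gompertz-Makeham hazard
#' `h(x) = a * exp(b * x) + c`: the annual death probability at age `x` is
#' `1 - exp(-H)` with `H` the hazard integrated over `[x, x + 1]`. Used by
#' the test suite as a realistic stand-in for period life tables; with
#' `b > 0` the probabilities increase with age. Probabilities that would
#' exceed 1 are capped with a warning.
#'
#' @param a Baseline hazard (per year), > 0.
#' @param b Shape (per year), >= 0; `b = 0` gives a constant hazard.
#' @param c Makeham (age-independent) hazard, >= 0.
#' @param max_age Last age in the table (<= 120).
#' @return A [life_table()] covering ages `0:max_age`.
#' @export
gompertz_life_table <- function(a, b, c = 0, max_age = 110) {
  stopifnot(a > 0, b >= 0, c >= 0, max_age >= 1, max_age <= 120)
  x <- 0:max_age
  H <- if (b < 1e-12) rep(a + c, length(x)) else a / b * exp(b * x) * (exp(b) - 1) + c
  q <- -expm1(-H)
  if (any(q >= 1)) {
    warning("annual death probability capped at 1 from age ",
            x[which(q >= 1)[1]], call. = FALSE)
    q <- pmin(q, 1)
  }
  life_table(x, q)
}

#' Simulate trial-style survival targets from a known schedule
#'
#' Runs the cohort engine with a known recurrence schedule and reads off the
#' model's DDFS and OS at months 12, 24, 36 and 48, packaged as
#' [calibration_targets()]. Deterministic; closes the loop for calibration
#' parameter-recovery tests ([calibrate_arm()] applied to these targets must
#' recover the generating rates).
#'
#' @param schedule A [recurrence_schedule()].
#' @param params A [model_params()]; its schedule slot is replaced by
#'   `schedule`.
#' @param lt A [life_table()].
#' @param arm Label for the generated targets.
#' @return A [calibration_targets()].
#' @export
simulate_trial_targets <- function(schedule, params, lt, arm = "synthetic") {
  stopifnot(inherits(schedule, "recurrence_schedule"),
            inherits(params, "model_params"))
  p <- structure(modifyList(unclass(params), list(schedule = schedule)),
                 class = "model_params")
  tr <- run_cohort(p, lt, max_months = 48)
  months <- c(12L, 24L, 36L, 48L)
  calibration_targets(arm,
                      ddfs = model_ddfs(tr, months),
                      os = model_os(tr, months))
}
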