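#' Model parameters for one strategy
#'
#' All inputs of the four-state cohort model for a single strategy. Defaults
#' are the base-case values: 2021 US dollars, monthly cycles, ages in years.
#' The olaparib strategy adds the monthly drug cost for the one-year treatment
#' course (discontinued on metastatic recurrence), a denser oncologist-visit
#' schedule during treatment, and a utility multiplier (< 1) applied to the
#' no-recurrence utility during the treatment year.
#'
#' @param olaparib Logical; `TRUE` for the adjuvant-olaparib strategy.
#' @param schedule A [recurrence_schedule()] for this arm.
#' @param starting_age Cohort starting age in years (base case 42, the trial
#'   median; 50 and 60 are examined as scenarios).
#' @param monthly_drug_cost Monthly cost of olaparib, dollars (14523).
#' @param oncologist_visit_cost Cost per oncologist visit, dollars (867).
#' @param imaging_cost Cost of annual diagnostic mammogram plus breast MRI,
#'   dollars (540).
#' @param monthly_metastatic_cost Monthly cost of care for metastatic
#'   recurrence, dollars (23599).
#' @param utility_no_recurrence Annual utility of the no-recurrence state
#'   (0.98).
#' @param utility_metastatic Annual utility of metastatic recurrence (0.55).
#' @param olaparib_utility_multiplier Multiplier (<= 1) on the no-recurrence
#'   utility while on olaparib (0.9).
#' @param hr Treatment [hazard_ratio()] for metastatic recurrence
#'   (0.61, 95% CI 0.48-0.77); kept with the parameters so sensitivity
#'   analyses can rebuild the treated schedule.
#' @param monthly_metastatic_death_rate Monthly rate of breast-cancer death
#'   after metastatic recurrence (0.052, from a 13.3-month median survival).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   health outcomes (0.03).
#' @param imaging_fraction Fraction of the cohort with at least one breast,
#'   who receive annual surveillance imaging (0.535).
#' @param treatment_duration Olaparib treatment duration in months (12).
#' @param horizon_age Maximum age simulated (110; the cohort is effectively
#'   extinct earlier).
#' @return An object of class `model_params`.
#' @export
model_params <- function(olaparib,
                         schedule,
                         starting_age = 42,
                         monthly_drug_cost = 14523,
                         oncologist_visit_cost = 867,
                         imaging_cost = 540,
                         monthly_metastatic_cost = 23599,
                         utility_no_recurrence = 0.98,
                         utility_metastatic = 0.55,
                         olaparib_utility_multiplier = 0.9,
                         hr = hazard_ratio(),
                         monthly_metastatic_death_rate = 0.052,
                         annual_discount_rate = 0.03,
                         imaging_fraction = 0.535,
                         treatment_duration = 12,
                         horizon_age = 110) {
  stopifnot(is.logical(olaparib), length(olaparib) == 1L,
            inherits(schedule, "recurrence_schedule"),
            inherits(hr, "hazard_ratio"))
  p <- list(
    olaparib = olaparib, schedule = schedule, starting_age = starting_age,
    monthly_drug_cost = monthly_drug_cost,
    oncologist_visit_cost = oncologist_visit_cost,
    imaging_cost = imaging_cost,
    monthly_metastatic_cost = monthly_metastatic_cost,
    utility_no_recurrence = utility_no_recurrence,
    utility_metastatic = utility_metastatic,
    olaparib_utility_multiplier = olaparib_utility_multiplier,
    hr = hr,
    monthly_metastatic_death_rate = monthly_metastatic_death_rate,
    annual_discount_rate = annual_discount_rate,
    imaging_fraction = imaging_fraction,
    treatment_duration = treatment_duration,
    horizon_age = horizon_age
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  for (nm in c("monthly_drug_cost", "oncologist_visit_cost", "imaging_cost",
               "monthly_metastatic_cost")) {
    chk(num1(p[[nm]]) && p[[nm]] >= 0, paste0("`", nm, "` must be >= 0"))
  }
  for (nm in c("utility_no_recurrence", "utility_metastatic",
               "olaparib_utility_multiplier", "imaging_fraction")) {
    chk(num1(p[[nm]]) && p[[nm]] >= 0 && p[[nm]] <= 1,
        paste0("`", nm, "` must be in [0, 1]"))
  }
  chk(num1(p$monthly_metastatic_death_rate) &&
        p$monthly_metastatic_death_rate >= 0,
      "`monthly_metastatic_death_rate` must be >= 0")
  chk(num1(p$annual_discount_rate) && p$annual_discount_rate >= 0,
      "`annual_discount_rate` must be >= 0")
  chk(num1(p$treatment_duration) && p$treatment_duration > 0,
      "`treatment_duration` must be > 0")
  chk(num1(p$starting_age) && p$starting_age >= 0,
      "`starting_age` must be >= 0")
  chk(num1(p$horizon_age) && p$horizon_age > p$starting_age,
      "`horizon_age` must exceed `starting_age`")
  invisible(p)
}

# return a modified copy, revalidated; schedule/hr replaced as objects
modify_params <- function(p, ...) {
  new <- list(...)
  for (nm in names(new)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm, call. = FALSE)
    p[[nm]] <- new[[nm]]
  }
  validate_model_params(p)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Cohort model parameters - %s strategy\n",
              if (x$olaparib) "adjuvant olaparib" else "no olaparib"))
  cat(sprintf("  starting age %g y, horizon age %g y, discount %.1f%%/y\n",
              x$starting_age, x$horizon_age, 100 * x$annual_discount_rate))
  cat(sprintf("  utilities: no recurrence %.2f%s, metastatic %.2f\n",
              x$utility_no_recurrence,
              if (x$olaparib)
                sprintf(" (x %.2f on treatment)", x$olaparib_utility_multiplier)
              else "",
              x$utility_metastatic))
  cat(sprintf(
    "  costs/mo: drug %s, metastatic %s; visit %s, imaging %s (x %.3f)\n",
    format(x$monthly_drug_cost, big.mark = ","),
    format(x$monthly_metastatic_cost, big.mark = ","),
    format(x$oncologist_visit_cost, big.mark = ","),
    format(x$imaging_cost, big.mark = ","), x$imaging_fraction))
  cat(sprintf("  metastatic death rate %.3f/mo; HR %.2f (%.2f-%.2f)\n",
              x$monthly_metastatic_death_rate, x$hr$point, x$hr$ci_low,
              x$hr$ci_high))
  invisible(x)
}

#' Trial survival calibration targets for one arm
#'
#' Distant disease-free survival (DDFS) and overall survival (OS) fractions at
#' months 12, 24, 36 and 48 to which the recurrence schedule is calibrated.
#' Both series must be non-increasing with values in (0, 1].
#'
#' @param arm Arm label, e.g. `"placebo"` or `"olaparib"`.
#' @param ddfs,os Numeric length-4 vectors of survival fractions at months
#'   12, 24, 36, 48.
#' @return An object of class `calibration_targets`.
#' @export
calibration_targets <- function(arm, ddfs, os) {
  months <- c(12L, 24L, 36L, 48L)
  for (nm in c("ddfs", "os")) {
    v <- get(nm)
    if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0) || any(v > 1)) {
      stop("`", nm, "` must be 4 fractions in (0, 1]", call. = FALSE)
    }
    if (any(diff(v) > 1e-12)) {
      stop("`", nm, "` must be non-increasing over months", call. = FALSE)
    }
  }
  structure(list(arm = as.character(arm),
                 months = months,
                 ddfs = stats::setNames(as.numeric(ddfs), months),
                 os = stats::setNames(as.numeric(os), months)),
            class = "calibration_targets")
}

#' @export
print.calibration_targets <- function(x, ...) {
  cat(sprintf("Calibration targets - %s arm\n", x$arm))
  print(round(rbind(DDFS = x$ddfs, OS = x$os), 4))
  invisible(x)
}

#' OlympiA trial survival targets
#'
#' The published 12/24/36/48-month DDFS and OS of the OlympiA trial's two
#' arms (updated interim analysis), used to calibrate the model's recurrence
#' schedules.
#'
#' @param arm `"placebo"` (no olaparib) or `"olaparib"`.
#' @return A [calibration_targets()].
#' @export
olympia_targets <- function(arm = c("placebo", "olaparib")) {
  arm <- match.arg(arm)
  if (arm == "placebo") {
    calibration_targets("placebo",
                        ddfs = c(0.903, 0.840, 0.810, 0.791),
                        os   = c(0.969, 0.928, 0.891, 0.864))
  } else {
    calibration_targets("olaparib",
                        ddfs = c(0.944, 0.906, 0.880, 0.865),
                        os   = c(0.980, 0.950, 0.928, 0.898))
  }
}
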