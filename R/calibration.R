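#' Closed-form starting rates from DDFS targets
#'
#' Converts the year-over-year DDFS decrements into constant monthly rates:
#' year `k`'s rate is `-log(S_k / S_{k-1}) / 12` with `S_0 = 1`. This treats
#' the DDFS decrement as pure recurrence (ignoring background mortality), so
#' it slightly overstates the recurrence rate; it is the calibration starting
#' point, not the final answer.
#'
#' @param targets A [calibration_targets()].
#' @return A [recurrence_schedule()] with the closed-form year 1-4 rates.
#' @export
initial_rates_from_targets <- function(targets) {
  stopifnot(inherits(targets, "calibration_targets"))
  s <- c(1, unname(targets$ddfs))
  recurrence_schedule(-log(s[-1] / s[-5]) / 12)
}

#' Calibrate an arm's recurrence schedule to trial survival targets
#'
#' Sequentially fits the monthly metastatic-recurrence rate of model years 1
#' through 4 so that the cohort model reproduces the arm's DDFS at months 12,
#' 24, 36 and 48. Because DDFS at month `12k` depends only on the rates of
#' years `<= k`, the system is triangular and each year can be fitted holding
#' earlier years fixed. OS is not fitted — post-recurrence mortality and
#' life-table mortality are fixed inputs — but the report records the
#' model-vs-target OS deviations as a validation output.
#'
#' Two modes: `"grid"` walks the rate in increments of `step` (default
#' 0.0001) until the model DDFS brackets the target, keeping the grid value
#' with the smaller error; `"bisect"` refines by bisection until the model
#' DDFS is within `tol` of the target.
#'
#' @param targets A [calibration_targets()].
#' @param params A [model_params()] for this arm (its schedule slot provides
#'   the post-year-4 extrapolation and is replaced by the fit).
#' @param lt A [life_table()].
#' @param step Grid increment on the monthly rate (grid mode).
#' @param tol Convergence tolerance on the survival fraction (bisect mode);
#'   grid mode flags convergence when every DDFS deviation is below
#'   `12 * step`, the resolution limit of the grid.
#' @param mode `"grid"` or `"bisect"`.
#' @param init Optional starting [recurrence_schedule()]; defaults to
#'   [initial_rates_from_targets()].
#' @param max_iter Iteration cap per year.
#' @return A `calibration_report`: list with the fitted `schedule`, a
#'   `deviations` data frame (measure, month, target, model, deviation),
#'   `iterations`, `converged`, `mode` and `arm`.
#' @export
calibrate_arm <- function(targets, params, lt,
                          step = 1e-4, tol = 1e-6,
                          mode = c("grid", "bisect"),
                          init = NULL, max_iter = 10000L) {
  stopifnot(inherits(targets, "calibration_targets"),
            inherits(params, "model_params"), step > 0, tol > 0)
  mode <- match.arg(mode)
  if (is.null(init)) init <- initial_rates_from_targets(targets)
  rates <- init$monthly_rates_y1_4
  base_sched <- params$schedule
  iters <- 0L

  ddfs_at <- function(rates_y14, month) {
    sch <- recurrence_schedule(rates_y14,
                               annual_prob_y5_9 = base_sched$annual_prob_y5_9,
                               annual_prob_y10p = base_sched$annual_prob_y10p)
    p <- structure(modifyList(unclass(params), list(schedule = sch)),
                   class = "model_params")
    model_ddfs(run_cohort(p, lt, max_months = month), month)
  }

  for (k in 1:4) {
    month_k <- 12L * k
    target <- unname(targets$ddfs[as.character(month_k)])
    f <- function(rate) {
      rk <- rates
      rk[k] <- rate
      ddfs_at(rk, month_k)
    }
    if (mode == "grid") {
      rate <- max(rates[k], 0)
      val <- f(rate)
      it <- 0L
      # model DDFS decreases in the rate: step towards the target
      dir <- if (val > target) 1 else -1
      repeat {
        it <- it + 1L
        if (it > max_iter) {
          stop("calibration did not converge for year ", k,
               " (best rate ", signif(rate, 6), ")", call. = FALSE)
        }
        nxt <- max(rate + dir * step, 0)
        nval <- f(nxt)
        if (abs(nval - target) >= abs(val - target) && nxt != rate) break
        rate <- nxt
        val <- nval
        if (rate == 0 && dir < 0) break
      }
      rates[k] <- rate
      iters <- iters + it
    } else {
      lo <- 0
      hi <- max(4 * rates[k], 0.05)
      it <- 0L
      while (f(hi) > target) {
        hi <- hi * 2
        it <- it + 1L
        if (it > 60L) stop("cannot bracket year ", k, call. = FALSE)
      }
      repeat {
        it <- it + 1L
        if (it > max_iter) {
          stop("bisection did not converge for year ", k, call. = FALSE)
        }
        mid <- (lo + hi) / 2
        val <- f(mid)
        if (abs(val - target) <= tol || (hi - lo) < 1e-14) break
        if (val > target) lo <- mid else hi <- mid
      }
      rates[k] <- (lo + hi) / 2
      iters <- iters + it
    }
  }

  schedule <- recurrence_schedule(rates,
                                  annual_prob_y5_9 = base_sched$annual_prob_y5_9,
                                  annual_prob_y10p = base_sched$annual_prob_y10p)
  fit_params <- structure(modifyList(unclass(params),
                                     list(schedule = schedule)),
                          class = "model_params")
  tr <- run_cohort(fit_params, lt, max_months = 48)
  months <- targets$months
  dev <- rbind(
    data.frame(measure = "ddfs", month = months,
               target = unname(targets$ddfs),
               model = model_ddfs(tr, months)),
    data.frame(measure = "os", month = months,
               target = unname(targets$os),
               model = model_os(tr, months))
  )
  dev$deviation <- dev$model - dev$target
  ddfs_tol <- if (mode == "grid") 12 * step else tol
  converged <- all(abs(dev$deviation[dev$measure == "ddfs"]) <= ddfs_tol)

  structure(list(arm = targets$arm, schedule = schedule, deviations = dev,
                 iterations = iters, converged = converged, mode = mode,
                 step = step, tol = tol),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report - %s arm (%s mode, %d evaluations, %s)\n",
              x$arm, x$mode, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("  fitted monthly rates, years 1-4: ",
      paste(formatC(x$schedule$monthly_rates_y1_4, format = "f", digits = 6),
            collapse = " "), "\n")
  d <- x$deviations
  d$target <- round(d$target, 4)
  d$model <- round(d$model, 4)
  d$deviation <- round(d$deviation, 5)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param report A `calibration_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(report, path) {
  stopifnot(inherits(report, "calibration_report"))
  jsonlite::write_json(list(
    arm = report$arm, mode = report$mode, converged = report$converged,
    iterations = report$iterations,
    monthly_rates_y1_4 = report$schedule$monthly_rates_y1_4,
    annual_prob_y5_9 = report$schedule$annual_prob_y5_9,
    annual_prob_y10p = report$schedule$annual_prob_y10p,
    deviations = report$deviations
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
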