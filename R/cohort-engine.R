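#' @title Four-state cohort engine
#' @description Internal notes: the engine tracks state occupancy of the
#'   cohort at the end of each monthly cycle. States: `no_recurrence`,
#'   `metastatic`, `death_bc` (breast-cancer death, reachable only from
#'   metastatic) and `death_other`. Rewards accrue on the state occupied
#'   during a cycle (occupancy at cycle start), transitions apply at cycle
#'   end, and each cycle's accrual is discounted by
#'   `(1 + annual_discount_rate)^(-month/12)`. No half-cycle correction.
#' @name cohort-engine
#' @keywords internal
NULL

STATE_NAMES <- c("no_recurrence", "metastatic", "death_bc", "death_other")

#' One-cycle transition probabilities from a state
#'
#' The row of the monthly transition matrix for one origin state. Living
#' states combine their cause-specific rates (recurrence or breast-cancer
#' death, plus background mortality) with the competing-risk apportionment;
#' death states are absorbing.
#'
#' @param state One of `"no_recurrence"`, `"metastatic"`, `"death_bc"`,
#'   `"death_other"`.
#' @param month Model month index (>= 1) during the cycle.
#' @param age Age in years during the cycle.
#' @param params A [model_params()].
#' @param lt A [life_table()].
#' @return Named numeric vector of probabilities over the four states,
#'   summing to one.
#' @export
cycle_transition_row <- function(state, month, age, params, lt) {
  if (!state %in% STATE_NAMES) stop("unknown state: ", state, call. = FALSE)
  if (month < 1) stop("`month` must be >= 1", call. = FALSE)
  row <- stats::setNames(numeric(4), STATE_NAMES)
  if (state %in% c("death_bc", "death_other")) {
    row[state] <- 1
    return(row)
  }
  b <- monthly_background_death_rate(lt, age)
  if (state == "no_recurrence") {
    r <- schedule_rate(params$schedule, month)
    cr <- competing_risk_probs(c(r, b))
    row["metastatic"] <- cr$event[1]
    row["death_other"] <- cr$event[2]
    row["no_recurrence"] <- cr$stay
  } else {
    cr <- competing_risk_probs(c(params$monthly_metastatic_death_rate, b))
    row["death_bc"] <- cr$event[1]
    row["death_other"] <- cr$event[2]
    row["metastatic"] <- cr$stay
  }
  row
}

#' Run the cohort simulation
#'
#' Simulates the cohort from `starting_age` in monthly cycles, starting fully
#' in the no-recurrence state, until `horizon_age`, `max_months` cycles, or
#' cohort extinction (alive fraction below `1e-9`), whichever comes first.
#' Accrues per-cycle life-years, QALYs and costs, discounted at the annual
#' discount rate.
#'
#' Cost schedule: the olaparib strategy pays the monthly drug cost during
#' months 1-12 for the no-recurrence occupancy only (treatment stops at
#' recurrence), monthly oncologist visits during months 1-12, six-monthly
#' visits through month 72, then annual visits; the no-olaparib strategy has
#' six-monthly visits through month 60, then annual. Surveillance imaging is
#' annual, paid by the `imaging_fraction` of the no-recurrence occupancy.
#' Metastatic occupancy pays the all-inclusive monthly metastatic-care cost.
#'
#' @param params A [model_params()].
#' @param lt A [life_table()] covering ages through the horizon.
#' @param max_months Optional cap on the number of cycles (used by
#'   calibration, which only needs the first 48 months).
#' @return A `cohort_trace` object; see [model_ddfs()], [model_os()],
#'   [trace_totals()], [as.data.frame.cohort_trace()].
#' @examples
#' lt <- gompertz_life_table(a = 2e-5, b = 0.09)
#' sched <- recurrence_schedule(c(0.006, 0.004, 0.003, 0.002))
#' tr <- run_cohort(model_params(olaparib = FALSE, schedule = sched), lt)
#' trace_totals(tr)
#' @export
run_cohort <- function(params, lt, max_months = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(lt, "life_table"))
  n <- ceiling((params$horizon_age - params$starting_age) * 12)
  if (!is.null(max_months)) n <- min(n, as.integer(max_months))
  if (n < 1) stop("horizon allows no cycles", call. = FALSE)
  m <- seq_len(n)
  age_start <- params$starting_age + (m - 1) / 12
  if (max(floor(age_start)) > max(lt$age)) {
    stop("life table ends at age ", max(lt$age),
         " but the horizon requires age ", max(floor(age_start)),
         call. = FALSE)
  }

  b <- monthly_background_death_rate(lt, age_start)
  r <- schedule_rate(params$schedule, m)
  d <- params$monthly_metastatic_death_rate

  # no-recurrence row: competing recurrence vs background death
  R1 <- r + b
  pe1 <- -expm1(-R1)
  p_rec <- ifelse(R1 > 0, pe1 * r / R1, 0)
  p_do1 <- pe1 - p_rec
  stay1 <- 1 - pe1
  # metastatic row: competing breast-cancer vs background death
  R2 <- d + b
  pe2 <- -expm1(-R2)
  p_dbc <- ifelse(R2 > 0, pe2 * d / R2, 0)
  p_do2 <- pe2 - p_dbc
  stay2 <- 1 - pe2

  # occupancy at end of month k (index k+1 holds month k; index 1 is month 0)
  nr <- c(1, cumprod(stay1))
  inflow <- nr[m] * p_rec
  met <- .metastatic_occupancy(stay2, inflow)
  met_full <- c(0, met)
  met_start <- met_full[m]
  dbc <- c(0, cumsum(met_start * p_dbc))
  dot <- c(0, cumsum(nr[m] * p_do1 + met_start * p_do2))

  # truncate at cohort extinction
  alive <- nr + met_full
  last <- if (any(alive < 1e-9)) which(alive < 1e-9)[1] - 1L else n + 1L
  keep <- seq_len(last)            # months 0 .. last-1
  n_eff <- last - 1L               # number of cycles retained
  mm <- seq_len(n_eff)

  occ <- cbind(no_recurrence = nr[keep], metastatic = met_full[keep],
               death_bc = dbc[keep], death_other = dot[keep])

  # rewards: occupancy at cycle start, discount by end-of-cycle month
  nr_s <- nr[mm]
  met_s <- met_full[mm]
  df <- (1 + params$annual_discount_rate)^(-mm / 12)

  on_tx <- params$olaparib & mm <= params$treatment_duration
  u_nr <- ifelse(on_tx,
                 params$utility_no_recurrence * params$olaparib_utility_multiplier,
                 params$utility_no_recurrence)
  ly <- (nr_s + met_s) / 12
  qaly <- (nr_s * u_nr + met_s * params$utility_metastatic) / 12

  visit <- if (params$olaparib) {
    mm <= 12 | (mm > 12 & mm <= 72 & mm %% 6 == 0) | (mm > 72 & mm %% 12 == 0)
  } else {
    (mm <= 60 & mm %% 6 == 0) | (mm > 60 & mm %% 12 == 0)
  }
  imaging <- mm %% 12 == 0
  cost <- nr_s * (params$monthly_drug_cost * on_tx +
                    params$oncologist_visit_cost * visit +
                    params$imaging_cost * params$imaging_fraction * imaging) +
    met_s * params$monthly_metastatic_cost

  structure(list(
    month = keep - 1L,
    age = params$starting_age + (keep - 1L) / 12,
    occupancy = occ,
    cycle = data.frame(month = mm, cost = cost, ly = ly, qaly = qaly,
                       disc_cost = cost * df, disc_ly = ly * df,
                       disc_qaly = qaly * df),
    totals = list(
      cost = sum(cost * df), ly = sum(ly * df), qaly = sum(qaly * df),
      undiscounted = list(cost = sum(cost), ly = sum(ly), qaly = sum(qaly))
    ),
    params = params
  ), class = "cohort_trace")
}

# metastatic occupancy by linear recurrence met[k] = met[k-1]*stay[k] + in[k];
# vectorised via cumulative products unless they underflow or a stay hits 0
.metastatic_occupancy <- function(stay, inflow) {
  n <- length(stay)
  if (all(stay > 0)) {
    C <- cumprod(stay)
    if (C[n] > 1e-250) {
      return(C * cumsum(inflow / C))
    }
  }
  met <- numeric(n)
  prev <- 0
  for (k in seq_len(n)) {
    prev <- prev * stay[k] + inflow[k]
    met[k] <- prev
  }
  met
}

#' Model distant disease-free survival at a month
#'
#' DDFS is the fraction of the cohort alive without distant recurrence, i.e.
#' the no-recurrence occupancy at the stated month.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param month Month index within the trace (0 gives 1). Vectorised.
#' @return Survival fraction(s).
#' @export
model_ddfs <- function(trace, month) {
  stopifnot(inherits(trace, "cohort_trace"))
  idx <- match(month, trace$month)
  if (anyNA(idx)) stop("month beyond trace", call. = FALSE)
  unname(trace$occupancy[idx, "no_recurrence"])
}

#' Model overall survival at a month
#'
#' One minus the occupancy of the two death states at the stated month.
#'
#' @inheritParams model_ddfs
#' @return Survival fraction(s).
#' @export
model_os <- function(trace, month) {
  stopifnot(inherits(trace, "cohort_trace"))
  idx <- match(month, trace$month)
  if (anyNA(idx)) stop("month beyond trace", call. = FALSE)
  unname(1 - trace$occupancy[idx, "death_bc"] -
           trace$occupancy[idx, "death_other"])
}

#' Discounted totals of a cohort trace
#'
#' @param trace A `cohort_trace`.
#' @return List with `cost`, `ly`, `qaly` (discounted) and an `undiscounted`
#'   sub-list.
#' @export
trace_totals <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  trace$totals
}

#' @export
print.cohort_trace <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Cohort trace - %s strategy, start age %g, %d cycles\n",
              if (x$params$olaparib) "olaparib" else "no olaparib",
              x$params$starting_age, nrow(x$cycle)))
  cat(sprintf("  discounted:   cost $%s, %.2f LY, %.2f QALY\n",
              format(round(t$cost), big.mark = ","), t$ly, t$qaly))
  cat(sprintf("  undiscounted: cost $%s, %.2f LY, %.2f QALY\n",
              format(round(t$undiscounted$cost), big.mark = ","),
              t$undiscounted$ly, t$undiscounted$qaly))
  invisible(x)
}

#' Cohort trace as a data frame
#'
#' One row per month (month 0 = model start), with the four state occupancies
#' and, for months >= 1, that cycle's discounted cost, life-years and QALYs.
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  df <- data.frame(month = x$month, age = x$age, x$occupancy)
  cyc <- x$cycle[, c("month", "disc_cost", "disc_ly", "disc_qaly")]
  merge(df, cyc, by = "month", all.x = TRUE, sort = TRUE)
}

#' Export a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
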