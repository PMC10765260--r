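test_that("transition rows are valid distributions", {
  lt <- gomp_lt()
  p <- params_with()
  for (st in c("death_bc", "death_other")) {
    row <- cycle_transition_row(st, 5, 60, p, lt)
    expect_identical(unname(row[st]), 1)
    expect_equal(sum(row), 1)
  }
  # no hazards at all: the cohort stays put
  p0 <- params_with(schedule = recurrence_schedule(rep(0, 4)))
  row <- cycle_transition_row("no_recurrence", 1, 42, p0, zero_lt())
  expect_identical(unname(row["no_recurrence"]), 1)
  # metastatic exit with no background mortality is the pure death hazard
  row <- cycle_transition_row("metastatic", 1, 42, p, zero_lt())
  expect_equal(unname(row["death_bc"]), 1 - exp(-0.052))
  expect_equal(sum(row), 1, tolerance = 1e-12)
  expect_error(cycle_transition_row("cured", 1, 42, p, lt), "unknown state")
})

test_that("a hazard-free cohort accrues exactly its horizon", {
  p <- params_with(schedule = recurrence_schedule(rep(0, 4),
                                                  annual_prob_y5_9 = 0,
                                                  annual_prob_y10p = 0),
                   starting_age = 5, horizon_age = 15,
                   utility_no_recurrence = 1, annual_discount_rate = 0,
                   oncologist_visit_cost = 0, imaging_cost = 0)
  tr <- run_cohort(p, zero_lt(30), max_months = 120)
  expect_equal(trace_totals(tr)$ly, 10)
  expect_equal(trace_totals(tr)$qaly, 10)
  expect_equal(model_ddfs(tr, c(0, 60, 120)), c(1, 1, 1))
})

test_that("metastatic survival has the intended ~13.3-month median", {
  # geometric survival under the monthly death probability
  pm <- 1 - exp(-0.052)
  surv <- cumprod(rep(1 - pm, 20))
  expect_identical(which(surv <= 0.5)[1], 14L)
  # same through the engine: force immediate recurrence, no background death
  p <- params_with(schedule = recurrence_schedule(c(1000, 0, 0, 0)),
                   starting_age = 40, horizon_age = 60)
  tr <- run_cohort(p, zero_lt(60))
  os <- model_os(tr, 1:30)
  expect_identical(which(os <= 0.5)[1] - 1L, 14L)  # month 1 = recurrence
})

test_that("occupancy is conserved for arbitrary parameter draws", {
  set.seed(11)
  lt <- gomp_lt()
  for (i in 1:12) {
    p <- params_with(
      olaparib = i %% 2 == 0,
      schedule = recurrence_schedule(stats::runif(4, 0, 0.05)),
      monthly_metastatic_death_rate = stats::runif(1, 0, 0.3),
      starting_age = sample(30:70, 1)
    )
    tr <- run_cohort(p, lt)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    # survival curves are non-increasing, and OS dominates DDFS
    ddfs <- model_ddfs(tr, tr$month)
    os <- model_os(tr, tr$month)
    expect_true(all(diff(ddfs) <= 1e-12))
    expect_true(all(diff(os) <= 1e-12))
    expect_true(all(os - ddfs >= -1e-12))
  }
})

test_that("engine agrees with an explicit transition-matrix oracle", {
  set.seed(23)
  lt <- gomp_lt()
  for (i in 1:4) {
    p <- params_with(
      olaparib = i %% 2 == 0,
      schedule = recurrence_schedule(stats::runif(4, 0.001, 0.02)),
      starting_age = 45
    )
    n <- 90
    oracle <- matrix_oracle(p, lt, n)
    tr <- run_cohort(p, lt, max_months = n)
    expect_equal(tr$occupancy, oracle$occupancy, tolerance = 1e-10)
    expect_equal(trace_totals(tr)$ly, oracle$ly, tolerance = 1e-10)
    expect_equal(trace_totals(tr)$qaly, oracle$qaly, tolerance = 1e-10)
    expect_equal(trace_totals(tr)$cost, oracle$cost, tolerance = 1e-8)
  }
})

test_that("a null intervention changes nothing", {
  lt <- gomp_lt()
  sched <- recurrence_schedule(c(0.0085, 0.006, 0.003, 0.0018))
  mk <- function(olaparib) {
    params_with(olaparib = olaparib, schedule = sched,
                monthly_drug_cost = 0, olaparib_utility_multiplier = 1,
                oncologist_visit_cost = 0)
  }
  ta <- trace_totals(run_cohort(mk(TRUE), lt))
  tb <- trace_totals(run_cohort(mk(FALSE), lt))
  expect_equal(ta$ly, tb$ly, tolerance = 1e-9)
  expect_equal(ta$qaly, tb$qaly, tolerance = 1e-9)
  expect_equal(ta$cost, tb$cost, tolerance = 1e-9)
})

test_that("discounting and mortality move totals in the right direction", {
  lt <- gomp_lt()
  p <- params_with()
  t3 <- trace_totals(run_cohort(p, lt))
  t0 <- trace_totals(run_cohort(
    params_with(annual_discount_rate = 0), lt))
  expect_gt(t0$qaly, t3$qaly)
  expect_gt(t0$cost, t3$cost)
  expect_gt(t0$ly, t3$ly)
  # discounted cycle accruals never exceed undiscounted ones
  expect_true(all(t3$undiscounted$cost >= t3$cost))
  # harsher post-recurrence mortality costs life-years, monotonically
  lys <- vapply(c(0.03, 0.052, 0.1, 0.2), function(d) {
    trace_totals(run_cohort(
      params_with(monthly_metastatic_death_rate = d), lt))$ly
  }, numeric(1))
  expect_true(all(diff(lys) < 0))
})

test_that("traces export and error as documented", {
  lt <- gomp_lt()
  tr <- run_cohort(params_with(), lt, max_months = 24)
  expect_error(model_ddfs(tr, 25), "beyond")
  df <- as.data.frame(tr)
  expect_identical(nrow(df), 25L)
  expect_true(is.na(df$disc_cost[df$month == 0]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  expect_identical(nrow(utils::read.csv(path)), 25L)
  # life table must cover the horizon
  expect_error(run_cohort(params_with(starting_age = 42), life_table(0:80, rep(0.01, 81))),
               "life table ends")
})
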