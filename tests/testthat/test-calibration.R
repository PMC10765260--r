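test_that("closed-form starting rates match the DDFS decrements", {
  tg <- olympia_targets("placebo")
  s <- initial_rates_from_targets(tg)
  expect_equal(s$monthly_rates_y1_4[1], -log(0.903) / 12)
  expect_equal(s$monthly_rates_y1_4[3], -log(0.810 / 0.840) / 12)
  expect_equal(s$monthly_rates_y1_4[1], 0.008503, tolerance = 1e-4)
  so <- initial_rates_from_targets(olympia_targets("olaparib"))
  expect_equal(so$monthly_rates_y1_4[1], -log(0.944) / 12)
  expect_equal(so$monthly_rates_y1_4[1], 0.004802, tolerance = 1e-3)
  # flat targets mean no recurrence
  flat <- calibration_targets("flat", rep(1, 4), rep(1, 4))
  expect_equal(initial_rates_from_targets(flat)$monthly_rates_y1_4, rep(0, 4))
})

test_that("calibration recovers the rates that generated the targets", {
  lt <- gomp_lt()
  truth <- c(0.006, 0.004, 0.003, 0.002)
  p <- params_with(schedule = recurrence_schedule(truth))
  tg <- simulate_trial_targets(recurrence_schedule(truth), p, lt)
  # grid mode: within the grid step of the truth
  rep_g <- calibrate_arm(tg, p, lt, mode = "grid")
  expect_true(rep_g$converged)
  expect_lt(max(abs(rep_g$schedule$monthly_rates_y1_4 - truth)), 1e-4)
  # bisection mode: essentially exact
  rep_b <- calibrate_arm(tg, p, lt, mode = "bisect")
  expect_true(rep_b$converged)
  expect_lt(max(abs(rep_b$schedule$monthly_rates_y1_4 - truth)), 1e-5)
})

test_that("self-consistent targets converge immediately to zero rates", {
  lt <- gomp_lt()
  p <- params_with(schedule = recurrence_schedule(rep(0, 4)))
  tg <- simulate_trial_targets(recurrence_schedule(rep(0, 4)), p, lt)
  rep0 <- calibrate_arm(tg, p, lt, mode = "grid")
  expect_true(rep0$converged)
  expect_equal(rep0$schedule$monthly_rates_y1_4, rep(0, 4))
  expect_lte(rep0$iterations, 20)  # a few bracketing steps per year at most
})

test_that("bisection fit is insensitive to the starting point", {
  lt <- gomp_lt()
  p <- params_with()
  tg <- olympia_targets("placebo")
  from_init <- calibrate_arm(tg, p, lt, mode = "bisect")
  from_zero <- calibrate_arm(tg, p, lt, mode = "bisect",
                             init = recurrence_schedule(rep(0, 4)))
  expect_equal(from_init$schedule$monthly_rates_y1_4,
               from_zero$schedule$monthly_rates_y1_4, tolerance = 1e-6)
})

test_that("calibrated placebo arm reproduces the trial DDFS", {
  bc <- base_case_cache()
  rep_n <- bc$bp$report_no_olaparib
  ddfs_dev <- rep_n$deviations[rep_n$deviations$measure == "ddfs", ]
  expect_true(rep_n$converged)
  expect_lt(abs(ddfs_dev$deviation[ddfs_dev$month == 12]), 1e-3)
  # later-year fits leave the earlier years' DDFS intact
  expect_lt(max(abs(ddfs_dev$deviation)), 1e-3)
})

test_that("parameter recovery holds across random schedules and tables", {
  set.seed(37)
  tables <- list(gomp_lt(),
                 gompertz_life_table(a = 5e-5, b = 0.08),
                 gompertz_life_table(a = 1e-5, b = 0.1, c = 5e-4))
  for (lt in tables) {
    for (i in 1:7) {
      truth <- stats::runif(4, 0.001, 0.02)
      p <- params_with(schedule = recurrence_schedule(truth))
      tg <- simulate_trial_targets(recurrence_schedule(truth), p, lt)
      fit <- calibrate_arm(tg, p, lt, mode = "grid")
      expect_lt(max(abs(fit$schedule$monthly_rates_y1_4 - truth)), 1e-4)
    }
  }
})

test_that("HR-derived olaparib schedule is consistent with the trial", {
  bc <- base_case_cache()
  sched <- treated_schedule_from_placebo(
    bc$bp$no_olaparib$schedule, bc$bp$olaparib$hr)
  p <- structure(modifyList(unclass(bc$bp$olaparib),
                            list(schedule = sched)),
                 class = "model_params")
  tr <- run_cohort(p, bc$lt, max_months = 48)
  expect_lt(abs(model_ddfs(tr, 48) - 0.865), 0.005)
})

test_that("simulated targets are valid and monotone for any input", {
  lt <- gomp_lt()
  p <- params_with()
  tg <- simulate_trial_targets(recurrence_schedule(rep(0, 4)), p, zero_lt())
  expect_equal(unname(tg$ddfs), rep(1, 4))
  expect_equal(unname(tg$os), rep(1, 4))
  set.seed(5)
  for (i in 1:5) {
    tg <- simulate_trial_targets(
      recurrence_schedule(stats::runif(4, 0, 0.05)), p, lt)
    expect_true(all(diff(tg$ddfs) <= 0) && all(diff(tg$os) <= 0))
  }
})

test_that("calibration reports serialize to JSON", {
  lt <- gomp_lt()
  p <- params_with()
  fit <- calibrate_arm(olympia_targets("placebo"), p, lt, mode = "grid")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(fit, path)
  js <- jsonlite::read_json(path)
  expect_identical(js$arm, "placebo")
  expect_length(js$monthly_rates_y1_4, 4)
  expect_true(js$converged)
})
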