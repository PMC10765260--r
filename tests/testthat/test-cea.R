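test_that("incremental comparison arithmetic and flags are right", {
  mk <- function(cost, ly, qaly) list(cost = cost, ly = ly, qaly = qaly)
  r <- compare_strategies(mk(300, 2, 2), mk(100, 1, 1))
  expect_equal(r$d_cost, 200)
  expect_equal(r$icer_qaly, 200)
  expect_equal(r$icer_ly, 200)
  expect_identical(r$status, "icer")
  # identical strategies: zero increments, undefined ICER
  r0 <- compare_strategies(mk(100, 1, 1), mk(100, 1, 1))
  expect_equal(r0$d_cost, 0)
  expect_true(is.na(r0$icer_qaly))
  # dominance flags
  expect_identical(compare_strategies(mk(50, 2, 2), mk(100, 1, 1))$status,
                   "dominant")
  expect_identical(compare_strategies(mk(200, 1, 1), mk(100, 2, 2))$status,
                   "dominated")
})

test_that("one-way sensitivity bars behave as documented", {
  bc <- base_case_cache()
  ranges <- data.frame(
    parameter = c("monthly_drug_cost", "hazard_ratio",
                  "utility_no_recurrence"),
    low = c(10892, 0.48, 0.735),
    high = c(18154, 0.77, 1))
  torn <- one_way_sa(bc$bp, bc$lt, ranges)
  expect_s3_class(torn, "tornado")
  expect_true(all(diff(torn$width) <= 0))
  # higher drug cost always worsens the ICER; better utility improves it
  dr <- torn[torn$parameter == "monthly_drug_cost", ]
  expect_gt(dr$icer_high, dr$icer_low)
  ut <- torn[torn$parameter == "utility_no_recurrence", ]
  expect_lt(ut$icer_high, ut$icer_low)
  # degenerate range gives a zero-width bar
  deg <- one_way_sa(bc$bp, bc$lt,
                    data.frame(parameter = "monthly_drug_cost",
                               low = 14523, high = 14523))
  expect_equal(deg$width, 0)
  expect_error(one_way_sa(bc$bp, bc$lt,
                          data.frame(parameter = "nope", low = 1, high = 2)),
               "unknown parameter")
})

test_that("ICER is strictly increasing in the monthly drug cost", {
  bc <- base_case_cache()
  icers <- vapply(c(8000, 12000, 14523, 18000, 22000), function(v) {
    olaparibCEA:::.icer_at(bc$bp, bc$lt, "monthly_drug_cost", v)
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("threshold search inverts the ICER to within a dollar", {
  bc <- base_case_cache()
  base_icer <- bc$res$icer_qaly
  # a threshold at the base-case ICER returns the base value
  v <- threshold_search("monthly_drug_cost", base_icer, c(10892, 18154),
                        bc$bp, bc$lt)
  expect_equal(v, 14523, tolerance = 1e-3)
  # the crossing value reproduces the target ICER when plugged back
  v <- threshold_search("monthly_drug_cost", 150000, c(10892, 25000),
                        bc$bp, bc$lt)
  expect_lt(abs(olaparibCEA:::.icer_at(bc$bp, bc$lt,
                                       "monthly_drug_cost", v) - 150000), 1)
  expect_error(threshold_search("monthly_drug_cost", 1e7, c(10892, 18154),
                                bc$bp, bc$lt), "does not cross")
})

test_that("fitted distributions match their closed forms", {
  # hazard ratio: log-normal read off the 95% CI
  ln <- fit_distribution(0.61, 0.48, 0.77, "lognormal")
  expect_equal(ln$pars$meanlog, log(0.61))
  expect_equal(ln$pars$sdlog, (log(0.77) - log(0.48)) / (2 * 1.96))
  expect_equal(ln$pars$sdlog, 0.1206, tolerance = 1e-3)
  ci <- exp(ln$pars$meanlog + c(-1.96, 1.96) * ln$pars$sdlog)
  expect_equal(ci, c(0.482, 0.773), tolerance = 1e-3)
  # metastatic utility: beta with SE from the lower bound
  be <- fit_distribution(0.55, 0.413, 0.688, "beta")
  m <- be$pars$shape1 / (be$pars$shape1 + be$pars$shape2)
  v <- m * (1 - m) / (be$pars$shape1 + be$pars$shape2 + 1)
  expect_equal(m, 0.55)
  expect_equal(sqrt(v), (0.55 - 0.413) / 1.96, tolerance = 1e-10)
  # degenerate range collapses to a point mass
  fx <- fit_distribution(10, 10, 10, "gamma")
  expect_identical(fx$family, "fixed")
  expect_identical(draw_distribution(fx, 3), rep(10, 3))
  expect_error(fit_distribution(5, 6, 7), "low <= base")
})

test_that("distribution means and draws match the base-case values", {
  specs <- default_psa_specs()
  expect_named(specs)
  rg <- default_sa_ranges()
  set.seed(99)
  for (nm in names(specs)) {
    base <- rg$base[rg$parameter == nm]
    expect_lt(abs(distribution_mean(specs[[nm]]) - base) / base, 0.02)
    x <- draw_distribution(specs[[nm]], 2e5)
    expect_lt(abs(mean(x) - base) / base, 0.01)
    expect_true(all(x >= 0))
  }
  # the utility multiplier never exceeds 1
  mult <- draw_distribution(specs$olaparib_utility_multiplier, 1e4)
  expect_true(all(mult >= 0.8 & mult <= 1))
})
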