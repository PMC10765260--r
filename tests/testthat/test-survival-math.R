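test_that("rate/probability conversions match closed forms", {
  expect_identical(rate_to_prob(0, 12), 0)
  expect_equal(rate_to_prob(log(2), 1), 0.5)
  # 13.3 months is approximately the median under the metastatic death rate
  expect_equal(rate_to_prob(0.052, 13.3), 1 - exp(-0.052 * 13.3))
  expect_equal(rate_to_prob(0.052, 13.3), 0.499, tolerance = 0.002)

  expect_identical(prob_to_rate(0, 12), 0)
  # year-1 recurrence rate from 90.3% 12-month DDFS
  expect_equal(prob_to_rate(1 - 0.903, 12), -log(0.903) / 12)
  expect_equal(prob_to_rate(0.097, 12), 0.008503, tolerance = 1e-4)
})

test_that("rate and probability transforms are mutual inverses", {
  p <- c(0.1, 0.5, 0.9, seq(0.001, 0.999, length.out = 40))
  for (t in c(1, 12, 13.3)) {
    expect_equal(rate_to_prob(prob_to_rate(p, t), t), p, tolerance = 1e-12)
  }
  r <- c(1e-6, 0.0085, 0.052, 0.5)  # p(12 mo) up to ~0.998
  expect_equal(prob_to_rate(rate_to_prob(r, 12), 12), r, tolerance = 1e-12)
})

test_that("rate_to_prob is monotone and bounded", {
  r <- seq(0, 2, length.out = 50)
  p <- rate_to_prob(r, 6)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(rate_to_prob(0.05, c(1, 6, 12, 60))) > 0))
})

test_that("conversion domain errors are raised", {
  expect_error(rate_to_prob(-0.1, 1), "non-negative")
  expect_error(rate_to_prob(0.1, 0), "positive")
  expect_error(prob_to_rate(1, 12), "infinite")
  expect_error(prob_to_rate(1.2, 12), "\\[0, 1\\]")
  expect_error(median_survival_to_rate(0), "positive")
})

test_that("median survival converts to the published monthly death rate", {
  expect_equal(round(median_survival_to_rate(13.3), 3), 0.052)
  expect_equal(median_survival_to_rate(log(2)), 1)
  # halving the median doubles the rate
  expect_equal(median_survival_to_rate(6.65),
               2 * median_survival_to_rate(13.3))
  expect_equal(round(median_survival_to_rate(6.65), 3), 0.104)
})

test_that("hazard-ratio application is proportional on the rate scale", {
  expect_equal(apply_hazard_ratio(0.0085, 1), 0.0085)
  expect_identical(apply_hazard_ratio(0, 0.61), 0)
  expect_error(apply_hazard_ratio(0.01, 0), "positive")
  r <- c(0.001, 0.0085, 0.02)
  expect_true(all(apply_hazard_ratio(r, 0.61) < r))
  # scaling the cumulative 48-month placebo DDFS hazard by the trial HR
  # lands within 0.3 pp of the olaparib arm's printed 48-month DDFS
  s <- exp(-apply_hazard_ratio(-log(0.791), 0.61))
  expect_lt(abs(s - 0.865), 0.003)
})

test_that("hazard_ratio objects enforce CI ordering", {
  hr <- hazard_ratio(0.61, 0.48, 0.77)
  expect_s3_class(hr, "hazard_ratio")
  expect_error(hazard_ratio(0.61, 0.7, 0.77), "ci_low")
  expect_error(hazard_ratio(0.9, 0.48, 0.77), "ci_low")
  expect_equal(apply_hazard_ratio(0.01, hr), 0.0061)
})

test_that("competing risks apportion the total event probability", {
  # a single live cause reduces to the marginal conversion
  cr <- competing_risk_probs(c(0.0085, 0), 1)
  expect_equal(cr$event[1], rate_to_prob(0.0085, 1))
  expect_identical(cr$event[2], 0)
  # symmetric causes split the event mass equally
  cr <- competing_risk_probs(c(0.05, 0.05), 1)
  expect_equal(cr$event[1], cr$event[2])
  expect_equal(sum(cr$event), rate_to_prob(0.1, 1))
  # closed form for the metastatic state's two exits
  cr <- competing_risk_probs(c(0.052, 0.001), 1)
  expect_equal(cr$event[1], (0.052 / 0.053) * (1 - exp(-0.053)))
  expect_error(competing_risk_probs(c(0.05, -0.01)), "non-negative")
})

test_that("competing-risk probabilities and stay term always sum to one", {
  set.seed(42)
  for (i in 1:25) {
    rates <- stats::runif(sample(1:5, 1), 0, 0.5)
    cr <- competing_risk_probs(rates, t = stats::runif(1, 0.1, 24))
    expect_equal(sum(cr$event) + cr$stay, 1, tolerance = 1e-12)
    expect_true(all(cr$event >= 0) && cr$stay >= 0)
  }
  # zero rates: nothing happens
  cr <- competing_risk_probs(c(0, 0), 1)
  expect_identical(cr$stay, 1)
})
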