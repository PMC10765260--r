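#' Convert a constant hazard rate to an event probability
#'
#' Under a constant (exponential) hazard, the probability of an event within
#' `t` time units is `1 - exp(-rate * t)`. Used throughout the model to turn
#' monthly transition rates into monthly cycle probabilities.
#'
#' @param rate Non-negative hazard rate (events per unit time, here month^-1).
#'   Vectorised.
#' @param t Positive duration, in the same time unit as `rate`.
#' @return Event probability in `[0, 1)`.
#' @examples
#' rate_to_prob(0.052, 13.3)  # ~0.5: 13.3 months is the median at this rate
#' @seealso [prob_to_rate()] for the inverse transform.
#' @export
rate_to_prob <- function(rate, t = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be finite and positive", call. = FALSE)
  }
  -expm1(-rate * t)
}

#' Convert an event probability to a constant hazard rate
#'
#' Inverse of [rate_to_prob()]: the constant rate that yields probability `p`
#' over duration `t` is `-log(1 - p) / t`.
#'
#' @param p Probability in `[0, 1)`. Vectorised.
#' @param t Positive duration.
#' @return Hazard rate per unit time.
#' @examples
#' prob_to_rate(1 - 0.903, 12)  # monthly recurrence rate from 90.3% 1-y DDFS
#' @export
prob_to_rate <- function(p, t = 1) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  if (any(p == 1)) {
    stop("`p` = 1 implies an infinite rate", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be finite and positive", call. = FALSE)
  }
  -log1p(-p) / t
}

#' Constant death rate implied by a median survival
#'
#' Under exponential survival, `S(median) = 1/2`, so the rate is
#' `log(2) / median`. The model's monthly rate of death after metastatic
#' recurrence (0.052) comes from a published 13.3-month median survival in
#' metastatic triple-negative breast cancer.
#'
#' @param median Positive median survival time (months).
#' @return Death rate per month.
#' @examples
#' median_survival_to_rate(13.3)  # 0.052 to 3 decimals
#' @export
median_survival_to_rate <- function(median) {
  if (any(!is.finite(median)) || any(median <= 0)) {
    stop("`median` must be finite and positive", call. = FALSE)
  }
  log(2) / median
}

#' Apply a hazard ratio to a rate
#'
#' Proportional hazards on the rate scale: the treated rate is `rate * hr`.
#' Probabilities are derived afterwards via [rate_to_prob()].
#'
#' @param rate Non-negative baseline rate. Vectorised.
#' @param hr Positive hazard ratio (a number or a [hazard_ratio()] object,
#'   whose point estimate is used).
#' @return Scaled rate.
#' @export
apply_hazard_ratio <- function(rate, hr) {
  if (inherits(hr, "hazard_ratio")) hr <- hr$point
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("`hr` must be a single positive number", call. = FALSE)
  }
  rate * hr
}

#' Competing-risk event probabilities under constant hazards
#'
#' With several causes acting simultaneously at constant rates, the total
#' event probability over `t` is `1 - exp(-t * sum(rates))`, apportioned to
#' cause `k` proportionally to `rates[k] / sum(rates)`. The cause-specific
#' probabilities plus the stay probability sum to one; the result does not
#' depend on any ordering of causes.
#'
#' @param rates Numeric vector of non-negative cause-specific rates.
#' @param t Positive duration.
#' @return A list with `event`, the vector of cause-specific probabilities
#'   (named as `rates`), and `stay`, the probability of no event.
#' @examples
#' competing_risk_probs(c(recurrence = 0.0085, other_death = 0.0001), t = 1)
#' @export
competing_risk_probs <- function(rates, t = 1) {
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all `rates` must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(t) || t <= 0) {
    stop("`t` must be finite and positive", call. = FALSE)
  }
  total <- sum(rates)
  if (total == 0) {
    event <- rates * 0
  } else {
    event <- -expm1(-total * t) * rates / total
  }
  list(event = event, stay = 1 - sum(event))
}

#' Hazard ratio with confidence interval
#'
#' Container for a treatment-effect hazard ratio and its 95% CI. The base-case
#' effect of adjuvant olaparib on distant recurrence is the stratified trial
#' hazard ratio 0.61 (95% CI 0.48-0.77).
#'
#' @param point Point estimate, positive.
#' @param ci_low,ci_high 95% confidence bounds with
#'   `0 < ci_low <= point <= ci_high`.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(point = 0.61, ci_low = 0.48, ci_high = 0.77) {
  stopifnot(is.numeric(point), is.numeric(ci_low), is.numeric(ci_high),
            length(point) == 1L, length(ci_low) == 1L, length(ci_high) == 1L)
  if (!(ci_low > 0 && ci_low <= point && point <= ci_high)) {
    stop("need 0 < ci_low <= point <= ci_high", call. = FALSE)
  }
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("Hazard ratio %.3g (95%% CI %.3g-%.3g)\n",
              x$point, x$ci_low, x$ci_high))
  invisible(x)
}
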