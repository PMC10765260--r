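#' Fit a parameter distribution from base value and range
#'
#' Builds the second-order distribution for one model input from its
#' base-case value and (low, high) range, following the conventions of the
#' probabilistic analysis: the standard error is taken from the lower bound,
#' `SE = (base - low) / 1.96` (the published ranges are asymmetric), and
#'
#' * `gamma` (costs): moment-matched to mean `base` and that SE;
#' * `beta` (utilities, post-recurrence death rate): moment-matched likewise;
#' * `lognormal` (hazard ratio): `meanlog = log(base)`,
#'   `sdlog = (log(high) - log(low)) / (2 * 1.96)`, so the range is read as a
#'   95% CI;
#' * `beta_scaled` (utility multiplier): a beta moment-matched on the
#'   rescaled `[low, high]` interval, so draws never leave the range (in
#'   particular the multiplier never exceeds 1);
#' * `fixed`: point mass at `base` (used when `low == high == base`).
#'
#' @param base Base-case value with `low <= base <= high`.
#' @param low,high Range bounds.
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"beta_scaled"`,
#'   `"fixed"`.
#' @return A `distribution_spec`: list with `family`, fitted `pars`, and the
#'   `base`, `low`, `high` inputs. Its fitted mean equals `base` for the
#'   moment-matched families.
#' @export
fit_distribution <- function(base, low, high,
                             family = c("beta", "gamma", "lognormal",
                                        "beta_scaled", "fixed")) {
  family <- match.arg(family)
  if (!(low <= base && base <= high)) {
    stop("need low <= base <= high", call. = FALSE)
  }
  if (low == high || family == "fixed") {
    return(structure(list(family = "fixed", pars = list(value = base),
                          base = base, low = low, high = high),
                     class = "distribution_spec"))
  }
  se <- (base - low) / 1.96
  pars <- switch(family,
    gamma = {
      if (se <= 0) stop("gamma needs base > low", call. = FALSE)
      list(shape = base^2 / se^2, rate = base / se^2)
    },
    beta = {
      if (se <= 0) stop("beta needs base > low", call. = FALSE)
      v <- se^2
      if (v >= base * (1 - base)) {
        stop("beta variance too large for mean ", base, call. = FALSE)
      }
      k <- base * (1 - base) / v - 1
      list(shape1 = base * k, shape2 = (1 - base) * k)
    },
    beta_scaled = {
      m <- (base - low) / (high - low)
      v <- (se / (high - low))^2
      if (v <= 0 || v >= m * (1 - m)) {
        stop("scaled beta variance incompatible with mean", call. = FALSE)
      }
      k <- m * (1 - m) / v - 1
      list(shape1 = m * k, shape2 = (1 - m) * k)
    },
    lognormal = {
      if (low <= 0) stop("lognormal needs low > 0", call. = FALSE)
      list(meanlog = log(base), sdlog = (log(high) - log(low)) / (2 * 1.96))
    }
  )
  structure(list(family = family, pars = pars,
                 base = base, low = low, high = high),
            class = "distribution_spec")
}

#' Draw from a fitted parameter distribution
#'
#' @param spec A `distribution_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_distribution <- function(spec, n) {
  stopifnot(inherits(spec, "distribution_spec"), n >= 1)
  p <- spec$pars
  switch(spec$family,
    fixed = rep(p$value, n),
    gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
    beta = stats::rbeta(n, p$shape1, p$shape2),
    beta_scaled = spec$low +
      (spec$high - spec$low) * stats::rbeta(n, p$shape1, p$shape2),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog)
  )
}

#' Mean of a fitted parameter distribution
#'
#' @param spec A `distribution_spec`.
#' @return The analytic mean.
#' @export
distribution_mean <- function(spec) {
  p <- spec$pars
  switch(spec$family,
    fixed = p$value,
    gamma = p$shape / p$rate,
    beta = p$shape1 / (p$shape1 + p$shape2),
    beta_scaled = spec$low + (spec$high - spec$low) *
      p$shape1 / (p$shape1 + p$shape2),
    lognormal = exp(p$meanlog + p$sdlog^2 / 2)
  )
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("%s distribution, base %.4g (range %.4g-%.4g); pars: %s\n",
              x$family, x$base, x$low, x$high,
              paste(names(x$pars), signif(unlist(x$pars), 5),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Default probabilistic-analysis distributions
#'
#' Fits the [fit_distribution()] family stated in [default_sa_ranges()] for
#' every input with one (the discount rate has none and stays fixed).
#'
#' @return Named list of `distribution_spec` objects.
#' @export
default_psa_specs <- function() {
  rg <- default_sa_ranges()
  rg <- rg[!is.na(rg$distribution), ]
  specs <- lapply(seq_len(nrow(rg)), function(i) {
    fit_distribution(rg$base[i], rg$low[i], rg$high[i], rg$distribution[i])
  })
  stats::setNames(specs, rg$parameter)
}
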