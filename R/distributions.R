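#' Method-of-moments sampling distributions for model parameters
#'
#' Converts a `(mean, sd)` specification into the hyperparameters of the
#' distribution family assigned to that parameter class: gamma for costs
#' (shape = (mean/sd)^2, rate = mean/sd^2), beta for probabilities and
#' utilities (a = mean * nu, b = (1 - mean) * nu with nu chosen to match the
#' SD), normal for the CVC insertion-cycle quantities, and median-centred
#' lognormal or Gompertz for the survival medians. For the moment-matched
#' families the resulting distribution reproduces the target mean exactly
#' and the target SD to numerical precision. `sd = 0` yields a point mass.
#'
#' For `"lognormal-median"` the parameter is the median survival time; the
#' log-scale spread is solved from the coefficient of variation so the
#' distribution mean still equals `mean`. For `"gompertz-median"` the median
#' is re-expressed through a Gompertz (shape, rate) pair via
#' [gompertz_rate_for_median()] and draws perturb both parameters
#' multiplicatively with the requested coefficient of variation, recomputing
#' the median; this family is median-centred rather than moment-matched.
#'
#' @param mean Target mean (for the median families, the target median).
#' @param sd Target standard deviation; `0` gives a degenerate point mass.
#' @param family One of `"gamma"`, `"beta"`, `"normal"`,
#'   `"lognormal-median"`, `"gompertz-median"`.
#' @param shape Gompertz shape parameter used by `"gompertz-median"`
#'   (per-year log-hazard slope).
#' @return An object of class `vad_dist`: list with `family`, `pars`,
#'   `mean`, `sd`.
#' @examples
#' d <- derive_sampling_distribution(68.0747, 43.2521, "gamma")
#' d$pars$shape # ~2.477
#' @export
derive_sampling_distribution <- function(mean, sd,
                                         family = c("gamma", "beta", "normal",
                                                    "lognormal-median",
                                                    "gompertz-median"),
                                         shape = 1) {
  family <- match.arg(family)
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sd, "sd", lower = 0)
  if (sd == 0) {
    return(structure(list(family = "point", pars = list(value = mean),
                          mean = mean, sd = 0), class = "vad_dist"))
  }
  pars <- switch(family,
    gamma = {
      if (mean <= 0) stop_vad("gamma requires a positive mean")
      list(shape = (mean / sd)^2, rate = mean / sd^2)
    },
    beta = {
      if (mean <= 0 || mean >= 1) {
        stop_vad("beta requires mean strictly inside (0, 1)")
      }
      nu <- mean * (1 - mean) / sd^2 - 1
      if (nu <= 0) {
        stop_vad("beta SD ", sd, " is infeasible for mean ", mean,
                 " (requires sd^2 < mean * (1 - mean))")
      }
      list(a = mean * nu, b = (1 - mean) * nu)
    },
    normal = list(mean = mean, sd = sd),
    `lognormal-median` = {
      if (mean <= 0) stop_vad("lognormal-median requires a positive median")
      cv <- sd / mean
      sdlog <- sqrt(log(1 + cv^2))
      list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    `gompertz-median` = {
      if (mean <= 0) stop_vad("gompertz-median requires a positive median")
      list(shape = shape, rate = gompertz_rate_for_median(shape, mean),
           cv = sd / mean)
    }
  )
  structure(list(family = family, pars = pars, mean = mean, sd = sd),
            class = "vad_dist")
}

#' Draw random values from a derived sampling distribution
#'
#' @param dist A `vad_dist` object from [derive_sampling_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(dist, n) {
  stopifnot(inherits(dist, "vad_dist"))
  p <- dist$pars
  switch(dist$family,
    point = rep(p$value, n),
    gamma = rgamma(n, shape = p$shape, rate = p$rate),
    beta = rbeta(n, p$a, p$b),
    normal = rnorm(n, p$mean, p$sd),
    `lognormal-median` = rlnorm(n, p$meanlog, p$sdlog),
    `gompertz-median` = {
      a <- p$shape * pmax(1 + p$cv * rnorm(n), 1e-6)
      b <- p$rate * pmax(1 + p$cv * rnorm(n), 1e-6)
      gompertz_median(a, b)
    },
    stop_vad("unknown distribution family: ", dist$family)
  )
}

#' Gompertz median survival time and its inverse
#'
#' Under the (shape `a`, rate `b`) parameterisation with survivor function
#' `S(t) = exp(-(b/a) * (exp(a * t) - 1))`, the median is
#' `t50 = log(1 + a * log(2) / b) / a`. `gompertz_rate_for_median()` solves
#' the rate from a target median at fixed shape,
#' `b = a * log(2) / (exp(a * t50) - 1)`. Both fall back to the exponential
#' limit as `a -> 0`.
#'
#' @param shape Gompertz shape (per year); may be negative, but a negative
#'   shape admits no finite median when `b/|a| < log(2)` (an error).
#' @param rate Gompertz rate (per year), positive.
#' @param median Target median survival time in years.
#' @return Median time in years, or the rate reproducing `median`.
#' @export
gompertz_median <- function(shape, rate) {
  stopifnot(all(rate > 0))
  out <- ifelse(abs(shape) < 1e-12,
                log(2) / rate,
                log1p(shape * log(2) / rate) / shape)
  if (any(!is.finite(out) | out <= 0)) {
    stop_vad("Gompertz parameters admit no finite median ",
             "(need b/|a| > log(2) when the shape is negative)")
  }
  out
}

#' @rdname gompertz_median
#' @export
gompertz_rate_for_median <- function(shape, median) {
  stopifnot(all(median > 0))
  ifelse(abs(shape) < 1e-12,
         log(2) / median,
         shape * log(2) / expm1(shape * median))
}
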