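#' Fit a parametric survival model to catheter dwell times
#'
#' Maximum-likelihood fit with right-censoring (censored observations
#' contribute `log S(t)`, events `log f(t)`) for one of the exponential,
#' Weibull, lognormal or Gompertz families, via [flexsurv::flexsurvreg()].
#' The fitted median solves `S(t) = 0.5` under the fitted parameters.
#'
#' @param times Positive observation times (years).
#' @param events Event indicator: logical/0-1 vector, or a character vector
#'   with `"removal"` as the event and `"censored"` otherwise (the cohort
#'   table convention).
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"gompertz"`.
#' @return An object of class `vad_survfit`: list with `family`, `params`
#'   (named natural-scale estimates), `loglik`, `AIC`, `median`, `n`,
#'   `n_events`, and the underlying `flexsurvreg` fit in `fit`. Requires at
#'   least ten uncensored events; an all-censored or degenerate input is an
#'   error, as is optimizer non-convergence (the error carries the
#'   diagnostics).
#' @examples
#' t <- rexp(200, rate = 2)
#' f <- fit_parametric(t, rep(TRUE, 200), "exponential")
#' f$median # ~ log(2)/2
#' @export
fit_parametric <- function(times, events,
                           family = c("exponential", "weibull", "lognormal",
                                      "gompertz")) {
  family <- match.arg(family)
  ev <- as_event_indicator(events)
  if (length(times) != length(ev)) {
    stop_vad("times and events must have the same length")
  }
  keep <- !is.na(times) & !is.na(ev)
  times <- times[keep]; ev <- ev[keep]
  if (any(times <= 0)) stop_vad("all observation times must be positive")
  if (sum(ev) < 10) {
    stop_vad("at least 10 uncensored events are required (got ", sum(ev), ")",
             class = "vadcea_precondition_error")
  }
  dist <- c(exponential = "exp", weibull = "weibull", lognormal = "lnorm",
            gompertz = "gompertz")[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(times, ev) ~ 1, dist = dist),
    error = function(e) {
      stop_vad("parametric fit failed for family '", family, "': ",
               conditionMessage(e), class = "vadcea_convergence_error")
    }
  )
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0) {
    stop_vad("optimizer did not converge for family '", family,
             "' (code ", fit$opt$convergence, ")",
             class = "vadcea_convergence_error")
  }
  pars <- setNames(fit$res[, "est"], rownames(fit$res))
  structure(
    list(
      family = family,
      params = pars,
      loglik = as.numeric(fit$loglik),
      AIC = as.numeric(fit$AIC),
      median = survfit_median(family, pars),
      n = length(times),
      n_events = sum(ev),
      data_id = survdata_id(times, ev),
      fit = fit
    ),
    class = "vad_survfit"
  )
}

as_event_indicator <- function(events) {
  if (is.character(events) || is.factor(events)) {
    as.integer(as.character(events) == "removal")
  } else {
    as.integer(as.logical(events))
  }
}

survdata_id <- function(times, ev) {
  c(n = length(times), n_events = sum(ev), t_sum = sum(times))
}

survfit_median <- function(family, pars) {
  switch(family,
    exponential = log(2) / pars[["rate"]],
    weibull = stats::qweibull(0.5, pars[["shape"]], pars[["scale"]]),
    lognormal = stats::qlnorm(0.5, pars[["meanlog"]], pars[["sdlog"]]),
    gompertz = gompertz_median(pars[["shape"]], pars[["rate"]])
  )
}

n_params <- function(family) {
  c(exponential = 1L, weibull = 2L, lognormal = 2L, gompertz = 2L)[[family]]
}

#' Survivor and density functions of a fitted model
#'
#' @param object A `vad_survfit`.
#' @param t Times (years).
#' @return Numeric vector of `S(t)` or `f(t)`.
#' @export
surv_prob <- function(object, t) {
  stopifnot(inherits(object, "vad_survfit"))
  p <- object$params
  switch(object$family,
    exponential = stats::pexp(t, p[["rate"]], lower.tail = FALSE),
    weibull = stats::pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]],
                                   lower.tail = FALSE)
  )
}

#' @rdname surv_prob
#' @export
surv_dens <- function(object, t) {
  stopifnot(inherits(object, "vad_survfit"))
  p <- object$params
  switch(object$family,
    exponential = stats::dexp(t, p[["rate"]]),
    weibull = stats::dweibull(t, p[["shape"]], p[["scale"]]),
    lognormal = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    gompertz = flexsurv::dgompertz(t, p[["shape"]], p[["rate"]])
  )
}

#' Select the best-fitting family by AIC
#'
#' Compares fits of different families on identical data and returns the
#' family with the smallest AIC; exact ties are broken toward the family
#' with fewer parameters. Fits over different data are an error.
#'
#' @param fits List of `vad_survfit` objects.
#' @return The winning family name (character), with the full AIC ranking in
#'   attribute `"ranking"`.
#' @export
select_family <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "vad_survfit")))
  ids <- vapply(fits, \(f) paste(signif(f$data_id, 12), collapse = "|"),
                character(1))
  if (length(unique(ids)) != 1) {
    stop_vad("fits were made on different data; AIC is not comparable",
             class = "vadcea_data_mismatch_error")
  }
  ranking <- tibble::tibble(
    family = vapply(fits, `[[`, character(1), "family"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    k = vapply(vapply(fits, `[[`, character(1), "family"), n_params,
               integer(1))
  ) |> arrange(.data$AIC, .data$k)
  structure(ranking$family[1], ranking = ranking)
}

#' Kaplan-Meier estimate with median
#'
#' Product-limit estimator (through [survival::survfit()]) returned as a
#' tidy step function; the median is the first time at which the estimated
#' survivor function drops to 0.5 or below, `NA` (flagged) if the curve
#' never reaches it.
#'
#' @inheritParams fit_parametric
#' @return List of class `vad_km`: `steps` (tibble `time`, `n_risk`,
#'   `n_event`, `surv`), `median`, `median_defined`.
#' @export
km_estimate <- function(times, events) {
  ev <- as_event_indicator(events)
  stopifnot(length(times) == length(ev), length(times) >= 1)
  sf <- survival::survfit(survival::Surv(times, ev) ~ 1)
  steps <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                          n_event = sf$n.event, surv = sf$surv)
  below <- steps$time[steps$surv <= 0.5 & steps$n_event > 0]
  med <- if (length(below) > 0) min(below) else NA_real_
  structure(list(steps = steps, median = med,
                 median_defined = !is.na(med)),
            class = "vad_km")
}

#' @export
print.vad_survfit <- function(x, ...) {
  cat("<vad_survfit>", x$family, "fit on", x$n, "observations (",
      x$n_events, "events )\n")
  cat("  loglik", format(x$loglik), " AIC", format(x$AIC),
      " median", format(x$median), "years\n")
  invisible(x)
}

#' Tidy a fitted parametric survival model
#'
#' @param x A `vad_survfit`.
#' @param ... Unused.
#' @return `tidy()`: tibble of natural-scale parameter estimates with
#'   standard errors; `glance()`: one-row model summary (family, loglik,
#'   AIC, median, n, events).
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.vad_survfit <- function(x, ...) {
  res <- x$fit$res
  tibble::tibble(term = rownames(res), estimate = res[, "est"],
                 std.error = res[, "se"])
}

#' @rdname tidy.vad_survfit
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.vad_survfit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, AIC = x$AIC,
                 median = x$median, n = x$n, n_events = x$n_events)
}

#' @export
generics::tidy

#' @export
generics::glance
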