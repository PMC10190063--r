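#' Plot helpers for analysis results
#'
#' `plot_tornado()` draws the ranked one-way sensitivity bars,
#' `plot_ceac()` the cost-effectiveness acceptability curves, and
#' `plot_psa_scatter()` the incremental cost-effectiveness plane. Each is
#' also reachable through `ggplot2::autoplot()` on the corresponding result
#' class.
#'
#' @param x A `vad_tornado`, `vad_ceac` or `vad_scatter` object.
#' @param top Number of parameters shown in the tornado (default 15).
#' @return A ggplot object.
#' @name vadcea-plots
NULL

#' @rdname vadcea-plots
#' @export
plot_tornado <- function(x, top = 15) {
  stopifnot(inherits(x, "vad_tornado"))
  base <- attr(x, "icer_base")
  pair <- attr(x, "pair")
  d <- x |>
    utils::head(top) |>
    mutate(key = factor(.data$key, levels = rev(.data$key)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$key)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$key),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = paste0("ICER ", pair[1], " vs ", pair[2],
                             " (USD/QALY)"),
                  y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @rdname vadcea-plots
#' @export
plot_ceac <- function(x) {
  stopifnot(inherits(x, "vad_ceac"))
  ggplot2::ggplot(x, ggplot2::aes(.data$wtp, .data$probability,
                                  colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability optimal", colour = "Device",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' @rdname vadcea-plots
#' @export
plot_psa_scatter <- function(x) {
  stopifnot(inherits(x, "vad_scatter"))
  ref <- attr(x, "reference")
  d <- x |> filter(.data$comparator != ref)
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_qaly, .data$delta_cost,
                                  colour = .data$comparator)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = paste("Incremental QALYs vs", ref),
                  y = paste("Incremental cost vs", ref, "(USD)"),
                  colour = "Device",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @rdname vadcea-plots
#' @param object Result object.
#' @param ... Passed through.
#' @exportS3Method ggplot2::autoplot
autoplot.vad_tornado <- function(object, ...) plot_tornado(object, ...)

#' @rdname vadcea-plots
#' @exportS3Method ggplot2::autoplot
autoplot.vad_ceac <- function(object, ...) plot_ceac(object)

#' @rdname vadcea-plots
#' @exportS3Method ggplot2::autoplot
autoplot.vad_scatter <- function(object, ...) plot_psa_scatter(object)

#' Survival curve of a fitted parametric model
#'
#' Overlays the fitted survivor function on the Kaplan-Meier estimate of the
#' data it was fitted to.
#'
#' @param object A `vad_survfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vad_survfit <- function(object, ...) {
  km <- km_estimate(object$fit$data$Y[, "time"],
                    object$fit$data$Y[, "status"])
  tmax <- max(km$steps$time)
  grid <- seq(0, tmax, length.out = 200)
  fitted <- tibble::tibble(time = grid, surv = surv_prob(object, grid))
  ggplot2::ggplot() +
    ggplot2::geom_step(data = km$steps,
                       ggplot2::aes(.data$time, .data$surv),
                       colour = "grey40") +
    ggplot2::geom_line(data = fitted,
                       ggplot2::aes(.data$time, .data$surv),
                       colour = "firebrick") +
    ggplot2::labs(x = "Years", y = "S(t)",
                  title = paste("Fitted", object$family, "survival")) +
    ggplot2::theme_minimal()
}
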