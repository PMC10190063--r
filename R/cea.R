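#' Cost-effectiveness ratio of an arm outcome
#'
#' @param outcome One-row outcome tibble (or any list with `cost` and
#'   `qaly`), e.g. from [evaluate_arm()].
#' @return Cost per QALY in USD/QALY. Zero QALYs is an error.
#' @export
cer <- function(outcome) {
  if (any(outcome$qaly <= 0)) {
    stop_vad("CER is undefined for nonpositive QALYs")
  }
  outcome$cost / outcome$qaly
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Compares arm `a` against arm `b`: the ICER
#' `(cost_a - cost_b) / (qaly_a - qaly_b)` is reported when both increments
#' have the same sign (the ratio is identical whichever arm is listed
#' first). When one arm is cheaper *and* more effective the comparison is
#' settled by dominance and no ratio is reported; identical outcomes give an
#' undefined-ICER flag rather than an error.
#'
#' @param a,b One-row outcome tibbles with `arm`, `cost`, `qaly`.
#' @param wtp Willingness-to-pay threshold used for the decision column.
#' @return One-row tibble: `arm1`, `arm2`, `delta_cost`, `delta_qaly`,
#'   `icer`, `dominance` (`"none"`, `"arm1-dominant"`, `"arm2-dominant"`,
#'   `"undefined"`), `decision_at_wtp`.
#' @export
icer <- function(a, b, wtp = NULL) {
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  dominance <- "none"
  ratio <- NA_real_
  if (dc == 0 && dq == 0) {
    dominance <- "undefined"
  } else if (dc <= 0 && dq >= 0) {
    dominance <- "arm1-dominant"
  } else if (dc >= 0 && dq <= 0) {
    dominance <- "arm2-dominant"
  } else {
    ratio <- dc / dq
  }
  decision <- NA_character_
  if (!is.null(wtp)) {
    nmb <- wtp * c(a$qaly, b$qaly) - c(a$cost, b$cost)
    pick <- if (nmb[1] == nmb[2]) which.min(c(a$cost, b$cost)) else
      which.max(nmb)
    decision <- c(a$arm, b$arm)[pick]
  }
  tibble::tibble(arm1 = a$arm, arm2 = b$arm, delta_cost = dc,
                 delta_qaly = dq, icer = ratio, dominance = dominance,
                 decision_at_wtp = decision)
}

#' Recommend an arm by net monetary benefit
#'
#' The strategy maximising `wtp * qaly - cost` is optimal at that
#' willingness-to-pay; on non-dominated frontiers this agrees with walking
#' the ICER ladder against the threshold. Ties go to the cheaper arm.
#'
#' @param outcomes Outcome tibble with one row per arm (same dwell).
#' @param wtp Willingness-to-pay in USD/QALY.
#' @return The recommended arm name.
#' @export
recommend_device <- function(outcomes, wtp) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) >= 2)
  assert_scalar_number(wtp, "wtp", lower = 0)
  nmb <- wtp * outcomes$qaly - outcomes$cost
  best <- which(nmb == max(nmb))
  if (length(best) > 1) best <- best[which.min(outcomes$cost[best])]
  outcomes$arm[best]
}

#' Cost-utility table across arms and dwell scenarios
#'
#' Adds CERs and the pairwise incremental comparisons (PICC vs CVC, IVAP vs
#' PICC, IVAP vs CVC) to a scenario outcome table, one block per dwell
#' scenario, in the classic Cost / QALY / CER / ICER layout.
#'
#' @param outcomes A `vad_outcomes` tibble from [scenario_table()].
#' @param wtp Willingness-to-pay threshold for the per-dwell recommendation.
#' @return List of class `vad_cea`: `summary` (tibble `dwell`, `arm`,
#'   `cost`, `qaly`, `cer`), `comparisons` (tibble of pairwise [icer()]
#'   rows per dwell), `recommended` (tibble `dwell`, `arm`).
#' @examples
#' cea_table(scenario_table(default_parameters()), wtp = 34794.8108)
#' @export
cea_table <- function(outcomes, wtp = default_parameters()$settings$wtp) {
  stopifnot(is.data.frame(outcomes))
  pairs <- list(c("PICC", "CVC"), c("IVAP", "PICC"), c("IVAP", "CVC"))
  dwells <- unique(outcomes$dwell)
  summary <- outcomes |>
    mutate(cer = .data$cost / .data$qaly) |>
    select("dwell", "arm", "cost", "qaly", "cer")
  comparisons <- purrr::map(dwells, \(dw) {
    rows <- outcomes |> filter(.data$dwell == dw)
    purrr::map(pairs, \(pr) {
      a <- rows |> filter(.data$arm == pr[1])
      b <- rows |> filter(.data$arm == pr[2])
      if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
      icer(a, b, wtp = wtp) |> mutate(dwell = dw, .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  recommended <- purrr::map(dwells, \(dw) {
    tibble::tibble(dwell = dw,
                   arm = recommend_device(outcomes |>
                                            filter(.data$dwell == dw), wtp))
  }) |> purrr::list_rbind()
  structure(list(summary = summary, comparisons = comparisons,
                 recommended = recommended, wtp = wtp),
            class = "vad_cea")
}

#' @export
print.vad_cea <- function(x, ...) {
  cat("<vad_cea> cost-utility analysis (WTP", format(x$wtp), "USD/QALY)\n\n")
  print(as.data.frame(x$summary |>
                        mutate(across(dplyr::where(is.numeric),
                                      \(v) round(v, 2)))),
        row.names = FALSE)
  cat("\nIncremental comparisons:\n")
  print(as.data.frame(x$comparisons |>
                        select("dwell", "arm1", "arm2", "icer", "dominance") |>
                        mutate(icer = round(.data$icer, 2))),
        row.names = FALSE)
  cat("\nRecommended:",
      paste(x$recommended$dwell, "->", x$recommended$arm, collapse = ", "),
      "\n")
  invisible(x)
}

#' Full base-case analysis from a parameter set
#'
#' Convenience wrapper: evaluates the three arms over the requested dwell
#' scenarios and computes the cost-utility table at the configured
#' willingness-to-pay.
#'
#' @inheritParams weighted_utility
#' @param dwells Dwell scenarios.
#' @return A `vad_cea` object (see [cea_table()]).
#' @export
base_case_analysis <- function(params = default_parameters(),
                               dwells = c("6m", "12m", "full")) {
  cea_table(scenario_table(params, dwells), wtp = params$settings$wtp)
}
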