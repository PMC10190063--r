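#' Complication-weighted health utility of an arm
#'
#' The decision tree splits every arm into patients with and without
#' complications; the arm's effective utility is
#' `p * u_complication + (1 - p) * u`.
#'
#' @param params A `vad_parameters` object.
#' @param arm `"CVC"`, `"PICC"` or `"IVAP"`.
#' @return Dimensionless utility in \[0, 1\].
#' @examples
#' weighted_utility(default_parameters(), "PICC") # 0.879284
#' @export
weighted_utility <- function(params, arm) {
  ak <- arm_param_keys(arm)
  v <- param_value(params, c(ak$p, ak$u, ak$u_comp))
  unname(v[ak$p] * v[ak$u_comp] + (1 - v[ak$p]) * v[ak$u])
}

#' Expected complication-management cost of an arm
#'
#' Complication probability times the constituent-ratio-weighted mean of the
#' per-type treatment costs; applied once per patient over the whole
#' catheterisation course.
#'
#' @inheritParams weighted_utility
#' @return Expected cost in USD.
#' @export
expected_complication_cost <- function(params, arm) {
  ak <- arm_param_keys(arm)
  mix <- params$mix |> filter(.data$arm == !!arm)
  if (nrow(mix) == 0) return(0)
  missing <- setdiff(mix$cost_key, params$params$key)
  if (length(missing) > 0) {
    stop_vad("complication type(s) without a cost parameter: ",
             paste(missing, collapse = ", "), class = "vadcea_key_error")
  }
  costs <- param_value(params, mix$cost_key)
  unname(param_value(params, ak$p)) * sum(mix$share * costs)
}

#' Expected cost and QALYs of one arm at one dwell time
#'
#' Evaluates the decision tree for a single arm. For PICC and IVAP the
#' effective on-catheter time is `T = min(dwell, median survival)` (with
#' `"full"` meaning the median), total cost is insertion +
#' `(T / maintenance interval)` per-visit maintenance (fractional visit
#' counts allowed) + removal + the expected complication cost, and QALYs are
#' `T` times the complication-weighted utility. The CVC arm is a composite
#' of repeated insertion episodes spanning the whole course regardless of
#' dwell: cost is the mean insertion count times the per-episode
#' (insertion + maintenance + removal) cost plus the once-per-course
#' expected complication cost; QALYs add the on-catheter part (insertions x
#' per-catheter median x weighted utility) and the intermission part
#' (number of intermissions x intermission length x intermission utility).
#'
#' @inheritParams weighted_utility
#' @param dwell Dwell-time scenario: years, `"<n>m"`, or `"full"` (see
#'   [parse_dwell()]).
#' @return One-row tibble with the arm, dwell, cost components
#'   (`cost_insertion`, `cost_maintenance`, `cost_removal`,
#'   `cost_complication`), total `cost`, QALY components
#'   (`qaly_on_catheter`, `qaly_intermission`) and total `qaly`.
#' @examples
#' evaluate_arm(default_parameters(), "IVAP", "12m")$cost # 1320.06
#' @export
evaluate_arm <- function(params, arm, dwell = "full") {
  stopifnot(inherits(params, "vad_parameters"), arm %in% arm_names())
  s <- params$settings
  dw <- parse_dwell(dwell, s$days_per_month, s$days_per_year)
  vals <- as.list(setNames(params$params$mean, params$params$key))
  out <- arm_cost_qaly(vals, params$mix, arm, dw)
  tibble::tibble(arm = arm, dwell = dwell_label(dwell), dwell_years = dw,
                 !!!out)
}

# vectorised decision-tree arithmetic shared by the base case and the PSA;
# `vals` is a named list whose elements are scalars or equal-length vectors
arm_cost_qaly <- function(vals, mix_table, arm, dwell_years) {
  ak <- arm_param_keys(arm)
  mix <- mix_table[mix_table$arm == arm, ]
  mixcost <- 0
  for (i in seq_len(nrow(mix))) {
    if (is.null(vals[[mix$cost_key[i]]])) {
      stop_vad("complication type '", mix$type[i],
               "' lacks a cost parameter value", class = "vadcea_key_error")
    }
    mixcost <- mixcost + mix$share[i] * vals[[mix$cost_key[i]]]
  }
  p <- vals[[ak$p]]
  comp_cost <- p * mixcost
  wu <- p * vals[[ak$u_comp]] + (1 - p) * vals[[ak$u]]

  if (arm == "CVC") {
    k <- vals[["CVC_mean_insertionTimes"]]
    ins <- k * vals[[ak$insertion]]
    mnt <- k * vals[[ak$maintenance]]
    rem <- k * vals[[ak$removal]]
    q_on <- k * vals[[ak$median]] * wu
    q_int <- vals[["CVC_intervals"]] * vals[["CVC_intermission"]] *
      vals[["u1_CVC_intermission"]]
  } else {
    interval <- vals[[ak$interval]]
    if (any(interval <= 0)) {
      stop_vad("maintenance interval must be positive")
    }
    tt <- pmin(dwell_years, vals[[ak$median]])
    ins <- vals[[ak$insertion]] + 0 * tt
    mnt <- (tt / interval) * vals[[ak$maintenance]]
    rem <- vals[[ak$removal]] + 0 * tt
    q_on <- tt * wu
    q_int <- 0 * tt
  }
  list(
    cost_insertion = ins, cost_maintenance = mnt, cost_removal = rem,
    cost_complication = comp_cost,
    cost = ins + mnt + rem + comp_cost,
    qaly_on_catheter = q_on, qaly_intermission = q_int,
    qaly = q_on + q_int
  )
}

#' Evaluate all arms over a set of dwell-time scenarios
#'
#' @inheritParams weighted_utility
#' @param dwells Nonempty list/vector of dwell specifications (default the
#'   six-month, twelve-month and full-course scenarios).
#' @return Tibble with one row per arm x dwell (class `vad_outcomes`).
#' @examples
#' scenario_table(default_parameters())
#' @export
scenario_table <- function(params, dwells = c("6m", "12m", "full")) {
  if (length(dwells) == 0) {
    stop_vad("at least one dwell scenario is required",
             class = "vadcea_empty_error")
  }
  out <- purrr::map(as.list(dwells), \(dw) {
    purrr::map(arm_names(), \(a) evaluate_arm(params, a, dw)) |>
      purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(out) <- c("vad_outcomes", class(out))
  out
}
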