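#' Base-case model parameters
#'
#' Builds the packaged base-case parameter set for the three-arm
#' decision-tree model: per-arm placement, maintenance and removal costs,
#' per-complication-type treatment costs, complication probabilities with
#' their per-type constituent ratios, health-state utilities, median
#' catheter survival times and maintenance intervals, plus the CVC
#' multi-insertion quantities (mean number of insertions, number and length
#' of the intermissions between insertions, and the intermission utility).
#'
#' Costs are in USD (converted from RMB at 6.9838 RMB/USD; the rate is kept
#' as metadata only), times in years, utilities dimensionless in \[0, 1\].
#'
#' Two derived columns are attached to every parameter row:
#' * `dsa_low`/`dsa_high` — one-way sensitivity bounds: the 95% confidence
#'   interval where one is available, otherwise mean +/- 10%, clamped to the
#'   parameter's natural support (costs >= 0, probabilities and utilities in
#'   \[0, 1\]).
#' * `psa_sd` — the standard deviation of the parameter-uncertainty
#'   distribution used by the probabilistic sensitivity analysis: the CI
#'   half-width divided by 1.96 where the CI is an interval for the mean;
#'   for the two per-visit maintenance costs, whose printed intervals are
#'   patient-level mean +/- 1.96 SD bands, that value divided by the square
#'   root of the arm sample size; the printed SD where no CI exists; and
#'   10% of the mean as a last resort. Complication probabilities are
#'   sampled from Beta(events, n - events) instead and median survival times
#'   from their fitted families, so their `psa_sd` is `NA`.
#'
#' @return An object of class `vad_parameters`: a list with elements
#'   `params` (tibble of all model parameters, one row per key), `mix`
#'   (tibble of complication-type counts and shares per arm), `arm_n`
#'   (named vector of matched arm sizes), `events` (named vector of
#'   patients with at least one complication per arm) and `settings`
#'   (willingness-to-pay threshold, currency rate, day-count conventions).
#' @examples
#' p <- default_parameters()
#' param_value(p, "c3_IVAP_insertion")
#' @export
default_parameters <- function() {
  params <- tibble::tribble(
    ~key,                              ~mean,      ~sd,       ~ci_low,    ~ci_high,  ~distribution, ~kind,          ~arm,
    "c1_CVC_insertion",                68.0747,    43.2521,   66.7348,    69.4147,   "gamma",       "cost",         "CVC",
    "c1_CVC_maintenance",              41.9615,    45.6716,   40.4214,    43.5015,   "gamma",       "cost",         "CVC",
    "c1_CVC_removal",                  8.2753,     3.3928,    8.1466,     8.4041,    "gamma",       "cost",         "CVC",
    "c2_PICC_insertion",               349.5522,   102.7811,  329.5638,   369.5405,  "gamma",       "cost",         "PICC",
    "c2_PICC_perMaintenance",          21.6773,    NA,        0.433,      42.9217,   "gamma",       "cost",         "PICC",
    "c2_PICC_removal",                 7.2909,     3.4561,    6.7812,     7.8007,    "gamma",       "cost",         "PICC",
    "c3_IVAP_insertion",               844.8203,   317.5976,  828.9301,   860.7106,  "gamma",       "cost",         "IVAP",
    "c3_IVAP_perMaintenance",          32.1395,    NA,        0.6413,     63.6376,   "gamma",       "cost",         "IVAP",
    "c3_IVAP_removal",                 82.3272,    6.8959,    81.5174,    83.137,    "gamma",       "cost",         "IVAP",
    "c_complication_allergy",          30.7898,    52.408,    -13.0244,   74.604,    "gamma",       "cost",         "shared",
    "c_complication_CatheterRupture",  44.1021,    NA,        35.2817,    52.9225,   "gamma",       "cost",         "shared",
    "c_complication_CRBSI",            47.1949,    NA,        37.7559,    56.6339,   "gamma",       "cost",         "shared",
    "c_complication_drugExtravasation",25.5226,    0.3675,    22.2205,    28.8248,   "gamma",       "cost",         "shared",
    "c_complication_exudation",        28.8435,    23.8289,   11.7973,    45.8896,   "gamma",       "cost",         "shared",
    "c_complication_infection",        131.2002,   196.0126,  -50.0812,   312.4816,  "gamma",       "cost",         "shared",
    "c_complication_Nslippage",        2.2624,     NA,        1.8099,     2.7149,    "gamma",       "cost",         "shared",
    "c_complication_occlusion",        38.6511,    36.5992,   19.8335,    57.4687,   "gamma",       "cost",         "shared",
    "c_complication_Pslippage",        152.7048,   61.313,    0.3948,     305.0149,  "gamma",       "cost",         "shared",
    "c_complication_skinDamage",       14.2501,    3.7543,    -19.4812,   47.9815,   "gamma",       "cost",         "shared",
    "c_complication_thrombosis",       17.0416,    19.8661,   -3.8066,    37.8898,   "gamma",       "cost",         "shared",
    "c_complication_Tslippage",        3.8460,     2.1042,    -1.381,     9.0731,    "gamma",       "cost",         "shared",
    "CVC_intermission",                0.0686,     0.1772,    0.06174,    0.07546,   "normal",      "duration",     "CVC",
    "CVC_mean_insertionTimes",         4.5589,     2.8271,    4.416248,   4.701477,  "normal",      "count",        "CVC",
    "CVC_intervals",                   3.5589,     2.8271,    3.416348,   3.701477,  "normal",      "count",        "CVC",
    "p1_CVC_complication",             0.0734,     NA,        NA,         NA,        "beta",        "probability",  "CVC",
    "p2_PICC_complication",            0.0728,     NA,        NA,         NA,        "beta",        "probability",  "PICC",
    "p3_IVAP_complication",            0.0384,     NA,        NA,         NA,        "beta",        "probability",  "IVAP",
    "T1_CVC_medianSurvivalTime",       0.01096,    NA,        NA,         NA,        "lognormal",   "median",       "CVC",
    "T2_PICC_maintenanceInterval",     0.0192,     NA,        NA,         NA,        NA,            "interval",     "PICC",
    "T2_PICC_medianSurvivalTime",      0.4137,     NA,        NA,         NA,        "gompertz",    "median",       "PICC",
    "T3_IVAP_maintenanceInterval",     0.0822,     NA,        NA,         NA,        NA,            "interval",     "IVAP",
    "T3_IVAP_medianSurvivalTime",      2.8493,     NA,        NA,         NA,        "gompertz",    "median",       "IVAP",
    "u1_CVC",                          0.8989706,  0.0644212, 0.8753407,  0.9226005, "beta",        "utility",      "CVC",
    "u1_CVC_complication",             0.8778395,  0.0228473, NA,         NA,        "beta",        "utility",      "CVC",
    "u1_CVC_intermission",             0.814,      NA,        NA,         NA,        "beta",        "utility",      "CVC",
    "u2_PICC",                         0.8806194,  0.0565468, 0.8602321,  0.9010067, "beta",        "utility",      "PICC",
    "u2_PICC_complication",            0.862279,   0.0614081, 0.8054858,  0.9190719, "beta",        "utility",      "PICC",
    "u3_IVAP",                         0.9448492,  0.0726747, 0.9340994,  0.955599,  "beta",        "utility",      "IVAP",
    "u3_IVAP_complication",            0.942318,   NA,        NA,         NA,        "beta",        "utility",      "IVAP"
  )

  mix <- tibble::tribble(
    ~arm,   ~type,               ~count, ~cost_key,
    "CVC",  "Pslippage",         13L,    "c_complication_Pslippage",
    "CVC",  "infection",         3L,     "c_complication_infection",
    "CVC",  "exudation",         27L,    "c_complication_exudation",
    "CVC",  "occlusion",         16L,    "c_complication_occlusion",
    "CVC",  "CRBSI",             1L,     "c_complication_CRBSI",
    "CVC",  "thrombosis",        9L,     "c_complication_thrombosis",
    "CVC",  "allergy",           7L,     "c_complication_allergy",
    "CVC",  "skinDamage",        19L,    "c_complication_skinDamage",
    "CVC",  "Tslippage",         16L,    "c_complication_Tslippage",
    "PICC", "Pslippage",         7L,     "c_complication_Pslippage",
    "PICC", "infection",         6L,     "c_complication_infection",
    "PICC", "exudation",         14L,    "c_complication_exudation",
    "PICC", "occlusion",         3L,     "c_complication_occlusion",
    "PICC", "thrombosis",        8L,     "c_complication_thrombosis",
    "PICC", "allergy",           8L,     "c_complication_allergy",
    "PICC", "skinDamage",        7L,     "c_complication_skinDamage",
    "PICC", "CatheterRupture",   2L,     "c_complication_CatheterRupture",
    "IVAP", "infection",         10L,    "c_complication_infection",
    "IVAP", "exudation",         1L,     "c_complication_exudation",
    "IVAP", "occlusion",         34L,    "c_complication_occlusion",
    "IVAP", "thrombosis",        8L,     "c_complication_thrombosis",
    "IVAP", "allergy",           1L,     "c_complication_allergy",
    "IVAP", "drugExtravasation", 3L,     "c_complication_drugExtravasation",
    "IVAP", "Nslippage",         1L,     "c_complication_Nslippage"
  )

  new_vad_parameters(
    params = params,
    mix = mix,
    arm_n = c(CVC = 1512L, PICC = 756L, IVAP = 1512L),
    events = c(CVC = 111L, PICC = 55L, IVAP = 58L),
    settings = list(
      wtp = 34794.8108,
      currency_rate = 6.9838,
      days_per_month = 30,
      days_per_year = 365
    )
  )
}

# constructor: derives mix shares, DSA bounds and PSA uncertainty SDs,
# then validates
new_vad_parameters <- function(params, mix, arm_n, events, settings) {
  mix <- mix |>
    group_by(.data$arm) |>
    mutate(share = .data$count / sum(.data$count)) |>
    ungroup() |>
    arrange(match(.data$arm, arm_names())) # canonical arm order

  params <- params |>
    mutate(
      dsa_low = dplyr::if_else(!is.na(.data$ci_low), .data$ci_low, .data$mean * 0.9),
      dsa_high = dplyr::if_else(!is.na(.data$ci_high), .data$ci_high, .data$mean * 1.1),
      dsa_low = pmax(.data$dsa_low, 0),
      dsa_high = dplyr::if_else(.data$kind %in% c("probability", "utility"),
                                pmin(.data$dsa_high, 1), .data$dsa_high),
      psa_sd = psa_uncertainty_sd(.data$key, .data$mean, .data$sd,
                                  .data$ci_low, .data$ci_high, .data$kind,
                                  .data$arm, arm_n)
    )

  p <- structure(
    list(params = params, mix = mix, arm_n = arm_n, events = events,
         settings = settings),
    class = "vad_parameters"
  )
  validate_parameters(p)
  p
}

# parameter-uncertainty SD policy for the PSA (see ?default_parameters)
psa_uncertainty_sd <- function(key, mean, sd, ci_low, ci_high, kind, arm,
                               arm_n) {
  per_visit <- c("c2_PICC_perMaintenance", "c3_IVAP_perMaintenance")
  out <- dplyr::case_when(
    kind %in% c("probability", "median", "interval") ~ NA_real_,
    key %in% per_visit ~
      ((ci_high - ci_low) / (2 * qnorm(0.975))) / sqrt(arm_n[arm]),
    !is.na(ci_low) & !is.na(ci_high) ~ (ci_high - ci_low) / (2 * qnorm(0.975)),
    !is.na(sd) ~ sd,
    TRUE ~ 0.1 * mean
  )
  unname(out)
}

#' Validate a model-parameter object
#'
#' Checks the structural invariants of a [vad_parameters] object: every
#' required parameter key is present exactly once, costs and times are
#' positive, probabilities and utilities lie in \[0, 1\], confidence
#' intervals bracket their means, complication-mix shares sum to one and
#' every mix type has a resolvable cost key, and the CVC intermission count
#' equals the mean insertion count minus one.
#'
#' @param p A `vad_parameters` object.
#' @return `p`, invisibly, if valid; otherwise an error describing the
#'   first violated rule (classed `vadcea_validation_error`, or
#'   `vadcea_schema_error` for missing/duplicated keys).
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "vad_parameters"))
  pr <- p$params
  required <- default_parameter_keys()
  missing <- setdiff(required, pr$key)
  if (length(missing) > 0) {
    stop_vad("parameter file is missing required key(s): ",
             paste(missing, collapse = ", "), class = "vadcea_schema_error")
  }
  if (anyDuplicated(pr$key)) {
    stop_vad("duplicated parameter key(s): ",
             paste(unique(pr$key[duplicated(pr$key)]), collapse = ", "),
             class = "vadcea_schema_error")
  }
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      stop_vad(msg, ": ", paste(pr$key[which(cond)], collapse = ", "),
               class = "vadcea_validation_error")
    }
  }
  bad(is.na(pr$mean), "parameter mean is missing")
  bad(pr$kind %in% c("cost", "duration", "count", "median", "interval") &
        pr$mean <= 0, "cost/time parameter must be positive")
  bad(pr$kind %in% c("probability", "utility") &
        (pr$mean < 0 | pr$mean > 1),
      "probability/utility must lie in [0, 1]")
  bad(!is.na(pr$ci_low) & !is.na(pr$ci_high) &
        !(pr$ci_low < pr$mean & pr$mean < pr$ci_high),
      "confidence interval does not bracket the mean")

  shares <- p$mix |> group_by(.data$arm) |> summarise(s = sum(.data$share))
  if (any(abs(shares$s - 1) > 1e-9)) {
    stop_vad("complication-mix shares do not sum to 1",
             class = "vadcea_validation_error")
  }
  unresolved <- setdiff(p$mix$cost_key, pr$key)
  if (length(unresolved) > 0) {
    stop_vad("complication types without a cost parameter: ",
             paste(unresolved, collapse = ", "),
             class = "vadcea_validation_error")
  }
  k <- param_value(p, "CVC_mean_insertionTimes")
  ni <- param_value(p, "CVC_intervals")
  if (abs(ni - (k - 1)) > 1e-6) {
    stop_vad("CVC_intervals must equal CVC_mean_insertionTimes - 1 ",
             "(got ", ni, " vs ", k - 1, ")",
             class = "vadcea_validation_error")
  }
  if (!all(arm_names() %in% names(p$arm_n))) {
    stop_vad("arm_n must name all three arms",
             class = "vadcea_schema_error")
  }
  invisible(p)
}

#' @rdname validate_parameters
#' @export
default_parameter_keys <- function() {
  c("c1_CVC_insertion", "c1_CVC_maintenance", "c1_CVC_removal",
    "c2_PICC_insertion", "c2_PICC_perMaintenance", "c2_PICC_removal",
    "c3_IVAP_insertion", "c3_IVAP_perMaintenance", "c3_IVAP_removal",
    "c_complication_allergy", "c_complication_CatheterRupture",
    "c_complication_CRBSI", "c_complication_drugExtravasation",
    "c_complication_exudation", "c_complication_infection",
    "c_complication_Nslippage", "c_complication_occlusion",
    "c_complication_Pslippage", "c_complication_skinDamage",
    "c_complication_thrombosis", "c_complication_Tslippage",
    "CVC_intermission", "CVC_mean_insertionTimes", "CVC_intervals",
    "p1_CVC_complication", "p2_PICC_complication", "p3_IVAP_complication",
    "T1_CVC_medianSurvivalTime", "T2_PICC_maintenanceInterval",
    "T2_PICC_medianSurvivalTime", "T3_IVAP_maintenanceInterval",
    "T3_IVAP_medianSurvivalTime",
    "u1_CVC", "u1_CVC_complication", "u1_CVC_intermission",
    "u2_PICC", "u2_PICC_complication", "u3_IVAP", "u3_IVAP_complication")
}

#' Read and modify single model parameters by key
#'
#' Every model parameter is reachable by its stable string key (the row
#' labels of the parameter table, e.g. `"c3_IVAP_perMaintenance"`), which is
#' what the one-way sensitivity analysis iterates over.
#'
#' @param p A `vad_parameters` object.
#' @param key Parameter key.
#' @param value Replacement mean value.
#' @return `param_value()` returns the parameter mean; `set_param()` returns
#'   a modified copy of `p` (the replacement is validated against the
#'   parameter's support but intentionally skips cross-parameter coupling
#'   checks, so sensitivity analyses can move one value at a time).
#' @export
param_value <- function(p, key) {
  stopifnot(inherits(p, "vad_parameters"))
  i <- match(key, p$params$key)
  if (any(is.na(i))) {
    stop_vad("unknown parameter key(s): ",
             paste(key[is.na(i)], collapse = ", "),
             class = "vadcea_key_error")
  }
  setNames(p$params$mean[i], key)
}

#' @rdname param_value
#' @export
set_param <- function(p, key, value) {
  stopifnot(inherits(p, "vad_parameters"))
  i <- match(key, p$params$key)
  if (is.na(i)) {
    stop_vad("unknown parameter key: ", key, class = "vadcea_key_error")
  }
  kind <- p$params$kind[i]
  if (kind %in% c("probability", "utility")) {
    assert_scalar_number(value, key, 0, 1)
  } else {
    assert_scalar_number(value, key, lower = 0)
  }
  p$params$mean[i] <- value
  p
}

#' Keys eligible for one-way sensitivity analysis
#'
#' The two fixed maintenance intervals carry no uncertainty distribution and
#' are excluded, leaving the 37 varied parameters.
#'
#' @param p A `vad_parameters` object.
#' @return Character vector of parameter keys.
#' @export
dsa_keys <- function(p) {
  stopifnot(inherits(p, "vad_parameters"))
  p$params$key[!is.na(p$params$distribution)]
}

#' One-way sensitivity bounds for every eligible parameter
#'
#' @param p A `vad_parameters` object.
#' @return Tibble with columns `key`, `mean`, `low`, `high`.
#' @export
dsa_bounds <- function(p) {
  stopifnot(inherits(p, "vad_parameters"))
  p$params |>
    filter(.data$key %in% dsa_keys(p)) |>
    select("key", "mean", low = "dsa_low", high = "dsa_high")
}

#' @export
print.vad_parameters <- function(x, ...) {
  cat("<vad_parameters>\n")
  cat("  parameters:", nrow(x$params), "keys (", length(dsa_keys(x)),
      "with uncertainty distributions )\n")
  cat("  arms:", paste(sprintf("%s n=%d events=%d", names(x$arm_n),
                               x$arm_n, x$events[names(x$arm_n)]),
                       collapse = ", "), "\n")
  cat("  WTP:", x$settings$wtp, "USD/QALY\n")
  invisible(x)
}
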