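#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the ICER of a designated pair of arms with one parameter at a
#' time moved to its lower and upper bound (95% confidence limits where
#' printed, otherwise mean +/- 10%, clamped to the parameter's support)
#' while all other parameters stay at base case. Entries are sorted by
#' spread, the classic tornado ordering. The two fixed maintenance
#' intervals carry no uncertainty range, leaving 37 eligible parameters in
#' the packaged base case.
#'
#' @param params A `vad_parameters` object.
#' @param pair Length-2 character vector: the compared arms, first minus
#'   second.
#' @param dwell Dwell scenario at which arms are evaluated.
#' @param keys Parameter keys to vary (default all eligible); unknown keys
#'   are an error.
#' @return Tibble of class `vad_tornado` with columns `key`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, sorted by decreasing spread; the
#'   base-case ICER and the pair are attached as attributes.
#' @examples
#' head(one_way_dsa(default_parameters(), c("IVAP", "PICC")), 3)
#' @export
one_way_dsa <- function(params, pair = c("IVAP", "CVC"), dwell = "full",
                        keys = NULL) {
  stopifnot(inherits(params, "vad_parameters"), length(pair) == 2,
            all(pair %in% arm_names()))
  eligible <- dsa_keys(params)
  keys <- keys %||% eligible
  unknown <- setdiff(keys, params$params$key)
  if (length(unknown) > 0) {
    stop_vad("unknown parameter key(s): ", paste(unknown, collapse = ", "),
             class = "vadcea_key_error")
  }
  pair_icer <- function(p) {
    icer(evaluate_arm(p, pair[1], dwell), evaluate_arm(p, pair[2], dwell))$icer
  }
  base <- pair_icer(params)
  bounds <- dsa_bounds(params) |> filter(.data$key %in% keys)
  out <- purrr::pmap(bounds, \(key, mean, low, high) {
    tibble::tibble(
      key = key, low = low, high = high,
      icer_low = pair_icer(set_param(params, key, low)),
      icer_high = pair_icer(set_param(params, key, high))
    )
  }) |>
    purrr::list_rbind() |>
    mutate(spread = abs(.data$icer_high - .data$icer_low)) |>
    arrange(dplyr::desc(.data$spread))
  attr(out, "pair") <- pair
  attr(out, "icer_base") <- base
  class(out) <- c("vad_tornado", class(out))
  out
}

#' Monte-Carlo probabilistic sensitivity analysis
#'
#' Draws every eligible parameter independently from its assigned
#' uncertainty distribution and evaluates the three arms per draw. Costs
#' are gamma, utilities beta (both moment-matched to the parameter's
#' uncertainty SD, see [default_parameters()]), complication probabilities
#' Beta(events, n - events) from the observed counts, the CVC
#' insertion-cycle quantities normal (truncated to their support: lengths
#' nonnegative, at least one insertion), the CVC median survival
#' median-centred lognormal, and the PICC/IVAP medians Gompertz with both
#' parameters perturbed at the same coefficient of variation. Complication
#' type mixes are held fixed; only the overall probability is sampled.
#'
#' @param params A `vad_parameters` object.
#' @param n Number of simulations (1000 by default).
#' @param seed Optional seed; identical seeds give identical draw matrices.
#' @param dwell Dwell scenario at which arms are evaluated.
#' @param survival_cv Coefficient of variation applied to the survival-time
#'   distributions.
#' @param gompertz_shape Gompertz shapes used to re-express the PICC/IVAP
#'   medians.
#' @return Object of class `vad_psa`: list with `draws` (n x parameter
#'   tibble), `outcomes` (tibble `draw`, `arm`, `cost`, `qaly`), `n`,
#'   `seed`, `dwell`, `wtp`.
#' @export
sample_psa <- function(params, n = 1000, seed = NULL, dwell = "full",
                       survival_cv = 0.1,
                       gompertz_shape = c(PICC = 1, IVAP = 1)) {
  stopifnot(inherits(params, "vad_parameters"))
  assert_scalar_number(n, "n", lower = 1)
  s <- params$settings
  dw <- parse_dwell(dwell, s$days_per_month, s$days_per_year)
  pr <- params$params
  arm_events <- setNames(as.numeric(params$events[names(params$arm_n)]),
                         names(params$arm_n))
  arm_sizes <- setNames(as.numeric(params$arm_n), names(params$arm_n))

  draws <- with_seed_if(seed, {
    cols <- purrr::pmap(
      pr |> select("key", "mean", "distribution", "kind", "arm", "psa_sd"),
      \(key, mean, distribution, kind, arm, psa_sd) {
        sample_psa_column(key, mean, distribution, kind, arm, psa_sd, n,
                          arm_events, arm_sizes, survival_cv, gompertz_shape)
      })
    tibble::as_tibble(setNames(cols, pr$key))
  })

  outcomes <- purrr::map(arm_names(), \(a) {
    o <- arm_cost_qaly(as.list(draws), params$mix, a, dw)
    tibble::tibble(draw = seq_len(n), arm = a, cost = o$cost, qaly = o$qaly)
  }) |> purrr::list_rbind()

  structure(list(draws = draws, outcomes = outcomes, n = n, seed = seed,
                 dwell = dwell_label(dwell), wtp = s$wtp),
            class = "vad_psa")
}

sample_psa_column <- function(key, mean, distribution, kind, arm, psa_sd, n,
                              arm_events, arm_sizes, survival_cv,
                              gompertz_shape) {
  if (is.na(distribution)) return(rep(mean, n)) # fixed intervals
  # an explicit zero uncertainty SD pins any parameter at its base value
  if (!is.na(psa_sd) && psa_sd == 0) return(rep(mean, n))
  if (kind == "probability") {
    ev <- arm_events[[arm]]
    return(rbeta(n, ev, arm_sizes[[arm]] - ev))
  }
  if (kind == "median") {
    fam <- if (distribution == "lognormal") "lognormal-median"
           else "gompertz-median"
    shape <- if (fam == "gompertz-median") gompertz_shape[[arm]] else 1
    d <- derive_sampling_distribution(mean, survival_cv * mean, fam,
                                      shape = shape)
    return(draw_dist(d, n))
  }
  if (is.na(psa_sd) || psa_sd == 0) return(rep(mean, n))
  d <- tryCatch(
    derive_sampling_distribution(mean, psa_sd, distribution),
    error = function(e) {
      stop_vad("cannot derive a sampling distribution for '", key, "': ",
               conditionMessage(e), class = "vadcea_distribution_error")
    }
  )
  x <- draw_dist(d, n)
  # truncate the normally distributed CVC cycle quantities to their support
  if (identical(key, "CVC_mean_insertionTimes")) x <- pmax(x, 1)
  if (key %in% c("CVC_intervals", "CVC_intermission")) x <- pmax(x, 0)
  x
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay gridpoint, the probability that an arm is
#' optimal is the fraction of PSA draws in which it maximises net monetary
#' benefit (ties to the cheaper arm); the probabilities across arms sum to
#' one at every gridpoint.
#'
#' @param psa A `vad_psa` object.
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default 0 to 40,000
#'   in 200 steps).
#' @return Tibble of class `vad_ceac` with columns `wtp`, `arm`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 40000, length.out = 201)) {
  stopifnot(inherits(psa, "vad_psa"), length(wtp_grid) > 0)
  wide <- psa$outcomes |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("cost", "qaly"))
  arms <- unique(psa$outcomes$arm)
  cost <- as.matrix(wide[paste0("cost_", arms)])
  qaly <- as.matrix(wide[paste0("qaly_", arms)])
  out <- purrr::map(wtp_grid, \(w) {
    nmb <- w * qaly - cost
    # ties to the cheaper arm: subtract a microscopic cost-ordering penalty
    pick <- max.col(nmb - 1e-12 * cost, ties.method = "first")
    tibble::tibble(wtp = w, arm = arms,
                   probability = tabulate(pick, length(arms)) / nrow(nmb))
  }) |> purrr::list_rbind()
  class(out) <- c("vad_ceac", class(out))
  out
}

#' Incremental cost/QALY scatter of PSA draws
#'
#' Per-draw increments of every comparator arm against a reference arm, the
#' data behind the classic cost-effectiveness plane scatter plot.
#'
#' @param psa A `vad_psa` object.
#' @param reference Reference arm.
#' @return Tibble of class `vad_scatter` with `draw`, `comparator`,
#'   `delta_cost`, `delta_qaly`.
#' @export
psa_scatter <- function(psa, reference = "CVC") {
  stopifnot(inherits(psa, "vad_psa"))
  if (!reference %in% psa$outcomes$arm) {
    stop_vad("reference arm '", reference, "' not present in the PSA")
  }
  ref <- psa$outcomes |>
    filter(.data$arm == reference) |>
    select("draw", ref_cost = "cost", ref_qaly = "qaly")
  out <- psa$outcomes |>
    inner_join(ref, by = "draw") |>
    mutate(delta_cost = .data$cost - .data$ref_cost,
           delta_qaly = .data$qaly - .data$ref_qaly) |>
    select("draw", comparator = "arm", "delta_cost", "delta_qaly")
  attr(out, "reference") <- reference
  class(out) <- c("vad_scatter", class(out))
  out
}
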