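#' Turn complication-type counts into constituent ratios
#'
#' @param counts Named nonnegative integer vector of per-type complication
#'   counts; the total must be positive.
#' @return Tibble with columns `type`, `count`, `share`; shares sum to 1.
#' @examples
#' complication_mix(c(exudation = 27, occlusion = 16))
#' @export
complication_mix <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_vad("counts must be a named vector of complication types")
  }
  if (any(counts < 0)) stop_vad("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) {
    stop_vad("at least one complication count must be positive",
             class = "vadcea_empty_error")
  }
  tibble::tibble(type = names(counts), count = as.integer(counts),
                 share = as.numeric(counts) / total)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins and `df = (r - 1)(c - 1)`, without continuity
#' correction (so the 2x2 case equals the textbook closed form).
#'
#' @param x An r x c matrix of nonnegative counts; every row and column sum
#'   must be positive.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(rbind(c(111, 1401), c(55, 701), c(58, 1454)))
#' @export
chi_square_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(!is.finite(x))) {
    stop_vad("contingency table must contain nonnegative finite counts")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop_vad("every row and column margin must be positive",
             class = "vadcea_margin_error")
  }
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Complication contingency table of a parameter set or cohort
#'
#' Builds the arms x (with/without complication) table used to compare
#' complication incidence across the three devices.
#'
#' @param x A `vad_parameters` object (uses the stored event counts and arm
#'   sizes) or a cohort tibble (tabulates `had_complication` by `device`).
#' @return 3 x 2 integer matrix with rows CVC/PICC/IVAP and columns
#'   `complication`, `none`.
#' @export
complication_contingency <- function(x) {
  if (inherits(x, "vad_parameters")) {
    ev <- x$events[arm_names()]
    n <- x$arm_n[arm_names()]
    m <- cbind(complication = as.integer(ev), none = as.integer(n - ev))
    rownames(m) <- arm_names()
    return(m)
  }
  stopifnot(is.data.frame(x))
  arms <- intersect(arm_names(), unique(x$device))
  m <- t(vapply(arms, \(a) {
    h <- x$had_complication[x$device == a]
    c(complication = sum(h), none = sum(!h))
  }, integer(2)))
  m
}

#' Estimate per-arm model parameters from a (matched) cohort
#'
#' The cohort-to-model construction step: component cost means and SDs,
#' the complication probability (patients with at least one complication
#' over arm size), the per-type complication mix, and the median survival
#' time from the supplied (or freshly fitted) parametric survival model.
#' CVC costs are per insertion episode (patient totals divided by the
#' number of insertions); PICC and IVAP maintenance is per visit, with the
#' visit count taken as observed dwell time over the arm's maintenance
#' interval.
#'
#' @param cohort Cohort tibble.
#' @param arm One of `"CVC"`, `"PICC"`, `"IVAP"`.
#' @param survival_fit Optional `vad_survfit` for the arm; if `NULL`, all
#'   four supported families are fitted to the arm's dwell times and the
#'   minimum-AIC family is selected.
#' @param template A `vad_parameters` object supplying the quantities that
#'   are not estimable from the cohort (maintenance intervals, utilities,
#'   settings).
#' @return List with `rows` (tibble `key`, `mean`, `sd`), `mix` (per-type
#'   counts), `type_costs` (tibble `cost_key`, `mean`, `sd`), `n`,
#'   `n_events`, `probability`, `median`, `family`.
#' @export
estimate_arm_parameters <- function(cohort, arm, survival_fit = NULL,
                                    template = default_parameters()) {
  stopifnot(is.data.frame(cohort), arm %in% arm_names())
  sub <- cohort |> filter(.data$device == arm)
  if (nrow(sub) == 0) {
    stop_vad("no patients with device ", arm, " in the cohort",
             class = "vadcea_empty_error")
  }
  ak <- arm_param_keys(arm)
  if (is.null(survival_fit)) {
    fits <- purrr::map(c("exponential", "weibull", "lognormal", "gompertz"),
                       \(fam) fit_parametric(sub$survival_time, sub$event, fam))
    survival_fit <- fits[[match(select_family(fits),
                                vapply(fits, `[[`, character(1), "family"))]]
  }

  if (arm == "CVC") {
    k <- sub$n_insertions
    per <- function(x) x / k
    rows <- tibble::tribble(
      ~key, ~mean, ~sd,
      ak$insertion, mean(per(sub$insertion_cost)), sd(per(sub$insertion_cost)),
      ak$maintenance, mean(per(sub$maintenance_cost)),
        sd(per(sub$maintenance_cost)),
      ak$removal, mean(per(sub$removal_cost)), sd(per(sub$removal_cost)),
      "CVC_mean_insertionTimes", mean(k), sd(k),
      "CVC_intervals", mean(k) - 1, sd(k),
      "CVC_intermission", mean(sub$intermission_time, na.rm = TRUE),
        sd(sub$intermission_time, na.rm = TRUE)
    )
  } else {
    interval <- unname(param_value(template, ak$interval))
    visits <- sub$survival_time / interval
    per_visit <- sub$maintenance_cost / visits
    rows <- tibble::tribble(
      ~key, ~mean, ~sd,
      ak$insertion, mean(sub$insertion_cost), sd(sub$insertion_cost),
      ak$maintenance, mean(per_visit), sd(per_visit),
      ak$removal, mean(sub$removal_cost), sd(sub$removal_cost)
    )
  }
  rows <- bind_rows(rows, tibble::tibble(
    key = c(ak$p, ak$median),
    mean = c(mean(sub$had_complication), survival_fit$median),
    sd = NA_real_
  ))

  events <- sub |> filter(.data$had_complication)
  mix <- if (nrow(events) > 0) {
    complication_mix(table(events$complication_type) |> c())
  } else {
    tibble::tibble(type = character(), count = integer(), share = numeric())
  }
  type_costs <- events |>
    group_by(.data$complication_type) |>
    summarise(mean = mean(.data$complication_cost),
              sd = sd(.data$complication_cost), n = dplyr::n()) |>
    rename(type = "complication_type")

  list(rows = rows, mix = mix, type_costs = type_costs,
       n = nrow(sub), n_events = nrow(events),
       probability = mean(sub$had_complication),
       median = survival_fit$median, family = survival_fit$family)
}

#' Assemble a full parameter set from a cohort
#'
#' Applies [estimate_arm_parameters()] to each arm and merges the estimates
#' into a copy of `template`, replacing every cohort-estimable quantity
#' (component costs, complication probabilities and mixes, pooled per-type
#' complication costs, survival medians, CVC insertion-cycle quantities)
#' while keeping the externally sourced ones (utilities, maintenance
#' intervals, willingness-to-pay). The result feeds straight into the
#' decision model, closing the cohort-to-model loop.
#'
#' @inheritParams estimate_arm_parameters
#' @param survival_fits Optional named list of `vad_survfit` per arm.
#' @return A validated `vad_parameters` object; the per-arm survival fit
#'   summaries are attached as attribute `"arm_estimates"`.
#' @export
estimate_parameters <- function(cohort, template = default_parameters(),
                                survival_fits = NULL) {
  stopifnot(is.data.frame(cohort))
  arms <- arm_names()
  est <- purrr::map(arms, \(a) {
    estimate_arm_parameters(cohort, a, survival_fit = survival_fits[[a]],
                            template = template)
  }) |> setNames(arms)

  p <- template
  for (a in arms) {
    for (i in seq_len(nrow(est[[a]]$rows))) {
      row <- est[[a]]$rows[i, ]
      j <- match(row$key, p$params$key)
      p$params$mean[j] <- row$mean
      if (!is.na(row$sd)) p$params$sd[j] <- row$sd
      # the template's confidence limits belong to its own means
      p$params$ci_low[j] <- NA_real_
      p$params$ci_high[j] <- NA_real_
    }
  }
  # pooled per-type complication costs across arms
  pooled <- purrr::imap(est, \(e, a) e$type_costs) |>
    purrr::list_rbind() |>
    group_by(.data$type) |>
    summarise(mean = sum(.data$mean * .data$n) / sum(.data$n),
              n = sum(.data$n))
  key_of_type <- template$mix |> distinct(.data$type, .data$cost_key)
  for (i in seq_len(nrow(pooled))) {
    ck <- key_of_type$cost_key[match(pooled$type[i], key_of_type$type)]
    j <- match(ck, p$params$key)
    if (!is.na(j)) {
      p$params$mean[j] <- pooled$mean[i]
      p$params$ci_low[j] <- NA_real_
      p$params$ci_high[j] <- NA_real_
    }
  }
  # observed mixes, falling back to the template for arms without events
  mix <- purrr::imap(est, \(e, a) {
    if (nrow(e$mix) == 0) {
      template$mix |> filter(.data$arm == a)
    } else {
      e$mix |>
        mutate(arm = a,
               cost_key = key_of_type$cost_key[
                 match(.data$type, key_of_type$type)]) |>
        select("arm", "type", "count", "cost_key", "share")
    }
  }) |> purrr::list_rbind()

  out <- new_vad_parameters(
    params = p$params |> select(-"dsa_low", -"dsa_high", -"psa_sd"),
    mix = mix |> select(-"share"),
    arm_n = vapply(est, `[[`, numeric(1), "n"),
    events = vapply(est, `[[`, numeric(1), "n_events"),
    settings = template$settings
  )
  attr(out, "arm_estimates") <- purrr::map(est, \(e) {
    list(family = e$family, median = e$median, probability = e$probability)
  })
  out
}
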