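#' Simulate a patient-level catheterisation cohort
#'
#' Generates synthetic patient records with the statistical structure the
#' downstream analysis assumes, so matching, survival fitting, estimation
#' and the decision model can be exercised (and their parameter recovery
#' tested) without hospital data. Each record carries the eleven matching
#' covariates, a device assignment confounded on those covariates through a
#' multinomial logit, per-device Bernoulli complication events with
#' categorical type mixes, gamma-distributed itemised costs, catheter
#' survival times (lognormal for CVC per-catheter dwell, Gompertz for PICC
#' and IVAP), and for CVC the number of insertion cycles
#' (`1 + Poisson(mean - 1)`) with gamma-distributed intermission lengths.
#'
#' Patient-level cost spreads use the printed SD where one exists, else the
#' 95% band width divided by 3.92, else 10% of the mean. Censoring, absent
#' by default (the modelled courses run from insertion to removal), marks a
#' random fraction of patients with an observation time drawn uniformly
#' over their survival time.
#'
#' @param n Total number of patients before matching.
#' @param params Ground-truth [vad_parameters] (default
#'   [default_parameters()]).
#' @param confounding Named list with elements `PICC` and `IVAP`: per-device
#'   log-odds coefficients (vs the CVC reference) on the covariates; see
#'   [default_confounding()]. Use `no_confounding()` for balanced arms.
#' @param prevalence Target marginal device shares at covariate means.
#' @param censoring_fraction Fraction of patients censored, in \[0, 1).
#' @param gompertz_shape Named vector of Gompertz shape parameters (per
#'   year) for the PICC and IVAP dwell-time distributions.
#' @param cvc_sdlog Log-scale SD of the CVC per-catheter dwell distribution.
#' @param seed Optional integer seed; the same configuration and seed give
#'   a byte-identical cohort.
#' @return A tibble of class `vad_cohort`, one row per patient, with the
#'   ground-truth `params` and the seed stored as attributes.
#' @examples
#' ch <- generate_cohort(n = 500, seed = 1)
#' dplyr::count(ch, device)
#' @export
generate_cohort <- function(n = 10718,
                            params = default_parameters(),
                            confounding = default_confounding(),
                            prevalence = c(CVC = 0.40, PICC = 0.16, IVAP = 0.44),
                            censoring_fraction = 0,
                            gompertz_shape = c(PICC = 1, IVAP = 1),
                            cvc_sdlog = 0.5,
                            seed = NULL) {
  stopifnot(inherits(params, "vad_parameters"))
  assert_scalar_number(n, "n", lower = 1)
  assert_scalar_number(censoring_fraction, "censoring_fraction", 0, 1 - 1e-9)
  with_seed_if(seed, {
    cov <- simulate_covariates(n)
    device <- assign_devices(cov, confounding, prevalence)
    ch <- purrr::map(arm_names(), \(arm) {
      idx <- which(device == arm)
      if (length(idx) == 0) return(NULL)
      simulate_arm_records(cov[idx, , drop = FALSE], idx, arm, params,
                           censoring_fraction, gompertz_shape, cvc_sdlog)
    }) |> purrr::list_rbind() |> arrange(.data$id)
    attr(ch, "truth") <- params
    attr(ch, "seed") <- seed
    class(ch) <- c("vad_cohort", class(ch))
    ch
  })
}

#' Default and null confounding structures for device assignment
#'
#' `default_confounding()` makes older, heavier patients with vascular
#' comorbidity more likely to receive an IVAP and less likely to receive a
#' PICC, producing covariate imbalance across arms before matching.
#' `no_confounding()` assigns devices independently of the covariates.
#'
#' @return Named list with `PICC` and `IVAP` log-odds coefficient vectors.
#' @export
default_confounding <- function() {
  list(
    PICC = c(age = -0.020, weight = -0.015, thrombosis_history = -0.8,
             hypertension = -0.25),
    IVAP = c(age = 0.030, weight = 0.020, thrombosis_history = 0.9,
             hypertension = 0.35, smoking = 0.2)
  )
}

#' @rdname default_confounding
#' @export
no_confounding <- function() {
  list(PICC = numeric(0), IVAP = numeric(0))
}

#' Covariates used for propensity-score matching
#'
#' @return Character vector of the eleven matching covariate names.
#' @export
matching_covariates <- function() {
  c("age", "sex", "ethnicity", "education", "height", "weight",
    "hypertension", "hyperlipidemia", "smoking", "allergy_history",
    "thrombosis_history")
}

simulate_covariates <- function(n) {
  tibble::tibble(
    age = round(pmin(pmax(rnorm(n, 50, 10), 18), 85), 1),
    sex = ifelse(runif(n) < 0.99, "female", "male"),
    ethnicity = ifelse(runif(n) < 0.93, "Han", "other"),
    education = sample(c("primary", "middle", "high", "college"), n,
                       replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15)),
    height = round(rnorm(n, 158, 6), 1),
    weight = round(pmax(rnorm(n, 58, 9), 35), 1),
    hypertension = as.integer(runif(n) < 0.15),
    hyperlipidemia = as.integer(runif(n) < 0.10),
    smoking = as.integer(runif(n) < 0.05),
    allergy_history = as.integer(runif(n) < 0.08),
    thrombosis_history = as.integer(runif(n) < 0.03)
  )
}

# numeric covariate matrix, continuous columns centred so the intercepts
# control marginal prevalence
covariate_matrix <- function(cov) {
  edu <- match(cov$education, c("primary", "middle", "high", "college"))
  cbind(
    age = cov$age - 50, sex = as.integer(cov$sex == "female") - 0.99,
    ethnicity = as.integer(cov$ethnicity == "Han") - 0.93,
    education = edu - 2.3, height = cov$height - 158,
    weight = cov$weight - 58, hypertension = cov$hypertension - 0.15,
    hyperlipidemia = cov$hyperlipidemia - 0.10, smoking = cov$smoking - 0.05,
    allergy_history = cov$allergy_history - 0.08,
    thrombosis_history = cov$thrombosis_history - 0.03
  )
}

assign_devices <- function(cov, confounding, prevalence) {
  stopifnot(all(c("PICC", "IVAP") %in% names(confounding)))
  prevalence <- prevalence[arm_names()] / sum(prevalence)
  X <- covariate_matrix(cov)
  lp <- function(coefs, intercept) {
    eta <- rep(intercept, nrow(X))
    if (length(coefs) > 0) {
      unknown <- setdiff(names(coefs), colnames(X))
      if (length(unknown) > 0) {
        stop_vad("unknown confounding covariate(s): ",
                 paste(unknown, collapse = ", "))
      }
      eta <- eta + X[, names(coefs), drop = FALSE] %*% coefs
    }
    as.numeric(eta)
  }
  eta_picc <- lp(confounding$PICC, log(prevalence["PICC"] / prevalence["CVC"]))
  eta_ivap <- lp(confounding$IVAP, log(prevalence["IVAP"] / prevalence["CVC"]))
  denom <- 1 + exp(eta_picc) + exp(eta_ivap)
  p <- cbind(CVC = 1 / denom, PICC = exp(eta_picc) / denom,
             IVAP = exp(eta_ivap) / denom)
  u <- runif(nrow(p))
  arm_names()[1L + (u > p[, "CVC"]) + (u > p[, "CVC"] + p[, "PICC"])]
}

# patient-level SD: printed SD, else CI width / 3.92, else 10% of mean
patient_sd <- function(params, key) {
  i <- match(key, params$params$key)
  row <- params$params[i, ]
  if (!is.na(row$sd)) return(row$sd)
  if (!is.na(row$ci_low) && !is.na(row$ci_high)) {
    return((row$ci_high - row$ci_low) / (2 * qnorm(0.975)))
  }
  0.1 * row$mean
}

rgamma_mom <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

simulate_arm_records <- function(cov, idx, arm, params, censoring_fraction,
                                 gompertz_shape, cvc_sdlog) {
  m <- nrow(cov)
  v <- function(key) unname(param_value(params, key))
  psd <- function(key) patient_sd(params, key)
  ak <- arm_param_keys(arm)
  mix <- params$mix |> filter(.data$arm == !!arm)

  # true catheter survival (per-catheter dwell for CVC)
  t_true <- if (arm == "CVC") {
    rlnorm(m, meanlog = log(v("T1_CVC_medianSurvivalTime")), sdlog = cvc_sdlog)
  } else {
    a <- gompertz_shape[[arm]]
    flexsurv::rgompertz(m, shape = a,
                        rate = gompertz_rate_for_median(a, v(ak$median)))
  }
  censored <- runif(m) < censoring_fraction
  t_obs <- ifelse(censored, runif(m) * t_true, t_true)

  had <- runif(m) < v(ak$p)
  type <- rep(NA_character_, m)
  comp_cost <- rep(0, m)
  if (any(had)) {
    ti <- sample.int(nrow(mix), sum(had), replace = TRUE, prob = mix$share)
    type[had] <- mix$type[ti]
    comp_cost[had] <- vapply(seq_along(ti), \(j) {
      ck <- mix$cost_key[ti[j]]
      rgamma_mom(1, v(ck), psd(ck))
    }, numeric(1))
  }

  if (arm == "CVC") {
    k <- 1L + rpois(m, v("CVC_intervals"))
    gm <- function(key) {
      mu <- v(key); s <- psd(key)
      rgamma(m, shape = k * (mu / s)^2, rate = mu / s^2) # sum of k episodes
    }
    insertion <- gm("c1_CVC_insertion")
    maintenance <- gm("c1_CVC_maintenance")
    removal <- gm("c1_CVC_removal")
    inter_mu <- v("CVC_intermission"); inter_sd <- psd("CVC_intermission")
    n_inter <- pmax(k - 1L, 0L)
    intermission <- ifelse(
      n_inter > 0,
      rgamma(m, shape = n_inter * (inter_mu / inter_sd)^2,
             rate = inter_mu / inter_sd^2) / pmax(n_inter, 1L),
      NA_real_
    )
  } else {
    k <- rep(NA_integer_, m)
    insertion <- rgamma_mom(m, v(ak$insertion), psd(ak$insertion))
    removal <- rgamma_mom(m, v(ak$removal), psd(ak$removal))
    visits <- t_obs / v(ak$interval)
    maintenance <- visits * rgamma_mom(m, v(ak$maintenance),
                                       psd(ak$maintenance))
    intermission <- rep(NA_real_, m)
  }

  bind_cols(
    tibble::tibble(id = idx),
    cov,
    tibble::tibble(
      device = arm,
      n_insertions = k,
      insertion_cost = insertion,
      maintenance_cost = maintenance,
      removal_cost = removal,
      had_complication = had,
      complication_type = type,
      complication_cost = comp_cost,
      intermission_time = intermission,
      survival_time = t_obs,
      event = ifelse(censored, "censored", "removal")
    )
  )
}

#' Write and read cohort tables as CSV
#'
#' Plain-CSV round trip for [generate_cohort()] output (category labels and
#' missing markers included). `read_cohort()` validates the header and
#' column types and fails with the offending row/column on malformed input.
#'
#' @param cohort A cohort tibble.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `vad_cohort` tibble.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  readr::write_csv(cohort, path, na = "NA")
  invisible(path)
}

cohort_col_types <- function() {
  readr::cols(
    id = readr::col_integer(), age = readr::col_double(),
    sex = readr::col_character(), ethnicity = readr::col_character(),
    education = readr::col_character(), height = readr::col_double(),
    weight = readr::col_double(), hypertension = readr::col_integer(),
    hyperlipidemia = readr::col_integer(), smoking = readr::col_integer(),
    allergy_history = readr::col_integer(),
    thrombosis_history = readr::col_integer(),
    device = readr::col_character(), n_insertions = readr::col_integer(),
    insertion_cost = readr::col_double(),
    maintenance_cost = readr::col_double(),
    removal_cost = readr::col_double(),
    had_complication = readr::col_logical(),
    complication_type = readr::col_character(),
    complication_cost = readr::col_double(),
    intermission_time = readr::col_double(),
    survival_time = readr::col_double(), event = readr::col_character()
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_vad("no such file: ", path)
  ch <- suppressWarnings(
    readr::read_csv(path, col_types = cohort_col_types(),
                    na = "NA", progress = FALSE)
  )
  if (nrow(ch) == 0) {
    stop_vad("cohort file is empty: ", path, class = "vadcea_empty_error")
  }
  probs <- readr::problems(ch)
  if (nrow(probs) > 0) {
    cols <- names(ch)[unique(probs$col)]
    stop_vad("malformed cohort file: ", nrow(probs), " parse problem(s), ",
             "first at row ", probs$row[1], ", column '",
             names(ch)[probs$col[1]], "' (", probs$expected[1], ")",
             class = "vadcea_parse_error")
  }
  missing <- setdiff(c(matching_covariates(), "id", "device",
                       "survival_time", "event"), names(ch))
  if (length(missing) > 0) {
    stop_vad("cohort file lacks column(s): ", paste(missing, collapse = ", "),
             class = "vadcea_schema_error")
  }
  class(ch) <- c("vad_cohort", class(ch))
  ch
}

# per-arm parameter-key map used across modules
arm_param_keys <- function(arm) {
  switch(arm,
    CVC = list(insertion = "c1_CVC_insertion",
               maintenance = "c1_CVC_maintenance",
               removal = "c1_CVC_removal", p = "p1_CVC_complication",
               u = "u1_CVC", u_comp = "u1_CVC_complication",
               median = "T1_CVC_medianSurvivalTime", interval = NA_character_),
    PICC = list(insertion = "c2_PICC_insertion",
                maintenance = "c2_PICC_perMaintenance",
                removal = "c2_PICC_removal", p = "p2_PICC_complication",
                u = "u2_PICC", u_comp = "u2_PICC_complication",
                median = "T2_PICC_medianSurvivalTime",
                interval = "T2_PICC_maintenanceInterval"),
    IVAP = list(insertion = "c3_IVAP_insertion",
                maintenance = "c3_IVAP_perMaintenance",
                removal = "c3_IVAP_removal", p = "p3_IVAP_complication",
                u = "u3_IVAP", u_comp = "u3_IVAP_complication",
                median = "T3_IVAP_medianSurvivalTime",
                interval = "T3_IVAP_maintenanceInterval"),
    stop_vad("unknown arm: ", arm)
  )
}
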