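#' Estimate propensity scores for a device pair
#'
#' Fits a logistic regression of membership in `pair[1]` (vs `pair[2]`) on
#' the matching covariates and returns the per-patient predicted
#' probability. Scores lie strictly inside (0, 1); (quasi-)complete
#' separation or non-convergence raises an error advising covariate removal.
#'
#' @param cohort Cohort tibble (must contain `id`, `device` and the
#'   covariates).
#' @param covariates Character vector of covariate column names (default the
#'   eleven matching covariates).
#' @param pair Length-2 character vector of device groups; the first is the
#'   modelled outcome.
#' @return Tibble with columns `id`, `device`, `score`.
#' @export
estimate_propensity <- function(cohort, covariates = matching_covariates(),
                                pair = c("PICC", "CVC")) {
  stopifnot(is.data.frame(cohort), length(pair) == 2)
  missing <- setdiff(c("id", "device", covariates), names(cohort))
  if (length(missing) > 0) {
    stop_vad("cohort lacks column(s): ", paste(missing, collapse = ", "))
  }
  sub <- cohort |> filter(.data$device %in% pair)
  if (length(unique(sub$device)) < 2) {
    stop_vad("both device groups of the pair must be present")
  }
  keep <- covariates[vapply(covariates,
                            \(v) length(unique(sub[[v]])) > 1, logical(1))]
  f <- as.formula(paste(".treated ~", paste(keep, collapse = " + ")))
  dat <- sub |> mutate(.treated = as.integer(.data$device == pair[1]))
  fit <- suppressWarnings(glm(f, family = binomial(), data = dat))
  score <- as.numeric(predict(fit, type = "response"))
  if (!fit$converged || any(score < 1e-8) || any(score > 1 - 1e-8)) {
    stop_vad("propensity model shows separation or failed to converge; ",
             "consider removing strongly predictive covariates",
             class = "vadcea_separation_error")
  }
  tibble::tibble(id = sub$id, device = sub$device, score = score)
}

#' Propensity-score matching of the three device groups
#'
#' Realises a 1:2:2 nearest-neighbour caliper design for three groups as two
#' pairwise matches sharing the reference arm: each reference patient
#' (PICC, the smallest group) is greedily matched without replacement to
#' `ratio` nearest neighbours in each of the other two arms, on the
#' propensity scores of the corresponding pairwise logistic models.
#' Reference patients are processed in a random order (seeded). A stratum is
#' kept only if every requested partner exists within the caliper; otherwise
#' it is dropped whole and any provisionally taken partners are released.
#'
#' @param cohort Cohort tibble.
#' @param covariates Covariate columns for the propensity models.
#' @param reference Reference arm (default `"PICC"`).
#' @param ratio Number of partners per reference patient in each other arm.
#' @param caliper Maximum allowed score distance.
#' @param scale `"probability"` (default) applies the caliper on the
#'   probability scale; `"logit"` on the log-odds scale.
#' @param seed Optional seed for the reference processing order.
#' @return An object of class `vad_match`: list with `matched` (cohort rows
#'   of matched patients plus a `stratum` column), `scores` (per-pair score
#'   tibbles), `caliper`, `scale`, and `n_matched` (named count per arm).
#' @export
match_cohort <- function(cohort, covariates = matching_covariates(),
                         reference = "PICC", ratio = 2, caliper = 0.1,
                         scale = c("probability", "logit"), seed = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(cohort))
  assert_scalar_number(ratio, "ratio", lower = 1)
  assert_scalar_number(caliper, "caliper", lower = 0)
  others <- setdiff(intersect(arm_names(), unique(cohort$device)), reference)
  if (!reference %in% cohort$device) {
    stop_vad("reference group '", reference, "' is empty",
             class = "vadcea_empty_error")
  }
  scores <- purrr::map(others, \(arm) {
    estimate_propensity(cohort, covariates, pair = c(reference, arm))
  }) |> setNames(others)

  ref_ids <- cohort$id[cohort$device == reference]
  ref_order <- with_seed_if(seed, sample(ref_ids))

  # per-arm lookup of candidate ids and (possibly logit-scaled) scores
  to_scale <- function(s) if (scale == "logit") qlogis(s) else s
  cand <- purrr::map(others, \(arm) {
    sc <- scores[[arm]]
    list(ids = sc$id[sc$device == arm],
         s = to_scale(sc$score[sc$device == arm]),
         ref = setNames(to_scale(sc$score[sc$device == reference]),
                        sc$id[sc$device == reference]),
         available = rep(TRUE, sum(sc$device == arm)))
  }) |> setNames(others)

  strata <- vector("list", length(ref_order))
  n_kept <- 0L
  for (rid in ref_order) {
    picks <- list()
    ok <- TRUE
    for (arm in others) {
      cd <- cand[[arm]]
      d <- abs(cd$s - cd$ref[[as.character(rid)]])
      d[!cd$available] <- Inf
      sel <- order(d)[seq_len(ratio)]
      if (any(!is.finite(d[sel])) || any(d[sel] > caliper)) {
        ok <- FALSE
        break
      }
      picks[[arm]] <- sel
    }
    if (!ok) next # drop the whole stratum; provisional picks were per-arm
    n_kept <- n_kept + 1L
    for (arm in others) {
      cand[[arm]]$available[picks[[arm]]] <- FALSE
    }
    strata[[n_kept]] <- tibble::tibble(
      stratum = n_kept,
      id = c(rid, unlist(purrr::map(others, \(arm) {
        cand[[arm]]$ids[picks[[arm]]]
      }), use.names = FALSE))
    )
  }
  assignment <- purrr::list_rbind(strata[seq_len(n_kept)])
  if (is.null(assignment) || nrow(assignment) == 0) {
    assignment <- tibble::tibble(stratum = integer(), id = integer())
  }
  matched <- cohort |>
    inner_join(assignment, by = "id") |>
    arrange(.data$stratum, .data$id)
  structure(
    list(
      matched = matched,
      scores = scores,
      caliper = caliper,
      scale = scale,
      n_matched = table(factor(matched$device, levels = arm_names())) |>
        as.integer() |> setNames(arm_names())
    ),
    class = "vad_match"
  )
}

#' @export
print.vad_match <- function(x, ...) {
  cat("<vad_match> ",
      paste(names(x$n_matched), x$n_matched, collapse = " : "),
      " (caliper ", x$caliper, " on the ", x$scale, " scale)\n", sep = "")
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' For each covariate and stage, reports the standardised mean difference
#' (largest absolute pairwise SMD across the three groups; for two groups
#' the usual `(m1 - m2) / pooled SD`) together with a one-way ANOVA F test
#' (continuous covariates) or a Pearson chi-square test (categorical ones).
#' Constant covariates get SMD 0 with the test skipped and a note.
#'
#' @param before,after Cohort tibbles before and after matching (`after`
#'   may be `NULL` to profile a single cohort).
#' @param covariates Covariate columns to assess.
#' @return Tibble with columns `covariate`, `stage`, `type`, `smd`,
#'   `statistic`, `p_value`, `note`.
#' @export
balance_table <- function(before, after = NULL,
                          covariates = matching_covariates()) {
  stopifnot(is.data.frame(before), nrow(before) > 0)
  stages <- list(before = before)
  if (!is.null(after)) {
    stopifnot(is.data.frame(after), nrow(after) > 0)
    stages$after <- after
  }
  purrr::imap(stages, \(dat, stage) {
    purrr::map(covariates, \(cv) {
      balance_row(dat, cv) |> mutate(stage = stage, .after = "covariate")
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

balance_row <- function(dat, cv) {
  x <- dat[[cv]]
  g <- factor(dat$device)
  continuous <- is.numeric(x) && length(unique(x)) > 5
  if (length(unique(x[!is.na(x)])) <= 1) {
    return(tibble::tibble(covariate = cv, type = "constant", smd = 0,
                          statistic = NA_real_, p_value = NA_real_,
                          note = "constant covariate; test skipped"))
  }
  if (continuous) {
    fit <- summary(aov(x ~ g))[[1]]
    tibble::tibble(covariate = cv, type = "continuous",
                   smd = max_pairwise_smd_cont(x, g),
                   statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
                   note = NA_character_)
  } else {
    tab <- table(x, g)
    ct <- suppressWarnings(chisq.test(tab))
    tibble::tibble(covariate = cv, type = "categorical",
                   smd = max_pairwise_smd_cat(x, g),
                   statistic = unname(ct$statistic),
                   p_value = unname(ct$p.value), note = NA_character_)
  }
}

max_pairwise_smd_cont <- function(x, g) {
  lv <- levels(droplevels(g))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  max(vapply(pairs, \(pr) {
    x1 <- x[g == pr[1]]; x2 <- x[g == pr[2]]
    pooled <- sqrt((var(x1) + var(x2)) / 2)
    if (pooled == 0) 0 else abs(mean(x1) - mean(x2)) / pooled
  }, numeric(1)))
}

max_pairwise_smd_cat <- function(x, g) {
  lv <- levels(droplevels(g))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  lev <- unique(x[!is.na(x)])
  max(vapply(pairs, \(pr) {
    max(vapply(lev, \(l) {
      p1 <- mean(x[g == pr[1]] == l); p2 <- mean(x[g == pr[2]] == l)
      pooled <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
      if (pooled == 0) 0 else abs(p1 - p2) / pooled
    }, numeric(1)))
  }, numeric(1)))
}
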