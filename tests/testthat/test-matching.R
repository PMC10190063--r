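test_that("propensity scores recover a known logistic model", {
  set.seed(101)
  n <- 4000
  age <- rnorm(n, 50, 10)
  eta <- -0.9 + 0.08 * (age - 50)
  device <- ifelse(runif(n) < plogis(eta), "PICC", "CVC")
  ch <- tibble::tibble(id = seq_len(n), device = device, age = age)
  sc <- estimate_propensity(ch, covariates = "age", pair = c("PICC", "CVC"))
  fit <- glm(I(device == "PICC") ~ age, family = binomial(), data = ch)
  expect_equal(sc$score, unname(predict(fit, type = "response")),
               tolerance = 1e-8)
  # hand-computed logistic at the fitted coefficients
  manual <- plogis(coef(fit)[1] + coef(fit)[2] * ch$age)
  expect_equal(sc$score, unname(manual), tolerance = 1e-8)
  # discrimination beats chance under genuine confounding
  expect_gt(empirical_auc(sc$score, as.integer(sc$device == "PICC")), 0.6)
})

test_that("scores concentrate at group prevalence without confounding", {
  set.seed(7)
  ch <- generate_cohort(n = 5000, confounding = no_confounding(), seed = 7)
  sc <- estimate_propensity(ch, pair = c("PICC", "CVC"))
  prev <- mean(sc$device == "PICC")
  expect_lt(sd(sc$score), 0.05)
  expect_equal(mean(sc$score), prev, tolerance = 0.02)
})

test_that("separation is reported as an actionable error", {
  set.seed(8)
  n <- 300
  x <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  ch <- tibble::tibble(id = seq_len(n),
                       device = rep(c("CVC", "PICC"), each = n / 2),
                       age = x)
  expect_error(estimate_propensity(ch, covariates = "age"),
               class = "vadcea_separation_error")
})

test_that("matching respects the caliper and samples without replacement", {
  ch <- generate_cohort(n = 5000, seed = 21)
  m <- match_cohort(ch, seed = 21)
  # 1:2:2 structure and no reuse of any patient
  expect_false(any(duplicated(m$matched$id)))
  counts <- m$matched |> dplyr::count(.data$stratum, .data$device)
  expect_true(all(counts$n[counts$device == "PICC"] == 1))
  expect_true(all(counts$n[counts$device != "PICC"] == 2))
  expect_equal(unname(m$n_matched["CVC"]), 2 * unname(m$n_matched["PICC"]))
  expect_equal(unname(m$n_matched["IVAP"]), 2 * unname(m$n_matched["PICC"]))
  # caliper bound holds for every matched pair, in both pairwise models
  for (arm in c("CVC", "IVAP")) {
    sc <- m$scores[[arm]]
    s <- setNames(sc$score, sc$id)
    per <- m$matched |> dplyr::filter(.data$device %in% c("PICC", arm))
    for (st in unique(per$stratum)) {
      ids <- per$id[per$stratum == st]
      ref <- per$id[per$stratum == st & per$device == "PICC"]
      others <- setdiff(ids, ref)
      expect_true(all(abs(s[as.character(others)] -
                            s[as.character(ref)]) <= m$caliper))
    }
  }
})

test_that("degenerate calipers and empty reference groups behave", {
  ch <- generate_cohort(n = 2000, seed = 31)
  tiny <- match_cohort(ch, caliper = 1e-7, seed = 31)
  expect_lt(sum(tiny$n_matched), 50)
  expect_error(match_cohort(ch |> dplyr::filter(device != "PICC")),
               class = "vadcea_empty_error")
  # near-identical scores (no confounding): essentially every reference
  # patient finds seeded partners inside the caliper
  flat <- generate_cohort(n = 3000, confounding = no_confounding(),
                          seed = 32)
  m <- match_cohort(flat, seed = 32)
  expect_gte(m$n_matched[["PICC"]], 0.95 * sum(flat$device == "PICC"))
})

test_that("matching improves balance on confounded cohorts", {
  worst <- function(bt) max(bt$smd)
  res <- vapply(c(11, 12, 13), function(sd) {
    ch <- generate_cohort(n = 4000, seed = sd)
    m <- match_cohort(ch, seed = sd)
    bt <- balance_table(ch, m$matched,
                        covariates = c("age", "weight",
                                       "thrombosis_history"))
    c(before = worst(bt[bt$stage == "before", ]),
      after = worst(bt[bt$stage == "after", ]))
  }, numeric(2))
  expect_true(all(res["after", ] < res["before", ]))
  expect_true(all(res["after", ] < 0.1))
})

test_that("balance table SMDs match the hand formula and handle constants", {
  set.seed(3)
  ch <- tibble::tibble(
    id = 1:300,
    device = rep(c("CVC", "PICC"), each = 150),
    age = c(rnorm(150, 52, 9), rnorm(150, 48, 10)),
    flag = 1
  )
  bt <- balance_table(ch, covariates = c("age", "flag"))
  expect_equal(bt$smd[bt$covariate == "age"],
               smd_two_group(ch$age[ch$device == "CVC"],
                             ch$age[ch$device == "PICC"]),
               tolerance = 1e-12)
  expect_equal(bt$smd[bt$covariate == "flag"], 0)
  expect_match(bt$note[bt$covariate == "flag"], "constant")
  # identical groups give SMD 0
  ch2 <- ch
  ch2$age <- rep(ch$age[1:150], 2)
  bt2 <- balance_table(ch2, covariates = "age")
  expect_equal(bt2$smd, 0, tolerance = 1e-12)
})

test_that("matched cohorts pass the statistical balance checks", {
  ch <- generate_cohort(n = 6000, seed = 99)
  m <- match_cohort(ch, seed = 99)
  bt <- balance_table(ch, m$matched)
  after <- bt[bt$stage == "after" & !is.na(bt$p_value), ]
  expect_true(all(after$p_value > 0.05))
})
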