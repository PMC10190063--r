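p0 <- default_parameters()

test_that("weighted utilities match hand arithmetic", {
  expect_equal(weighted_utility(p0, "PICC"),
               0.0728 * 0.862279 + (1 - 0.0728) * 0.8806194,
               tolerance = 1e-12)
  expect_equal(weighted_utility(p0, "PICC"), 0.879284, tolerance = 1e-6)
  expect_equal(weighted_utility(p0, "IVAP"), 0.944752, tolerance = 1e-6)
  # p = 0 returns the no-complication utility exactly
  pz <- set_param(p0, "p3_IVAP_complication", 0)
  expect_equal(weighted_utility(pz, "IVAP"),
               unname(param_value(p0, "u3_IVAP")))
})

test_that("expected complication costs are mix-weighted means times risk", {
  # brute-force sum over the nine CVC complication types
  mix <- p0$mix[p0$mix$arm == "CVC", ]
  brute <- 0.0734 * sum(mix$share * param_value(p0, mix$cost_key))
  expect_equal(expected_complication_cost(p0, "CVC"), brute,
               tolerance = 1e-12)
  expect_equal(expected_complication_cost(p0, "CVC"), 2.9918,
               tolerance = 1e-4)

  pz <- set_param(p0, "p1_CVC_complication", 0)
  expect_equal(expected_complication_cost(pz, "CVC"), 0)

  # single type with cost 100 at p = 0.5 costs 50 in expectation
  p1 <- p0
  p1$mix <- p1$mix[p1$mix$arm != "IVAP" | p1$mix$type == "occlusion", ]
  p1$mix$share[p1$mix$arm == "IVAP"] <- 1
  p1 <- set_param(p1, "c_complication_occlusion", 100)
  p1 <- set_param(p1, "p3_IVAP_complication", 0.5)
  expect_equal(expected_complication_cost(p1, "IVAP"), 50)

  # a mix type without a cost parameter is an error
  p2 <- p0
  p2$mix$cost_key[1] <- "c_complication_unknown"
  expect_error(expected_complication_cost(p2, "CVC"),
               class = "vadcea_key_error")
})

test_that("arm outcomes decompose into their components", {
  for (arm in arm_names()) {
    for (dw in list("6m", "12m", "full", 0.25)) {
      o <- evaluate_arm(p0, arm, dw)
      expect_equal(o$cost,
                   o$cost_insertion + o$cost_maintenance + o$cost_removal +
                     o$cost_complication, tolerance = 1e-9)
      expect_equal(o$qaly, o$qaly_on_catheter + o$qaly_intermission,
                   tolerance = 1e-12)
      expect_true(all(c(o$cost_insertion, o$cost_maintenance,
                        o$cost_removal, o$cost_complication) >= 0))
      expect_gte(o$qaly, 0)
    }
  }
  # dwell -> 0 leaves only insertion + removal + complication for simple arms
  tiny <- evaluate_arm(p0, "IVAP", 1e-12)
  expect_equal(tiny$cost,
               844.8203 + 82.3272 + expected_complication_cost(p0, "IVAP"),
               tolerance = 1e-6)
})

# median survival key per arm
arm_param_keys_test <- function(arm) {
  c(PICC = "T2_PICC_medianSurvivalTime",
    IVAP = "T3_IVAP_medianSurvivalTime")[[arm]]
}

test_that("costs are monotone in dwell and QALYs plateau at the median", {
  dwells <- c(0.05, 0.2, 0.4137, 0.8, 1.5, 2.8493, 5)
  for (arm in c("PICC", "IVAP")) {
    out <- purrr::map(dwells, \(d) evaluate_arm(p0, arm, d)) |>
      purrr::list_rbind()
    expect_true(all(diff(out$cost) >= -1e-9))
    expect_true(all(diff(out$qaly) >= -1e-12))
    med <- unname(param_value(p0, arm_param_keys_test(arm)))
    pre <- dwells < med
    expect_true(all(diff(out$qaly[pre]) > 0))
    post <- which(dwells >= med)
    if (length(post) > 1) {
      expect_equal(out$qaly[post], rep(out$qaly[post[1]], length(post)),
                   tolerance = 1e-12)
    }
  }
  # the CVC composite spans the whole course regardless of dwell
  cvc <- purrr::map(dwells, \(d) evaluate_arm(p0, "CVC", d)) |>
    purrr::list_rbind()
  expect_equal(cvc$cost, rep(cvc$cost[1], length(dwells)), tolerance = 1e-12)
  expect_equal(cvc$qaly, rep(cvc$qaly[1], length(dwells)), tolerance = 1e-12)
})

test_that("removing complications removes exactly the complication component", {
  pz <- p0
  for (k in c("p1_CVC_complication", "p2_PICC_complication",
              "p3_IVAP_complication")) {
    pz <- set_param(pz, k, 0)
  }
  for (arm in arm_names()) {
    a <- evaluate_arm(p0, arm, "full")
    z <- evaluate_arm(pz, arm, "full")
    expect_equal(z$cost_complication, 0)
    expect_equal(a$cost - z$cost, a$cost_complication, tolerance = 1e-9)
    expect_equal(weighted_utility(pz, arm),
                 unname(param_value(p0, paste0(
                   c(CVC = "u1_CVC", PICC = "u2_PICC",
                     IVAP = "u3_IVAP")[[arm]]))))
  }
})

test_that("expected values equal brute-force enumeration over all tree paths", {
  n_paths <- 0
  for (arm in arm_names()) {
    for (dw in c(180 / 365, 1, Inf)) {
      oracle <- enumerate_tree(p0, arm, dw)
      o <- evaluate_arm(p0, arm, if (is.infinite(dw)) "full" else dw)
      expect_equal(o$cost, oracle$cost, tolerance = 1e-9)
      expect_equal(o$qaly, oracle$qaly, tolerance = 1e-9)
    }
    n_paths <- n_paths + enumerate_tree(p0, arm, Inf)$n_paths
  }
  expect_equal(n_paths, 27) # 10 CVC + 9 PICC + 8 IVAP subbranches
})

test_that("the scenario table reproduces the published base case", {
  out <- scenario_table(p0)
  expect_equal(nrow(out), 9)
  get <- function(arm, dw, col) out[[col]][out$arm == arm & out$dwell == dw]
  expect_equal(get("CVC", "full", "cost"), 542.36, tolerance = 1e-4)
  expect_equal(get("PICC", "full", "cost"), 827.82, tolerance = 1e-4)
  expect_equal(get("IVAP", "full", "cost"), 2043.12, tolerance = 1e-4)
  expect_equal(get("IVAP", "12m", "cost"), 1320.06, tolerance = 1e-4)
  expect_equal(round(get("IVAP", "full", "qaly"), 2), 2.69)
  expect_error(scenario_table(p0, dwells = character()),
               class = "vadcea_empty_error")
})
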