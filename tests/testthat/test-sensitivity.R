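p0 <- default_parameters()

test_that("one-way DSA covers all 37 parameters and sorts by spread", {
  dsa <- one_way_dsa(p0, pair = c("IVAP", "PICC"))
  expect_equal(nrow(dsa), 37)
  expect_true(all(diff(dsa$spread) <= 1e-12))
  expect_true(all(dsa$spread >= 0))
  # endpoints at the base value reproduce the base-case ICER
  base <- attr(dsa, "icer_base")
  row <- dsa[dsa$key == "c1_CVC_insertion", ] # CVC params cannot move it
  expect_equal(row$icer_low, base, tolerance = 1e-12)
  expect_equal(row$icer_high, base, tolerance = 1e-12)
  expect_error(one_way_dsa(p0, keys = "nope"), class = "vadcea_key_error")
})

test_that("zero-width intervals give zero spread and costs act linearly", {
  q <- p0
  i <- match("c2_PICC_insertion", q$params$key)
  q$params$dsa_low[i] <- q$params$mean[i]
  q$params$dsa_high[i] <- q$params$mean[i]
  dsa <- one_way_dsa(q, pair = c("IVAP", "PICC"), keys = "c2_PICC_insertion")
  expect_equal(dsa$spread, 0, tolerance = 1e-12)

  # +/-10% excursions of a cost parameter shift the ICER symmetrically
  q2 <- p0
  j <- match("c3_IVAP_insertion", q2$params$key)
  q2$params$dsa_low[j] <- q2$params$mean[j] * 0.9
  q2$params$dsa_high[j] <- q2$params$mean[j] * 1.1
  dsa2 <- one_way_dsa(q2, pair = c("IVAP", "PICC"),
                      keys = "c3_IVAP_insertion")
  base <- attr(dsa2, "icer_base")
  expect_equal(dsa2$icer_high - base, base - dsa2$icer_low,
               tolerance = 1e-9)
})

test_that("per-visit maintenance costs dominate the tornado", {
  vs_picc <- one_way_dsa(p0, pair = c("IVAP", "PICC"))
  expect_setequal(vs_picc$key[1:2],
                  c("c3_IVAP_perMaintenance", "c2_PICC_perMaintenance"))
  vs_cvc <- one_way_dsa(p0, pair = c("IVAP", "CVC"))
  expect_equal(vs_cvc$key[1], "c3_IVAP_perMaintenance")
})

test_that("PSA draws are reproducible, support-respecting and mean-centred", {
  a <- sample_psa(p0, n = 400, seed = 5)
  b <- sample_psa(p0, n = 400, seed = 5)
  expect_equal(a$draws, b$draws)
  expect_equal(a$outcomes, b$outcomes)
  expect_false(identical(a$draws, sample_psa(p0, n = 400, seed = 6)$draws))

  d <- a$draws
  cost_keys <- p0$params$key[p0$params$kind == "cost"]
  expect_true(all(as.matrix(d[cost_keys]) > 0))
  u_keys <- p0$params$key[p0$params$kind == "utility"]
  expect_true(all(as.matrix(d[u_keys]) >= 0 & as.matrix(d[u_keys]) <= 1))
  p_keys <- p0$params$key[p0$params$kind == "probability"]
  expect_true(all(as.matrix(d[p_keys]) >= 0 & as.matrix(d[p_keys]) <= 1))
  expect_true(all(d$CVC_mean_insertionTimes >= 1))
  expect_true(all(d$CVC_intermission >= 0))
  # fixed intervals never move
  expect_equal(unique(d$T2_PICC_maintenanceInterval), 0.0192)
})

test_that("degenerate PSA (all spreads zero) reproduces the base case", {
  q <- p0
  q$params$psa_sd <- 0
  psa <- sample_psa(q, n = 50, seed = 1)
  base <- scenario_table(q, "full")
  for (arm in arm_names()) {
    oc <- psa$outcomes[psa$outcomes$arm == arm, ]
    expect_equal(oc$cost, rep(base$cost[base$arm == arm], 50),
                 tolerance = 1e-12)
    expect_equal(oc$qaly, rep(base$qaly[base$arm == arm], 50),
                 tolerance = 1e-12)
  }
})

test_that("PSA outcome means track the base case", {
  psa <- sample_psa(p0, n = 4000, seed = 9)
  base <- scenario_table(p0, "full")
  agg <- psa$outcomes |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(cost = mean(.data$cost), qaly = mean(.data$qaly))
  for (arm in arm_names()) {
    expect_lt(abs(agg$cost[agg$arm == arm] /
                    base$cost[base$arm == arm] - 1), 0.02)
    expect_lt(abs(agg$qaly[agg$arm == arm] /
                    base$qaly[base$arm == arm] - 1), 0.02)
  }
})

test_that("acceptability curves partition the draws and cross over", {
  psa <- sample_psa(p0, n = 2000, seed = 13)
  grid <- seq(0, 40000, length.out = 41)
  cc <- ceac(psa, grid)
  sums <- cc |>
    dplyr::group_by(.data$wtp) |>
    dplyr::summarise(s = sum(.data$probability))
  expect_equal(sums$s, rep(1, length(grid)), tolerance = 1e-9)

  at <- function(w, arm) cc$probability[cc$wtp == w & cc$arm == arm]
  expect_gt(at(0, "CVC"), 0.99)
  # IVAP overtakes CVC somewhere on the grid and stays largest at the
  # configured willingness-to-pay
  p_cvc <- vapply(grid, at, numeric(1), arm = "CVC")
  p_ivap <- vapply(grid, at, numeric(1), arm = "IVAP")
  expect_true(any(p_ivap > p_cvc))
  expect_true(any(p_cvc > p_ivap))
  crossing <- grid[min(which(p_ivap > p_cvc))]
  expect_lt(crossing, 10000)
  w_star <- grid[which.min(abs(grid - 34794.8108))]
  expect_equal(which.max(c(at(w_star, "CVC"), at(w_star, "PICC"),
                           at(w_star, "IVAP"))), 3)
})

test_that("the incremental scatter sits where the base case predicts", {
  psa <- sample_psa(p0, n = 1500, seed = 17)
  sc <- psa_scatter(psa, reference = "CVC")
  self <- sc[sc$comparator == "CVC", ]
  expect_true(all(self$delta_cost == 0 & self$delta_qaly == 0))
  ivap <- sc[sc$comparator == "IVAP", ]
  expect_gt(mean(ivap$delta_cost), 0)
  expect_gt(mean(ivap$delta_qaly), 0)
  base <- scenario_table(p0, "full")
  expect_equal(sign(mean(ivap$delta_cost)),
               sign(base$cost[base$arm == "IVAP"] -
                      base$cost[base$arm == "CVC"]))
  expect_error(psa_scatter(psa, reference = "PORT"), "not present")
})

test_that("plot builders return ggplot objects", {
  dsa <- one_way_dsa(p0, pair = c("IVAP", "PICC"),
                     keys = dsa_keys(p0)[1:5])
  expect_s3_class(plot_tornado(dsa), "ggplot")
  psa <- sample_psa(p0, n = 100, seed = 3)
  expect_s3_class(ggplot2::autoplot(ceac(psa, c(0, 20000))), "ggplot")
  expect_s3_class(ggplot2::autoplot(psa_scatter(psa)), "ggplot")
})
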