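test_that("packaged base-case parameters carry the expected values", {
  p <- default_parameters()
  expect_equal(unname(param_value(p, "c3_IVAP_insertion")), 844.8203)
  expect_equal(unname(param_value(p, "p2_PICC_complication")), 0.0728)
  expect_equal(unname(param_value(p, "CVC_mean_insertionTimes")), 4.5589)
  expect_equal(unname(param_value(p, "u1_CVC_intermission")), 0.814)
  # complication probabilities are consistent with the event counts
  expect_equal(p$events[["PICC"]] / p$arm_n[["PICC"]], 0.0728,
               tolerance = 2e-3)
  expect_equal(p$events[["IVAP"]] / p$arm_n[["IVAP"]], 0.0384,
               tolerance = 2e-3)
  # 37 parameters are eligible for sensitivity analysis (the two fixed
  # maintenance intervals carry no distribution)
  expect_length(dsa_keys(p), 37)
  expect_setequal(setdiff(p$params$key, dsa_keys(p)),
                  c("T2_PICC_maintenanceInterval",
                    "T3_IVAP_maintenanceInterval"))
  # per-arm mix counts match the per-arm complication totals
  counts <- tapply(p$mix$count, p$mix$arm, sum)
  expect_equal(counts[names(p$events)], p$events,
               ignore_attr = TRUE)
})

test_that("parameter validation catches broken inputs", {
  p <- default_parameters()
  expect_error(param_value(p, "no_such_key"), class = "vadcea_key_error")
  expect_error(set_param(p, "u2_PICC", 1.2))
  expect_error(set_param(p, "c2_PICC_insertion", -5))
  bad <- p
  bad$params$mean[bad$params$key == "u3_IVAP"] <- 1.7
  expect_error(validate_parameters(bad), class = "vadcea_validation_error")
  bad2 <- p
  bad2$params <- bad2$params[bad2$params$key != "p2_PICC_complication", ]
  expect_error(validate_parameters(bad2), class = "vadcea_schema_error")
  bad3 <- p
  i <- bad3$params$key == "CVC_intervals"
  bad3$params$mean[i] <- 2.5
  bad3$params$ci_low[i] <- NA
  bad3$params$ci_high[i] <- NA
  expect_error(validate_parameters(bad3), "insertionTimes")
})

test_that("config files round-trip in both dialects", {
  p <- default_parameters()
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_parameters(p, path)
    q <- load_parameters(path)
    expect_equal(q$params$mean, p$params$mean, tolerance = 1e-12)
    expect_equal(q$params$key, p$params$key)
    expect_equal(q$mix$count, p$mix$count)
    expect_equal(unlist(q$arm_n), unlist(p$arm_n), ignore_attr = TRUE)
    expect_equal(q$settings$wtp, p$settings$wtp)
    # evaluation is identical through the round trip
    expect_equal(evaluate_arm(q, "IVAP", "full")$cost,
                 evaluate_arm(p, "IVAP", "full")$cost, tolerance = 1e-9)
  }
})

test_that("malformed config files fail with informative schema errors", {
  p <- default_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, path)
  obj <- jsonlite::read_json(path)
  obj$parameters$p2_PICC_complication <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(path2), "p2_PICC_complication",
               class = "vadcea_schema_error")

  obj2 <- jsonlite::read_json(path)
  obj2$parameters$u2_PICC$mean <- 1.2
  path3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, path3, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(path3), class = "vadcea_validation_error")

  obj3 <- jsonlite::read_json(path)
  obj3$parameters$c1_CVC_removal$mean <- -8
  path4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj3, path4, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(path4), class = "vadcea_validation_error")
})

test_that("method-of-moments hyperparameters reproduce the worked examples", {
  d <- derive_sampling_distribution(68.0747, 43.2521, "gamma")
  expect_equal(d$pars$shape, (68.0747 / 43.2521)^2, tolerance = 1e-12)
  expect_equal(d$pars$rate, 68.0747 / 43.2521^2, tolerance = 1e-12)
  expect_equal(d$pars$shape, 2.477, tolerance = 5e-4)
  expect_equal(d$pars$rate, 0.03639, tolerance = 5e-4)
  # CI-halfwidth rule for the per-visit maintenance cost
  sd_c2 <- (42.9217 - 0.433) / (2 * qnorm(0.975))
  d2 <- derive_sampling_distribution(21.6773, sd_c2, "gamma")
  expect_equal(d2$pars$shape / d2$pars$rate, 21.6773, tolerance = 1e-9)

  expect_equal(draw_dist(derive_sampling_distribution(0.5, 0, "beta"), 3),
               rep(0.5, 3))
  expect_error(derive_sampling_distribution(0.9, 0.5, "beta"), "infeasible")
})

test_that("derived distributions match their target moments", {
  cases <- list(
    list(mean = 68.07, sd = 43.25, family = "gamma"),
    list(mean = 21.68, sd = 10.84, family = "gamma"),
    list(mean = 0.88, sd = 0.05, family = "beta"),
    list(mean = 0.0384, sd = 0.005, family = "beta"),
    list(mean = 4.5589, sd = 0.0727, family = "normal"),
    list(mean = 0.01096, sd = 0.001, family = "lognormal-median"),
    list(mean = 2.8493, sd = 0.28, family = "lognormal-median")
  )
  for (cs in cases) {
    d <- derive_sampling_distribution(cs$mean, cs$sd, cs$family)
    mom <- switch(d$family,
      gamma = c(d$pars$shape / d$pars$rate,
                sqrt(d$pars$shape) / d$pars$rate),
      beta = {
        a <- d$pars$a; b <- d$pars$b
        c(a / (a + b), sqrt(a * b / ((a + b)^2 * (a + b + 1))))
      },
      normal = c(d$pars$mean, d$pars$sd),
      `lognormal-median` = {
        m <- exp(d$pars$meanlog + d$pars$sdlog^2 / 2)
        v <- (exp(d$pars$sdlog^2) - 1) * m^2
        c(m, sqrt(v))
      })
    expect_equal(mom[1], cs$mean, tolerance = 1e-9)
    expect_equal(mom[2], cs$sd, tolerance = 1e-6)
  }
})

test_that("Gompertz median algebra is self-consistent", {
  for (a in c(0.2, 1, 3)) {
    for (m in c(0.05, 0.4137, 2.8493)) {
      b <- gompertz_rate_for_median(a, m)
      expect_equal(gompertz_median(a, b), m, tolerance = 1e-10)
      expect_equal(flexsurv::pgompertz(m, a, b, lower.tail = FALSE), 0.5,
                   tolerance = 1e-10)
    }
  }
  # exponential limit
  expect_equal(gompertz_rate_for_median(0, 0.5), log(2) / 0.5)
})
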