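# Independent oracles used across tests. These deliberately avoid the
# package's own evaluation code paths.

# Brute-force enumeration of the decision tree's terminal branches for one
# arm: one path per complication type plus the no-complication path
# (9 + 1 for CVC, 8 + 1 for PICC, 7 + 1 for IVAP -> 27 paths over the
# three arms). Expected values are probability-weighted sums of per-path
# payoffs.
enumerate_tree <- function(params, arm, dwell_years) {
  pv <- function(key) unname(param_value(params, key))
  mix <- params$mix[params$mix$arm == arm, ]
  if (arm == "CVC") {
    p <- pv("p1_CVC_complication")
    base_cost <- pv("CVC_mean_insertionTimes") *
      (pv("c1_CVC_insertion") + pv("c1_CVC_maintenance") +
         pv("c1_CVC_removal"))
    t_on <- pv("CVC_mean_insertionTimes") * pv("T1_CVC_medianSurvivalTime")
    q_extra <- pv("CVC_intervals") * pv("CVC_intermission") *
      pv("u1_CVC_intermission")
    u <- pv("u1_CVC"); uc <- pv("u1_CVC_complication")
  } else {
    ak <- if (arm == "PICC") {
      list(p = "p2_PICC_complication", ins = "c2_PICC_insertion",
           per = "c2_PICC_perMaintenance", rem = "c2_PICC_removal",
           med = "T2_PICC_medianSurvivalTime",
           int = "T2_PICC_maintenanceInterval", u = "u2_PICC",
           uc = "u2_PICC_complication")
    } else {
      list(p = "p3_IVAP_complication", ins = "c3_IVAP_insertion",
           per = "c3_IVAP_perMaintenance", rem = "c3_IVAP_removal",
           med = "T3_IVAP_medianSurvivalTime",
           int = "T3_IVAP_maintenanceInterval", u = "u3_IVAP",
           uc = "u3_IVAP_complication")
    }
    p <- pv(ak$p)
    t_on <- min(dwell_years, pv(ak$med))
    base_cost <- pv(ak$ins) + (t_on / pv(ak$int)) * pv(ak$per) + pv(ak$rem)
    q_extra <- 0
    u <- pv(ak$u); uc <- pv(ak$uc)
  }
  paths <- data.frame(prob = 1 - p, cost = base_cost,
                      qaly = t_on * u + q_extra)
  for (i in seq_len(nrow(mix))) {
    paths <- rbind(paths, data.frame(
      prob = p * mix$share[i],
      cost = base_cost + unname(param_value(params, mix$cost_key[i])),
      qaly = t_on * uc + q_extra
    ))
  }
  list(cost = sum(paths$prob * paths$cost),
       qaly = sum(paths$prob * paths$qaly),
       n_paths = nrow(paths))
}

# textbook two-group standardised mean difference
smd_two_group <- function(x1, x2) {
  abs(mean(x1) - mean(x2)) / sqrt((var(x1) + var(x2)) / 2)
}

# closed-form 2x2 Pearson chi-square
chisq_2x2_closed_form <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# empirical AUC of scores against a binary label
empirical_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ICER-ladder decision on a set of outcomes: drop dominated options, then
# walk the efficiency frontier accepting each step whose ICER is below WTP
icer_ladder_decision <- function(cost, qaly, wtp) {
  ord <- order(cost, qaly)
  cost <- cost[ord]; qaly <- qaly[ord]; idx <- ord
  # strict dominance removal
  keep <- rep(TRUE, length(cost))
  for (i in seq_along(cost)) {
    if (any(cost <= cost[i] & qaly >= qaly[i] &
              (cost < cost[i] | qaly > qaly[i]))) keep[i] <- FALSE
  }
  cost <- cost[keep]; qaly <- qaly[keep]; idx <- idx[keep]
  # extended dominance: enforce increasing ICERs along the frontier
  repeat {
    if (length(cost) < 3) break
    ic <- diff(cost) / diff(qaly)
    bad <- which(diff(ic) < 0)
    if (length(bad) == 0) break
    drop <- bad[1] + 1
    cost <- cost[-drop]; qaly <- qaly[-drop]; idx <- idx[-drop]
  }
  choice <- 1
  if (length(cost) > 1) {
    ic <- diff(cost) / diff(qaly)
    for (j in seq_along(ic)) if (ic[j] <= wtp) choice <- j + 1 else break
  }
  idx[choice]
}
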