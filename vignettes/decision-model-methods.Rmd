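---
title: "Methods: a decision-tree cost-utility model for venous access devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree cost-utility model for venous access devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vadcea)
```

## The model and its assumptions

`vadcea` evaluates a single-shot decision tree with three root branches —
CVC, PICC and IVAP — each splitting into a no-complication branch and one
branch per complication type observed for that device (9 types for CVC, 8
for PICC, 7 for IVAP; 27 terminal paths in total). It is a decision tree,
not a Markov model: there are no health-state transitions or cycles, so no
half-cycle correction applies, and with the short time frame neither costs
nor utilities are discounted.

Assumptions worth making explicit:

* **Complications are a per-course event.** The complication probability
  counts patients with at least one complication over the whole course, and
  the expected management cost (probability times the mix-weighted per-type
  cost) is charged once per patient — for CVC too, even though its course
  spans several insertion episodes. Utilities are likewise weighted once by
  the complication split.
* **Maintenance is proportional to dwell.** PICC and IVAP maintenance
  accrues per visit at one visit per maintenance interval (0.0192 y ≈ 7 d
  for PICC, 0.0822 y ≈ 30 d for IVAP), with *fractional* visit counts
  allowed: the expected visit count of a patient population need not be an
  integer, and rounding would bias twelve-month costs visibly.
* **Dwell scenarios cap effective time at the median.** At dwell `d` the
  on-catheter time is `min(d, median survival)`; the "more than 12 months"
  scenario is evaluated at the full median. Only IVAP's median (2.8493 y)
  exceeds one year, which is why CVC and PICC results are identical across
  scenarios.
* **The CVC arm is a composite.** Costs scale with the mean insertion count
  (4.5589); QALYs add an on-catheter part (insertions × per-catheter median
  dwell × weighted utility) and an intermission part (3.5589 intermissions ×
  0.0686 y × utility 0.814). The composite is invariant to the dwell
  scenario because the insertion cycle spans the course by construction.
* **Day-count conventions.** One month is 30 days and one year 365 days, so
  the six-month scenario is 180 days while the twelve-month scenario is a
  full 365-day year. Under these conventions the six-month IVAP cost implies
  essentially exactly six monthly visits (180/30, with 0.0822 y = 30.0 d)
  and the twelve-month cost implies 365/30.0 ≈ 12.17 visits; no other
  convention reproduces both scenario columns simultaneously.

Cost-effectiveness algebra follows the standard definitions: CER =
cost/QALY; ICER = Δcost/ΔQALY for pairs with same-signed increments, with
explicit dominance flags otherwise. The recommendation maximises net
monetary benefit (WTP × QALY − cost), which on non-dominated frontiers is
equivalent to walking the ICER ladder against the threshold (a property the
test suite checks by brute force over random outcome triples) but stays
well-defined under dominance and exact ties (ties go to the cheaper arm).

## Parameters

All parameters live in a flat, key-addressable table
(`default_parameters()`), in USD, years and dimensionless utilities:
per-arm insertion/maintenance/removal costs, twelve per-type complication
management costs, three complication probabilities with per-type mixes,
six health-state utilities plus the CVC intermission utility, three median
survival times, two maintenance intervals, and the CVC cycle quantities.
The willingness-to-pay threshold defaults to $34,794.81/QALY; the RMB
conversion rate (6.9838) is retained as metadata only — everything is
computed in USD.

Two derived ranges accompany each parameter:

* **One-way bounds** (`dsa_low`, `dsa_high`): the printed 95% confidence
  interval where one exists, otherwise mean ± 10%. Bounds are clamped to
  the parameter's natural support (costs at zero — several printed cost
  intervals dip below zero — and probabilities/utilities at one). The two
  fixed maintenance intervals have no uncertainty range, leaving 37
  parameters in the tornado.
* **PSA uncertainty SDs** (`psa_sd`): the probabilistic analysis propagates
  *parameter-estimate* uncertainty, not patient-level heterogeneity, so the
  sampling SD is the CI half-width over 1.96 where the CI is an interval
  for the mean. The two per-visit maintenance costs print patient-level
  mean ± 1.96 SD bands instead (they span roughly zero to twice the mean);
  feeding that scale into the PSA would make the cheapest arm lose its
  cost ranking in a quarter of draws, contradicting the deterministic
  ordering the model produces, so their band-derived SD is divided by the
  square root of the arm sample size to convert it to a standard error.
  Where neither SD nor CI exists, 10% of the mean is used, mirroring the
  one-way fallback rule.

Sampling families are assigned by parameter class, all moment-matched:
gamma for costs (asymmetric, positive), beta for utilities, Beta(events,
n − events) for complication probabilities (their uncertainty is binomial,
and the event counts are known), normal for the CVC cycle quantities
(truncated to their support after sampling: nonnegative lengths, at least
one insertion), a median-centred lognormal for the CVC survival median and
Gompertz-parameter perturbation for the PICC/IVAP medians, both at a 10%
coefficient of variation (the survival uncertainty scale is not reported
anywhere; 10% is a conventional moderate choice and the acceptability-curve
conclusions are insensitive to halving or doubling it). Complication-type
mixes are held fixed in the PSA; only the overall probability is sampled.

## The synthetic cohort generator

No patient-level data are distributed with the package, so
`generate_cohort()` creates records with the statistical structure the
analysis assumes, enabling end-to-end parameter-recovery testing:

* eleven matching covariates with plausible marginals for a Chinese
  breast-cancer population (age ~ N(50, 10²) y, ~99% female, ~93% Han,
  four education levels, height ~ N(158, 6²) cm, weight ~ N(58, 9²) kg,
  five binary histories);
* device assignment through a multinomial logit on those covariates
  (default: older, heavier patients with vascular comorbidity toward IVAP
  and away from PICC), with intercepts targeting 40/16/44% prevalence so
  PICC is the smallest group, as in the 1:2:2 matched design;
* Bernoulli complication events at the arm probabilities, categorical type
  draws from the arm mixes, and gamma itemised costs. Patient-level cost
  spreads use the printed SD, else the 95% band width over 3.92, else 10%
  of the mean;
* catheter survival: lognormal per-catheter dwell for CVC (median 0.01096 y,
  `sdlog` 0.5 — about a fourfold 95% range, typical of short-dwell
  lines) and Gompertz dwell for PICC/IVAP with shape 1/y (a mildly
  increasing removal hazard) and rate solved from the target median via
  `b = a log 2 / (e^{a t50} − 1)`;
* CVC insertion counts as 1 + Poisson(3.5589), preserving the printed mean,
  with gamma intermission lengths (a truncated normal at the printed
  patient SD 0.1772 > mean 0.0686 would shift the mean badly; gamma
  preserves it exactly);
* optional uniform right-censoring (`censoring_fraction`, default 0: the
  emulated courses run from insertion to removal by inclusion criteria).

What the generator does *not* emulate: calendar enrolment, billing-system
record layouts, within-patient correlation between cost components,
repeat-complication episodes, or covariate effects on complication risk and
survival (devices are confounded on covariates; outcomes given the device
are not). Parameter-recovery tests passing on this cohort therefore
validate the estimation arithmetic and the matching/fitting machinery, not
the model's fidelity to any real hospital population.

## Matching, survival fitting, estimation

The three-group 1:2:2 nearest-neighbour caliper design is realised as two
pairwise logistic propensity models sharing the PICC reference (PICC vs
CVC, PICC vs IVAP). Reference patients are processed in seeded random
order; each greedily takes its two nearest available neighbours per arm
within the caliper (0.1, applied on the probability scale — scores live in
(0, 1); a `scale = "logit"` flag is provided since the caliper scale is a
genuine modelling choice), without replacement, and a stratum short of any
partner is dropped whole. Balance diagnostics report standardised mean
differences (largest pairwise SMD across the three groups) with one-way
ANOVA for continuous and Pearson chi-square for categorical covariates.

Parametric survival fitting (exponential, Weibull, lognormal, Gompertz) is
maximum likelihood with right-censoring via `flexsurv::flexsurvreg()`;
family selection takes the minimum AIC, with exact ties broken toward fewer
parameters, and refuses to compare fits made on different data. A
Kaplan-Meier estimator (median = first time the survivor curve reaches
0.5, flagged as undefined if it never does) provides the nonparametric
cross-check. Estimation reverses the generator: per-episode costs for CVC
(totals divided by insertion counts), per-visit maintenance for PICC/IVAP
(totals divided by dwell/interval), complication probabilities as
patients-with-event over arm size, mixes from type counts, medians from the
selected fits. Utilities and maintenance intervals are not estimable from
the cohort and are carried over from the template parameter set.

## Numerical choices and degenerate inputs

* Method-of-moments conversions reproduce target means exactly and SDs to
  numerical precision; `sd = 0` yields an explicit point mass, and a beta
  SD with `sd² ≥ mean(1 − mean)` is rejected as infeasible.
* Gompertz medians use `log1p`/`expm1` forms with an exponential fallback
  below |shape| < 1e−12; a negative shape without a finite median errors.
* The decision-tree arithmetic is one vectorised code path shared by the
  base case and the PSA; the test suite pins it to an independent
  brute-force enumeration of all 27 terminal branches at 1e−9.
* Parametric fits require at least ten uncensored events; all-censored
  input, nonpositive times and optimizer non-convergence are distinct
  errors. CEAC ties are broken toward the cheaper arm via an infinitesimal
  cost penalty (1e−12 × cost) rather than row order.
* Config round-trips (JSON and YAML) restore parameters to better than
  1e−9 relative; schema errors name the missing field, and support
  violations (negative costs, utilities above one) are rejected on load.

## Problem sizes used by the test suite

The suite exercises parameter recovery on a 100,000-patient cohort
(probabilities to ±0.005 absolute, component cost means to ±2%, medians to
±3%), AIC family selection on 20 replicates of 3,000 uncensored dwell
times per family (the generating family must win at least 90% of
replicates), the probabilistic analysis at 10,000 draws (outcome means
within 2% of base case; CVC optimal with probability > 0.99 at WTP 0; IVAP
the modal choice at the threshold), and the tornado over all 37 eligible
parameters for both IVAP comparisons. These sizes give comfortable
statistical margins for every asserted tolerance while keeping the suite
fast enough to run routinely.

## Known limitations

* The model inherits the single-centre cost structure and utilities of its
  inputs; nothing in the package re-weights them to other settings.
* Catheter survival is cause-agnostic: removal is the event and anything
  else is censoring. A competing-risks treatment (e.g. Fine-Gray) would
  need an estimand the consumed medians do not encode.
* The per-visit maintenance SE conversion and the 10% survival CV are
  modelling choices where the source tables print no uncertainty on the
  relevant scale; both are isolated in one place (`psa_sd` and
  `survival_cv`) and easy to vary.
* The twelve-type complication-mix contingency table can be tested with
  `chi_square_test()`, but its structural zeros (types never observed for
  some devices) make the all-type statistic convention-dependent, so the
  package takes no position on it.
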