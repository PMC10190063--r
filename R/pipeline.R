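#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> match -> fit survival -> estimate -> evaluate on
#' a synthetic cohort: generates patients at the supplied ground truth,
#' rebalances the arms by propensity-score matching, fits and selects the
#' survival families, re-estimates the model parameters from the matched
#' cohort, and evaluates the decision tree plus cost-utility table from the
#' estimates. A master seed deterministically spawns per-stage child seeds,
#' so stages can be rerun in isolation and the whole pipeline is
#' reproducible.
#'
#' @param n Cohort size before matching.
#' @param params Ground-truth `vad_parameters`.
#' @param dwells Dwell scenarios for the evaluation stage.
#' @param match_args Extra arguments passed to [match_cohort()].
#' @param seed Master seed.
#' @return List of class `vad_pipeline`: `cohort`, `match`, `estimates`
#'   (a `vad_parameters`), `outcomes`, `cea`, `seed`.
#' @export
run_pipeline <- function(n = 10718, params = default_parameters(),
                         dwells = c("6m", "12m", "full"),
                         match_args = list(), seed = NULL) {
  cohort <- generate_cohort(n = n, params = params,
                            seed = child_seed(seed, "simulate"))
  m <- do.call(match_cohort,
               c(list(cohort = cohort, seed = child_seed(seed, "match")),
                 match_args))
  estimates <- estimate_parameters(m$matched, template = params)
  outcomes <- scenario_table(estimates, dwells)
  structure(
    list(cohort = cohort, match = m, estimates = estimates,
         outcomes = outcomes,
         cea = cea_table(outcomes, wtp = params$settings$wtp), seed = seed),
    class = "vad_pipeline"
  )
}

#' Command-line driver
#'
#' A thin argument-vector interface over the package functions, used by the
#' `inst/cli/vadcea.R` script. Subcommands: `simulate` (write a synthetic
#' cohort CSV), `match` (match a cohort CSV and write the matched rows),
#' `fit-survival` (fit all families per arm, write JSON fit summaries),
#' `estimate` (estimate parameters from a cohort, write a config),
#' `evaluate` (scenario + cost-utility table from a config), `dsa`
#' (tornado CSV), `psa` (draws/CEAC/scatter CSVs), and `base-case` (the
#' packaged base-case parameters through evaluate + dsa + psa, no cohort
#' needed). Every run writes a manifest JSON with the seed, options and
#' package version.
#'
#' @param args Character vector of arguments, e.g.
#'   `c("base-case", "--outdir", "out")`. Flags: `--config`, `--seed`,
#'   `--n`, `--wtp`, `--dwell`, `--outdir`, `--format`.
#' @return Invisibly, the output directory. Unknown subcommands or
#'   unreadable configs raise errors.
#' @export
vad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop_vad("usage: vadcea <simulate|match|fit-survival|estimate|evaluate",
             "|dsa|psa|base-case> [--config F] [--seed S] [--n N] ",
             "[--wtp W] [--dwell D] [--outdir DIR] [--format csv|json]")
  }
  cmd <- args[1]
  opt <- parse_cli_flags(args[-1])
  outdir <- opt$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(opt$seed)) as.integer(opt$seed) else NULL
  params <- if (!is.null(opt$config)) load_parameters(opt$config)
            else default_parameters()
  if (!is.null(opt$wtp)) params$settings$wtp <- as.numeric(opt$wtp)
  dwells <- if (!is.null(opt$dwell)) strsplit(opt$dwell, ",")[[1]]
            else c("6m", "12m", "full")
  n <- as.integer(opt$n %||% 10718)
  out <- function(name) file.path(outdir, name)

  switch(cmd,
    simulate = {
      ch <- generate_cohort(n = n, params = params,
                            seed = child_seed(seed, "simulate"))
      write_cohort(ch, out("cohort.csv"))
    },
    match = {
      ch <- read_cohort(opt$config %||%
                          stop_vad("match needs --config <cohort.csv>"))
      m <- match_cohort(ch, seed = child_seed(seed, "match"))
      write_cohort(m$matched, out("matched.csv"))
    },
    `fit-survival` = {
      ch <- read_cohort(opt$config %||%
                          stop_vad("fit-survival needs --config <cohort.csv>"))
      fits <- purrr::map(arm_names(), \(a) {
        sub <- ch[ch$device == a, ]
        purrr::map(c("exponential", "weibull", "lognormal", "gompertz"),
                   \(fam) {
          f <- fit_parametric(sub$survival_time, sub$event, fam)
          c(list(arm = a), glance(f))
        })
      }) |> purrr::flatten()
      jsonlite::write_json(fits, out("survival_fits.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    estimate = {
      ch <- read_cohort(opt$config %||%
                          stop_vad("estimate needs --config <cohort.csv>"))
      est <- estimate_parameters(ch)
      write_parameters(est, out("estimated_parameters.json"))
    },
    evaluate = {
      write_cea_outputs(base_case_analysis(params, dwells), out,
                        opt$format %||% "csv")
    },
    dsa = {
      readr::write_csv(one_way_dsa(params, c("IVAP", "CVC")),
                       out("tornado_IVAP_vs_CVC.csv"))
      readr::write_csv(one_way_dsa(params, c("IVAP", "PICC")),
                       out("tornado_IVAP_vs_PICC.csv"))
    },
    psa = {
      psa <- sample_psa(params, n = as.integer(opt$n %||% 1000),
                        seed = child_seed(seed, "psa"))
      readr::write_csv(psa$outcomes, out("psa_outcomes.csv"))
      readr::write_csv(ceac(psa), out("ceac.csv"))
      readr::write_csv(psa_scatter(psa), out("psa_scatter.csv"))
    },
    `base-case` = {
      write_cea_outputs(base_case_analysis(params, dwells), out, "csv")
      readr::write_csv(one_way_dsa(params, c("IVAP", "CVC")),
                       out("tornado_IVAP_vs_CVC.csv"))
      psa <- sample_psa(params, n = as.integer(opt$n %||% 1000),
                        seed = child_seed(seed, "psa"))
      readr::write_csv(ceac(psa), out("ceac.csv"))
    },
    stop_vad("unknown subcommand: '", cmd, "'")
  )
  manifest <- list(
    subcommand = cmd, seed = seed, options = opt,
    package_version = as.character(utils::packageVersion("vadcea")),
    r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(outdir)
}

write_cea_outputs <- function(cea, out, format) {
  if (identical(format, "json")) {
    jsonlite::write_json(list(summary = cea$summary,
                              comparisons = cea$comparisons,
                              recommended = cea$recommended),
                         out("cost_utility.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(cea$summary, out("cost_utility_summary.csv"))
    readr::write_csv(cea$comparisons, out("cost_utility_comparisons.csv"))
    readr::write_csv(cea$recommended, out("recommended.csv"))
  }
}

parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_vad("unexpected argument: '", a, "'")
    if (i + 1 > length(args)) stop_vad("flag ", a, " needs a value")
    opt[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opt
}
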