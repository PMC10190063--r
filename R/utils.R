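# internal helpers

# run `expr` under a fixed RNG state when seed is given, untouched otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# deterministic per-stage child seed from a master seed (kept < 2^31)
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, match = 23L, fit = 37L, estimate = 41L,
               evaluate = 53L, dsa = 61L, psa = 71L)
  off <- offsets[[stage]] %||% 97L
  (as.integer(seed) * 1009L + off) %% .Machine$integer.max
}

stop_vad <- function(..., class = "vadcea_error") {
  rlang::abort(paste0(...), class = class)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_vad(name, " must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_vad(name, " = ", format(x), " is outside [", lower, ", ", upper, "]")
  }
  invisible(x)
}

#' Convert a dwell-time specification to years
#'
#' Dwell times can be given as a number of years, as a month label such as
#' `"6m"`, or as `"full"` (the catheter's whole fitted lifetime, i.e. the
#' median survival time). One month counts as 30 days; the special case
#' `"12m"` counts as a full 365-day year so that six-month and twelve-month
#' scenarios correspond to 180 and 365 days respectively.
#'
#' @param dwell Numeric (years), `"full"`, or a string like `"6m"`.
#' @param days_per_month,days_per_year Day-count conventions (defaults 30
#'   and 365).
#' @return Dwell time in years (`Inf` for `"full"`).
#' @examples
#' parse_dwell("6m")   # 180/365
#' parse_dwell("12m")  # 1
#' parse_dwell("full") # Inf
#' @export
parse_dwell <- function(dwell, days_per_month = 30, days_per_year = 365) {
  if (is.numeric(dwell)) {
    if (length(dwell) != 1L || is.na(dwell) || dwell <= 0) {
      stop_vad("numeric dwell must be a single positive number of years")
    }
    return(dwell)
  }
  if (!is.character(dwell) || length(dwell) != 1L) {
    stop_vad("dwell must be a number of years, \"<n>m\", or \"full\"")
  }
  if (identical(dwell, "full")) return(Inf)
  m <- regmatches(dwell, regexec("^([0-9]+)m$", dwell))[[1]]
  if (length(m) != 2L) {
    stop_vad("unrecognised dwell specification: \"", dwell, "\"")
  }
  months <- as.numeric(m[2])
  if (months <= 0) stop_vad("dwell must be positive")
  days <- if (months %% 12 == 0) {
    (months / 12) * days_per_year
  } else {
    months * days_per_month
  }
  days / days_per_year
}

dwell_label <- function(dwell) {
  if (is.numeric(dwell) && is.infinite(dwell)) "full" else as.character(dwell)
}
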