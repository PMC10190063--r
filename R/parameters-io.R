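#' Read and write model-parameter configuration files
#'
#' The configuration is a flat `key -> {mean, sd, ci_low, ci_high,
#' distribution}` map using the parameter-table row labels as keys, together
#' with the per-arm complication-type counts, arm sizes and global settings.
#' Both JSON and YAML dialects are accepted; the dialect is inferred from
#' the file extension (`.json`, `.yaml`/`.yml`) or forced with `format`.
#' `load_parameters(write_parameters(p, path))` restores `p` exactly (up to
#' numeric text representation, better than 1e-9 relative).
#'
#' @param p A `vad_parameters` object.
#' @param path File path.
#' @param format `"json"`, `"yaml"` or `"auto"` (by extension).
#' @return `write_parameters()` returns `path` invisibly;
#'   `load_parameters()` returns a validated `vad_parameters` object.
#'   Files with missing keys raise a schema error naming the field; values
#'   outside a parameter's support (e.g. a negative cost or a utility above
#'   one) raise a validation error.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_parameters(default_parameters(), path)
#' p <- load_parameters(path)
#' @export
write_parameters <- function(p, path, format = c("auto", "json", "yaml")) {
  stopifnot(inherits(p, "vad_parameters"))
  format <- resolve_format(match.arg(format), path)
  keep <- c("mean", "sd", "ci_low", "ci_high", "distribution", "kind", "arm")
  par_map <- p$params |>
    select(dplyr::all_of(c("key", keep))) |>
    (\(d) setNames(
      purrr::pmap(d[keep], \(...) {
        row <- list(...)
        row[!vapply(row, \(v) is.na(v), logical(1))]
      }),
      d$key
    ))()
  mix_map <- p$mix |>
    group_by(.data$arm) |>
    summarise(m = list(setNames(as.list(.data$count), .data$type))) |>
    (\(d) setNames(d$m, d$arm))()
  obj <- list(
    parameters = par_map,
    complication_mix = mix_map,
    complication_cost_keys = setNames(as.list(p$mix$cost_key),
                                      paste(p$mix$arm, p$mix$type, sep = ".")),
    arm_n = as.list(p$arm_n),
    events = as.list(p$events),
    settings = p$settings
  )
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
load_parameters <- function(path, format = c("auto", "json", "yaml")) {
  if (!file.exists(path)) stop_vad("no such file: ", path)
  format <- resolve_format(match.arg(format), path)
  obj <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (section in c("parameters", "complication_mix", "arm_n", "events",
                    "settings")) {
    if (is.null(obj[[section]])) {
      stop_vad("config is missing the '", section, "' section",
               class = "vadcea_schema_error")
    }
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  params <- purrr::imap(obj$parameters, \(row, key) {
    if (is.null(row$mean)) {
      stop_vad("parameter '", key, "' is missing its mean",
               class = "vadcea_schema_error")
    }
    tibble::tibble(
      key = key, mean = as.numeric(row$mean), sd = num_or_na(row$sd),
      ci_low = num_or_na(row$ci_low), ci_high = num_or_na(row$ci_high),
      distribution = chr_or_na(row$distribution),
      kind = chr_or_na(row$kind), arm = chr_or_na(row$arm)
    )
  }) |> purrr::list_rbind()

  cost_keys <- obj$complication_cost_keys %||% list()
  mix <- purrr::imap(obj$complication_mix, \(types, arm_name) {
    ck <- vapply(names(types), \(ty) {
      cost_keys[[paste(arm_name, ty, sep = ".")]] %||%
        paste0("c_complication_", ty)
    }, character(1))
    tibble::tibble(
      arm = arm_name, type = names(types),
      count = as.integer(unlist(types)),
      cost_key = unname(ck)
    )
  }) |> purrr::list_rbind()

  new_vad_parameters(
    params = params, mix = mix,
    arm_n = unlist(obj$arm_n), events = unlist(obj$events),
    settings = obj$settings
  )
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = "json",
    yaml = ,
    yml = "yaml",
    stop_vad("cannot infer config dialect from extension '.", ext,
             "'; pass format = \"json\" or \"yaml\"")
  )
}
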