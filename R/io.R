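# configuration files and bit-stable writers

model_keys <- c("N", "prior", "alpha", "access_partial", "access_full",
                "p_with_numerals")
sim_keys <- c("n_participants", "n_target", "n_exposure", "cell_means",
              "sd_participant", "sd_item", "sd_resid",
              "comprehension_error_rate", "n_grid", "n_sims", "alpha_level",
              "n_boot")

parse_config_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "altrsa_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    json = function(p) jsonlite::fromJSON(p, simplifyVector = TRUE),
    yaml = yaml::read_yaml,
    yml = yaml::read_yaml,
    NULL
  )
  if (!is.null(reader)) {
    return(tryCatch(reader(path), error = function(e) {
      abort(sprintf("could not parse config '%s': %s", path, conditionMessage(e)),
            class = "altrsa_io_error")
    }))
  }
  # unknown extension: try JSON first, then YAML
  tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
           error = function(e) {
    tryCatch(yaml::read_yaml(path), error = function(e2) {
      abort(sprintf("could not parse config '%s' as JSON or YAML.", path),
            class = "altrsa_io_error")
    })
  })
}

#' Load and validate a configuration file
#'
#' Reads a JSON or YAML scenario or simulation configuration, rejects
#' unknown keys, fills documented defaults, and runs all invariant checks.
#' A *model* config describes a scenario for the pragmatic listener (keys
#' `N`, `prior`, `alpha`, `access_partial`, `access_full`,
#' `p_with_numerals`); a *simulation* config describes a synthetic
#' experiment (keys `n_participants`, `n_target`, `n_exposure`,
#' `cell_means`, `sd_participant`, `sd_item`, `sd_resid`,
#' `comprehension_error_rate`, plus the power-analysis keys `n_grid`,
#' `n_sims`, `alpha_level`, `n_boot`).
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file (other extensions are
#'   tried as JSON, then YAML).
#' @param type `"auto"` (classify by keys), `"model"` or `"simulation"`.
#' @return For a model config, an [rsa_config()]. For a simulation config, a
#'   list of class `altrsa_sim_config` with elements `spec`
#'   ([design_spec()]), `params` ([gen_params()]) and `power` (list of
#'   `n_grid`, `n_sims`, `alpha_level`, `n_boot`).
#' @examples
#' f <- tempfile(fileext = ".json")
#' jsonlite::write_json(list(N = 3, prior = "uniform", alpha = 3), f,
#'                      auto_unbox = TRUE)
#' load_config(f)
#' @export
load_config <- function(path, type = c("auto", "model", "simulation")) {
  type <- match.arg(type)
  raw <- parse_config_file(path)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    abort("config must be a mapping of named keys.", class = "altrsa_io_error")
  }
  # YAML 1.1 parses a bare `N` key as boolean FALSE; the only schema key that
  # resolves to FALSE is N itself, so map it back
  names(raw)[names(raw) == "FALSE" | names(raw) == "no"] <- "N"
  keys <- names(raw)
  if (type == "auto") {
    if (any(keys %in% model_keys) && !any(keys %in% sim_keys)) {
      type <- "model"
    } else if (any(keys %in% sim_keys) && !any(keys %in% model_keys)) {
      type <- "simulation"
    } else {
      abort("cannot classify config: keys match neither the model nor the simulation schema unambiguously; pass `type=`.",
            class = "altrsa_io_error")
    }
  }
  allowed <- if (type == "model") model_keys else sim_keys
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key '%s' for a %s config.", unknown[1], type),
          class = "altrsa_io_error")
  }
  if (type == "model") {
    N <- raw$N %||% 3
    rsa_config(
      N = N,
      prior = raw$prior %||% "uniform",
      alpha = raw$alpha %||% 1,
      access_partial = raw$access_partial %||% (N - 1),
      access_full = raw$access_full %||% N,
      p_with_numerals = raw$p_with_numerals %||% 0
    )
  } else {
    spec <- design_spec(
      n_participants = raw$n_participants %||% 240,
      n_target = raw$n_target %||% 8,
      n_exposure = raw$n_exposure %||% 24
    )
    defaults <- gen_params_exp2()
    cm <- raw$cell_means
    if (!is.null(cm)) cm <- unlist(cm)
    params <- gen_params(
      cell_means = cm %||% defaults$cell_means,
      sd_participant = raw$sd_participant %||% defaults$sd_participant,
      sd_item = raw$sd_item %||% defaults$sd_item,
      sd_resid = raw$sd_resid %||% defaults$sd_resid,
      comprehension_error_rate = raw$comprehension_error_rate %||% 0
    )
    structure(
      list(spec = spec, params = params,
           power = list(n_grid = raw$n_grid %||% c(100, 200, 350, 500),
                        n_sims = raw$n_sims %||% 500,
                        alpha_level = raw$alpha_level %||% 0.05,
                        n_boot = raw$n_boot %||% 1000)),
      class = "altrsa_sim_config"
    )
  }
}

prediction_cells <- function(x) {
  key <- function(k, a) {
    x$p_not_all[x$knowledgeability == k & x$alternatives == a]
  }
  list(
    partial_no_num = key("partial", "no_numerals"),
    partial_with_num = key("partial", "with_numerals"),
    full_no_num = key("full", "no_numerals"),
    full_with_num = key("full", "with_numerals")
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write results to disk
#'
#' CSV output has a fixed column order and `.` as the decimal separator
#' regardless of locale; JSON output keeps full double precision so values
#' round-trip through [jsonlite::fromJSON()] losslessly at 12+ significant
#' digits.
#'
#' @param x A result object: `rsa_prediction_table`, `rsa_fit`, `rsa_power`,
#'   an `rsa_sweep`, or a plain dataset tibble.
#' @param path Output file path; the format is inferred from the extension
#'   (`.json` or `.csv`) unless `format` is given.
#' @param format `NULL`, `"json"` or `"csv"`. Tables of trial records and
#'   sweeps are CSV-only; fits are JSON-only.
#' @return The path, invisibly.
#' @export
write_outputs <- function(x, path, format = NULL) {
  UseMethod("write_outputs")
}

infer_format <- function(path, format, allowed) {
  fmt <- format %||% tolower(tools::file_ext(path))
  if (!fmt %in% allowed) {
    abort(sprintf("cannot write this object to '%s': supported format(s): %s.",
                  path, paste(allowed, collapse = ", ")),
          class = "altrsa_io_error")
  }
  fmt
}

#' @export
write_outputs.rsa_prediction_table <- function(x, path, format = NULL) {
  fmt <- infer_format(path, format, c("json", "csv"))
  if (fmt == "json") {
    cells <- prediction_cells(x)
    payload <- list(
      config = config_as_list(attr(x, "config")),
      cells = cells,
      percent_rounded = lapply(cells, function(p) round(100 * p))
    )
    write_json_file(payload, path)
  } else {
    df <- tibble(condition = x$knowledgeability, alternatives = x$alternatives,
                 p_not_all = x$p_not_all, percent = x$percent)
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @export
write_outputs.rsa_fit <- function(x, path, format = NULL) {
  infer_format(path, format, "json")
  write_json_file(
    list(estimates = x$estimates, n_participants = x$n_participants,
         n_boot = x$n_boot, conf_level = x$conf_level,
         missing_cells = x$missing_cells,
         estimator = "participant-cell-mean contrasts with participant-level bootstrap (not a mixed-effects fit)"),
    path
  )
}

#' @export
write_outputs.rsa_power <- function(x, path, format = NULL) {
  fmt <- infer_format(path, format, c("json", "csv"))
  df <- tibble(n = x$n_participants, power = x$power, mc_se = x$mc_se)
  if (fmt == "json") {
    write_json_file(list(alpha_level = x$alpha_level[1], n_sims = x$n_sims[1],
                         curve = df), path)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @export
write_outputs.data.frame <- function(x, path, format = NULL) {
  infer_format(path, format, "csv")
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run records what produced its outputs: the command,
#' a config snapshot, the seed(s), the package version, a UTC timestamp and
#' the output paths.
#'
#' @param path Manifest path (JSON).
#' @param command Command name.
#' @param config Config snapshot (list, or an `rsa_config`).
#' @param seed Seed(s) used, or `NULL`.
#' @param outputs Character vector of output paths.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  if (inherits(config, "rsa_config")) config <- config_as_list(config)
  write_json_file(
    list(command = command, config = config, seed = seed,
         package_version = as.character(packageVersion("altrsa")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         outputs = as.list(outputs)),
    path
  )
}
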