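# Plain-text serialization. Trajectories and curves go to TSV (no
# community standard exists for ODE trajectories at this scale; SBML
# export is out of scope); configs round-trip through YAML or JSON; run
# manifests and fit results are JSON.

fmt9 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.9g", x))
}

#' Write a trajectory to TSV
#'
#' Writes the output grid as tab-separated values with the column order
#' `time s chi I1 I2 It Im Ip`, numbers at 9 significant digits, and the
#' located switching events appended as commented footer lines
#' (`# event <name> <time>`).
#'
#' @param trajectory An `ime_trajectory` from [simulate_circuit()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ime_trajectory"))
  cols <- c("time", "s", "chi", "I1", "I2", "It", "Im", "Ip")
  body <- vapply(seq_len(nrow(trajectory)), function(i) {
    paste(fmt9(unlist(trajectory[i, cols])), collapse = "\t")
  }, "")
  ev <- circuit_events(trajectory)
  footer <- if (nrow(ev)) {
    sprintf("# event %s %s", ev$name, fmt9(ev$time))
  } else character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body, footer), con)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return An `ime_trajectory` (without a parameter snapshot; the events
#'   footer is restored into the `events` attribute).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  ev_lines <- grep("^# event ", lines, value = TRUE)
  data_lines <- lines[!startsWith(lines, "#")]
  tbl <- utils::read.delim(text = paste(data_lines, collapse = "\n"),
                           sep = "\t", check.names = FALSE)
  ev <- if (length(ev_lines)) {
    parts <- strsplit(sub("^# event ", "", ev_lines), " ")
    tibble::tibble(name = vapply(parts, `[`, "", 1),
                   time = as.numeric(vapply(parts, `[`, "", 2)))
  } else {
    tibble::tibble(name = character(), time = numeric())
  }
  new_trajectory(tibble::as_tibble(tbl), ev, params = NULL, mode = NULL)
}

config_error <- function(msg, path = NULL) {
  stop(structure(class = c("ime_config_error", "error", "condition"),
                 list(message = if (is.null(path)) msg
                      else paste0(msg, " (at: ", path, ")"),
                      call = NULL)))
}

allowed_top <- c("parameters", "mode", "scenario", "options", "seed",
                 "output")
allowed_scenarios <- c("simulate", "dose", "synth-timecourse",
                       "synth-cells", "fit", "recover")

#' Read and validate a run configuration
#'
#' Configs are YAML (`.yml`/`.yaml`) or JSON (`.json`). Recognized keys:
#' `parameters` (any of k1, k2, k3, k4, k5, k6, A, r, s_schedule — missing
#' entries take the published defaults), `mode`, `scenario`, `options`
#' (scenario-specific), `seed`, `output`. Unknown keys are rejected with
#' the offending key path; invalid parameter values are rejected by
#' [circuit_params()] validation.
#'
#' @param path Config file path.
#' @return A list of class `ime_config` with elements `params`
#'   ([circuit_params()]), `mode`, `scenario`, `options`, `seed`, `output`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("config not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(raw)
}

as_run_config <- function(raw) {
  if (!is.list(raw)) config_error("config must be a mapping")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown)) {
    config_error("unknown config keys", paste(unknown, collapse = ", "))
  }
  par_raw <- raw$parameters %||% list()
  par_ok <- c("k1", "k2", "k3", "k4", "k5", "k6", "A", "r", "s_schedule")
  unknown_p <- setdiff(names(par_raw), par_ok)
  if (length(unknown_p)) {
    config_error("unknown parameter keys",
                 paste0("parameters.", unknown_p, collapse = ", "))
  }
  if (!is.null(par_raw$s_schedule)) {
    par_raw$s_schedule <- tibble::as_tibble(par_raw$s_schedule)
  }
  params <- tryCatch(do.call(circuit_params, par_raw),
                     error = function(e) {
                       config_error(conditionMessage(e), "parameters")
                     })
  mode <- tryCatch(irt2_mode(raw$mode %||% "wildtype"),
                   error = function(e) config_error("invalid mode", "mode"))
  scenario <- raw$scenario %||% "simulate"
  if (!scenario %in% allowed_scenarios) {
    config_error(paste0("unknown scenario '", scenario, "'"), "scenario")
  }
  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1) {
    config_error("seed must be a single integer", "seed")
  }
  structure(list(params = params, mode = mode, scenario = scenario,
                 options = raw$options %||% list(),
                 seed = as.integer(seed), output = raw$output),
            class = "ime_config")
}

#' Write a run configuration
#'
#' Round-trips losslessly through [read_config()].
#'
#' @param config An `ime_config` (or a plain list with the same keys).
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params
  raw <- list(
    parameters = list(k1 = p$k1, k2 = p$k2, k3 = p$k3, k4 = p$k4,
                      k5 = p$k5, k6 = p$k6, A = p$A, r = p$r,
                      s_schedule = list(time = p$s_schedule$time,
                                        level = p$s_schedule$level)),
    mode = config$mode, scenario = config$scenario,
    options = config$options, seed = config$seed, output = config$output
  )
  raw <- raw[!vapply(raw, is.null, TRUE)]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records the parameters, mode, scenario, seed, package and R versions
#' and a timestamp next to a run's outputs, so any published command can
#' be re-run to identical outputs.
#'
#' @param config An `ime_config`.
#' @param path Output JSON path.
#' @param outputs Character vector of files the run wrote.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, outputs = character()) {
  p <- config$params
  manifest <- list(
    package = "imeswitch",
    version = as.character(utils::packageVersion("imeswitch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scenario = config$scenario, mode = config$mode, seed = config$seed,
    parameters = list(k1 = p$k1, k2 = p$k2, k3 = p$k3, k4 = p$k4,
                      k5 = p$k5, k6 = p$k6, A = p$A, r = p$r),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
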