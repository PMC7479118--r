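# Configuration, tabular IO and run manifests. All files are plain text:
# TSV with '#' comment headers for data, JSON for configuration.

#' Published stability-table inputs
#'
#' The packaged table of published equilibrium measurements for the
#' alpha-actinin SR4 and titin I27 tandem-domain constructs: force,
#' temperature, single-domain unfolded probability p (bootstrap error) and
#' conformational free energy (force-calibration error). These are the
#' inputs from which [stability_table()] recomputes the free energies and
#' critical forces.
#'
#' @return `data.frame` with columns `domain`, `force_pN`, `force_se`,
#'   `temperature_C`, `p`, `p_se`, `dphi_kBT`, `dphi_se`, and the
#'   published reference values `dG_ref`, `dG0_ref`, `Fc_ref` for
#'   comparison.
#' @export
stability_inputs <- function() {
  path <- system.file("extdata", "stability_inputs.tsv",
                      package = "tethermech", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write a trajectory as TSV with a comment header
#'
#' The header records the seed, environment and acquisition settings, so
#' the file is traceable to its generating configuration; the event log is
#' written alongside as `<path>.events.tsv`.
#'
#' @param trajectory An `"mt_trajectory"`.
#' @param path Output file path.
#' @param write_events Also write the ground-truth event log.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, write_events = TRUE) {
  config <- attr(trajectory, "config")
  hdr <- c(
    sprintf("# seed: %s", attr(trajectory, "seed")),
    if (!is.null(config)) c(
      sprintf("# temperature_C: %s", config$env$temperature),
      sprintf("# sampling_rate_Hz: %s", config$sampling_rate),
      sprintf("# noise_sd_nm: %s", config$noise_sd),
      sprintf("# noise_model: %s", config$noise_model),
      sprintf("# smoothing_window: %s", config$smoothing_window)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(trajectory), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ev <- attr(trajectory, "events")
  if (write_events && !is.null(ev))
    write.table(ev, paste0(path, ".events.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return An `"mt_trajectory"` data frame; header key-values are attached
#'   as the `"header"` attribute, and the event log is re-read when the
#'   side file exists.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 50)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    hdr[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  out <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(out, "header") <- hdr
  evp <- paste0(path, ".events.tsv")
  if (file.exists(evp))
    attr(out, "events") <- read.table(evp, header = TRUE, sep = "\t")
  class(out) <- c("mt_trajectory", "data.frame")
  out
}

#' Write a flat key-value report
#'
#' Fit results and diagnostics as two-column TSV (`key`, `value`) or JSON.
#'
#' @param values Named list of scalars.
#' @param path Output path; the extension picks the format (`.json` or
#'   TSV otherwise).
#' @return `path`, invisibly.
#' @export
write_report <- function(values, path) {
  stopifnot(length(names(values)) == length(values))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    df <- data.frame(key = names(values),
                     value = vapply(values, function(v)
                       as.character(v), character(1)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# -- configuration ----------------------------------------------------------

.config_schema <- list(
  temperature_C = list(type = "numeric", check = function(x) x > -273.15,
                       default = 23),
  sampling_rate = list(type = "numeric", check = function(x) x > 0,
                       default = 50),
  noise_sd = list(type = "numeric", check = function(x) x >= 0, default = 6),
  noise_model = list(type = "character",
                     check = function(x) x %in% c("white", "ou"),
                     default = "white"),
  ou_tau = list(type = "numeric", check = function(x) x > 0, default = 0.05),
  smoothing_window = list(type = "numeric", check = function(x) x >= 1,
                          default = 20),
  seed = list(type = "numeric", check = function(x) x == round(x),
              default = 1),
  handle = list(type = "list", default = NULL),
  units = list(type = "list", default = NULL)
)

.unit_schema <- list(
  label = list(type = "character"),
  n_residues = list(type = "numeric", check = function(x) x >= 0),
  contour_per_residue = list(type = "numeric", check = function(x) x > 0,
                             default = 0.38),
  persistence_length = list(type = "numeric", check = function(x) x > 0,
                            default = 0.8),
  rod_length = list(type = "numeric", check = function(x) x >= 0),
  k0_unfold = list(type = "numeric", check = function(x) x > 0),
  dx_unfold = list(type = "numeric"),
  k0_refold = list(type = "numeric", check = function(x) x > 0,
                   default = NULL),
  dx_refold = list(type = "numeric", default = NULL),
  state0 = list(type = "character",
                check = function(x) x %in% c("folded", "unfolded"),
                default = "folded")
)

.validate_block <- function(block, schema, where, errors) {
  unknown <- setdiff(names(block), names(schema))
  for (u in unknown)
    errors <- c(errors, sprintf("%s: unknown key '%s'", where, u))
  for (key in names(schema)) {
    spec <- schema[[key]]
    if (!key %in% names(block)) {
      if (!"default" %in% names(spec))
        errors <- c(errors, sprintf("%s: missing required key '%s'",
                                    where, key))
      next
    }
    val <- block[[key]]
    if (is.null(val)) next
    okt <- switch(spec$type,
                  numeric = is.numeric(val),
                  character = is.character(val),
                  list = is.list(val))
    if (!okt) {
      errors <- c(errors, sprintf("%s.%s: expected %s", where, key,
                                  spec$type))
      next
    }
    if (!is.null(spec$check) && spec$type != "list" &&
        !all(spec$check(val)))
      errors <- c(errors, sprintf("%s.%s: invalid value %s", where, key,
                                  paste(val, collapse = ", ")))
  }
  errors
}

#' Load and validate a simulation configuration file
#'
#' Reads a JSON-syntax configuration describing the environment,
#' acquisition settings and construct units, validates it against the
#' schema (unknown keys and out-of-range values are itemised in the
#' error), fills defaults, and builds a [sim_config()].
#'
#' @param path Path to the JSON configuration.
#' @return A [sim_config()] with the source list in `attr(, "raw")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  errors <- .validate_block(raw, .config_schema, "config", character(0))
  if (is.null(raw$units) || !length(raw$units))
    errors <- c(errors, "config: at least one unit is required")
  else
    for (i in seq_along(raw$units))
      errors <- c(errors,
                  .validate_block(raw$units[[i]], .unit_schema,
                                  sprintf("units[%d]", i), character(0)))
  if (!is.null(raw$handle))
    errors <- c(errors, .validate_block(
      raw$handle,
      list(n_bp = list(type = "numeric", check = function(x) x > 0,
                       default = 572),
           persistence_length = list(type = "numeric",
                                     check = function(x) x > 0,
                                     default = 45),
           stretch_modulus = list(type = "numeric",
                                  check = function(x) x > 0,
                                  default = 1200),
           rise_per_bp = list(type = "numeric", check = function(x) x > 0,
                              default = 0.338)),
      "handle", character(0)))
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  get_or <- function(block, key, default)
    if (key %in% names(block) && !is.null(block[[key]])) block[[key]]
    else default
  units <- lapply(raw$units, function(u) {
    refold <- if (!is.null(get_or(u, "k0_refold", NULL)))
      rate_params(u$k0_refold, get_or(u, "dx_refold", 0))
    two_state_unit(
      label = u$label,
      folded = folded_domain_params(u$rod_length),
      unfolded = peptide_params(u$n_residues,
                                get_or(u, "contour_per_residue", 0.38),
                                get_or(u, "persistence_length", 0.8)),
      unfold = rate_params(u$k0_unfold, u$dx_unfold),
      refold = refold,
      state0 = get_or(u, "state0", "folded"))
  })
  handle <- if (is.null(raw$handle)) handle_params() else
    handle_params(get_or(raw$handle, "n_bp", 572),
                  get_or(raw$handle, "persistence_length", 45),
                  get_or(raw$handle, "stretch_modulus", 1200),
                  get_or(raw$handle, "rise_per_bp", 0.338))
  cfg <- sim_config(
    units = units, handle = handle,
    env = env_at(get_or(raw, "temperature_C", 23)),
    sampling_rate = get_or(raw, "sampling_rate", 50),
    noise_sd = get_or(raw, "noise_sd", 6),
    noise_model = get_or(raw, "noise_model", "white"),
    ou_tau = get_or(raw, "ou_tau", 0.05),
    smoothing_window = get_or(raw, "smoothing_window", 20),
    seed = as.integer(get_or(raw, "seed", 1)))
  attr(cfg, "raw") <- raw
  cfg
}

#' Write a simulation configuration as JSON
#'
#' Serialises a [sim_config()] to the JSON schema read by
#' [load_config()]; a write/read round trip reproduces the configuration.
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  units <- lapply(config$units, function(u) {
    out <- list(label = u$label,
                n_residues = u$unfolded$n_residues,
                contour_per_residue = u$unfolded$contour_per_residue,
                persistence_length = u$unfolded$persistence_length,
                rod_length = u$folded$rod_length,
                k0_unfold = u$unfold$k0,
                dx_unfold = u$unfold$delta_x,
                state0 = u$state0)
    if (!is.null(u$refold)) {
      out$k0_refold <- u$refold$k0
      out$dx_refold <- u$refold$delta_x
    }
    out
  })
  raw <- list(temperature_C = config$env$temperature,
              sampling_rate = config$sampling_rate,
              noise_sd = config$noise_sd,
              noise_model = config$noise_model,
              ou_tau = config$ou_tau,
              smoothing_window = config$smoothing_window,
              seed = config$seed,
              handle = config$handle[c("n_bp", "persistence_length",
                                       "stretch_modulus", "rise_per_bp")],
              units = units)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run manifest
#'
#' A traceability record for a scripted run: command, seed, config digest
#' (md5 of the config file when given), input/output paths, timestamp and
#' package version.
#'
#' @param command Short command name.
#' @param seed Integer seed used for the run.
#' @param config_path Optional path of the configuration file.
#' @param inputs,outputs Character vectors of file paths.
#' @param path Optional JSON path to write the manifest to.
#' @return The manifest as a named list (class `"run_manifest"`).
#' @export
run_manifest <- function(command, seed, config_path = NULL,
                         inputs = character(0), outputs = character(0),
                         path = NULL) {
  digest <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else NA_character_
  man <- structure(list(
    command = command,
    seed = seed,
    config = config_path,
    config_md5 = digest,
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("tethermech"))),
    class = "run_manifest")
  if (!is.null(path))
    jsonlite::write_json(unclass(man), path, auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(man)
}
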