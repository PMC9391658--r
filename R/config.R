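# Config keys accepted in scenario files, beyond the parameter fields.
.config_keys <- c("engine", "model", "dt", "seed", "boxcar", "outputs")
.param_keys <- c("kappa0", "P_kappa", "sigma_kappa", "beta", "rho_IR",
                 "rho_RS", "rho_VS", "rho_ID", "rho_treat", "T_max",
                 "rho_TR", "rho_TD", "v", "t_V_on", "V_max", "N0", "t_fnl",
                 "contact_mode", "treatment_mode", "vaccS_mode", "vaccR_mode")

#' Scenario configuration
#'
#' A serializable bundle of model parameters, engine choice, model
#' variant, step size, seed and optional boxcar expansion -- everything
#' needed to reproduce one run.
#'
#' @param params An [epi_params()].
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param model `"sirs"` (no D/T/V flows), `"sirs+d"` (adds
#'   disease-induced death) or `"sirs+dtv"` (full model).
#' @param dt Integration step (deterministic engine only); defaults to
#'   0.1 day for that engine.
#' @param seed RNG seed in `[0, 2^64 - 1]` (stochastic engine only).
#' @param boxcar `NULL`, a [boxcar_spec()] or list of them.
#' @param outputs Optional list with `variables` (columns to export) and
#'   `dir` (export directory).
#' @return A validated `scenario_config` object.
#' @examples
#' cfg <- scenario_config(epi_params(contact_mode = "constant"),
#'                        engine = "deterministic", model = "sirs")
#' @export
scenario_config <- function(params = epi_params(),
                            engine = c("deterministic", "stochastic"),
                            model = c("sirs+dtv", "sirs+d", "sirs"),
                            dt = NULL, seed = NULL, boxcar = NULL,
                            outputs = NULL) {
  cfg <- structure(list(params = params,
                        engine = match.arg(engine),
                        model = match.arg(model),
                        dt = dt, seed = seed, boxcar = boxcar,
                        outputs = outputs),
                   class = "scenario_config")
  validate_config(cfg)
}

#' Validate a scenario configuration
#'
#' Enforces all parameter invariants plus the engine/model consistency
#' rules: `dt` is present only for the deterministic engine (filled with
#' 0.1 when omitted), `seed` only for the stochastic engine and within
#' `[0, 2^64 - 1]`, and a model variant may not carry flows it excludes
#' (`sirs` has no death, treatment or vaccination; `sirs+d` no treatment
#' or vaccination).
#'
#' @param config A `scenario_config`.
#' @return The validated (possibly default-filled) configuration.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  validate_params(config$params)
  p <- config$params
  if (config$engine == "deterministic") {
    if (is.null(config$dt)) config$dt <- 0.1
    if (!is.numeric(config$dt) || config$dt <= 0 || config$dt > 1)
      stop("config error: dt must satisfy 0 < dt <= 1", call. = FALSE)
    if (!is.null(config$seed))
      stop("config error: seed applies only to the stochastic engine",
           call. = FALSE)
  } else {
    if (!is.null(config$dt))
      stop("config error: dt applies only to the deterministic engine",
           call. = FALSE)
    if (!is.null(config$seed)) normalize_seed(config$seed)
  }
  if (config$model == "sirs" &&
      (p$rho_ID > 0 || p$rho_treat > 0 || p$v > 0))
    stop("config error: model 'sirs' excludes rho_ID, rho_treat and v",
         call. = FALSE)
  if (config$model == "sirs+d" && (p$rho_treat > 0 || p$v > 0))
    stop("config error: model 'sirs+d' excludes rho_treat and v",
         call. = FALSE)
  if (!is.null(config$boxcar)) boxcar_K(config$boxcar)
  config
}

#' Load a scenario configuration from a JSON or YAML file
#'
#' The file holds flat keys: any [epi_params()] field (e.g. `kappa0`,
#' `rho_IR`), plus `engine`, `model`, `dt`, `seed`, `boxcar` (a list of
#' `{class, K}` entries) and `outputs`. Missing parameters take the
#' package defaults; unknown keys are rejected with the offending name.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config error: unsupported file type '.", ext, "'",
                     call. = FALSE))
  config_from_list(raw)
}

# Build a scenario_config from a flat named list (file contents or CLI).
config_from_list <- function(raw) {
  unknown <- setdiff(names(raw), c(.config_keys, .param_keys))
  if (length(unknown) > 0)
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pk <- raw[intersect(names(raw), .param_keys)]
  params <- do.call(epi_params, pk)
  boxcar <- NULL
  if (!is.null(raw$boxcar)) {
    bx <- raw$boxcar
    if (is.data.frame(bx)) bx <- split(bx, seq_len(nrow(bx)))
    boxcar <- lapply(bx, function(b) boxcar_spec(b$class, b$K))
  }
  scenario_config(params = params,
                  engine = if (is.null(raw$engine)) "deterministic" else raw$engine,
                  model = if (is.null(raw$model)) "sirs+dtv" else raw$model,
                  dt = raw$dt, seed = raw$seed, boxcar = boxcar,
                  outputs = raw$outputs)
}

#' Run a scenario configuration
#'
#' Dispatches to the deterministic or stochastic engine.
#'
#' @param config A `scenario_config`.
#' @return An `epi_trajectory`.
#' @export
run_scenario <- function(config) {
  config <- validate_config(config)
  if (config$engine == "deterministic") {
    simulate_deterministic(config$params, dt = config$dt,
                           boxcar = config$boxcar)
  } else {
    simulate_stochastic(config$params, seed = config$seed,
                        boxcar = config$boxcar)
  }
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario: %s engine, model %s", x$engine, x$model))
  if (!is.null(x$dt)) cat(sprintf(", dt = %g", x$dt))
  if (!is.null(x$seed)) cat(sprintf(", seed = %s", format(x$seed)))
  cat("\n")
  print(x$params)
  invisible(x)
}
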