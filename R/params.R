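#' Epidemic model parameters
#'
#' Bundles every rate, capacity and mode selector of the SIRS+DTV model
#' family into a validated parameter object shared by the deterministic and
#' stochastic engines. All rates are per capita per day. Defaults follow the
#' illustrative parameterization of a directly transmitted respiratory
#' pathogen: transmission parameter `beta = 0.3`, a 4-day infectious period
#' (`rho_IR = 0.25`), switch abruptness `sigma_kappa = 4`, and an infinite
#' behavioral switching point (`P_kappa = Inf`, i.e. no behavioral response).
#'
#' @param kappa0 Baseline per-capita contact rate (contacts/day).
#' @param P_kappa Prevalence switching point of the adaptive contact
#'   function; the prevalence `I/N` at which the contact rate has dropped to
#'   `kappa0/2`. `Inf` disables the behavioral response.
#' @param sigma_kappa Switch abruptness exponent (dimensionless, >= 0).
#'   Around 2 gives gradual switching, 5 fairly abrupt, 20 approximates a
#'   step at `P_kappa`.
#' @param beta Force of infection per contact (dimensionless).
#' @param rho_IR Recovery rate I -> R (/day); `1/rho_IR` is the mean
#'   infectious period.
#' @param rho_RS Immunity waning rate R -> S (/day).
#' @param rho_VS Vaccine-immunity waning rate V -> S (/day). Defaults to
#'   `rho_RS` (the two waning processes are assumed equal unless set apart).
#' @param rho_ID Disease-induced death rate in I (/day), aka virulence.
#' @param rho_treat Baseline treatment entry rate I -> T (/day).
#' @param T_max Treatment capacity: the number of individuals that can be
#'   under treatment at any one time before new admissions stop.
#' @param rho_TR Treatment discharge rate T -> R (/day).
#' @param rho_TD Death rate under treatment T -> D (/day).
#' @param v Vaccination rate (/day) applied to S (and R) while the rollout
#'   is active.
#' @param t_V_on Vaccination rollout start day.
#' @param V_max Total number of vaccination regimens available.
#' @param N0 Initial population size (individuals, integer >= 2).
#' @param t_fnl Simulation horizon (days).
#' @param contact_mode,treatment_mode,vaccS_mode,vaccR_mode Mode selectors
#'   in `"default"`, `"constant"` or `"custom"`, mirroring the model's
#'   runtime-alterable processes. `"default"` is the gated/adaptive form,
#'   `"constant"` the ungated constant rate, `"custom"` delegates to the
#'   matching `*_fn` function.
#' @param contact_fn For `contact_mode = "custom"`: `function(prevalence,
#'   params)` returning a contact rate (contacts/day).
#' @param treatment_fn,vaccS_fn,vaccR_fn For the corresponding `"custom"`
#'   modes: `function(state, params)` returning a per-day rate.
#'
#' @return An object of class `"epi_params"` (a named list).
#' @seealso [epi_state()], [simulate_deterministic()], [simulate_stochastic()]
#' @examples
#' p <- epi_params(kappa0 = 2, contact_mode = "constant", rho_ID = 0.005)
#' basic_reproduction_number(p)
#' @export
epi_params <- function(kappa0 = 2,
                       P_kappa = Inf,
                       sigma_kappa = 4,
                       beta = 0.3,
                       rho_IR = 0.25,
                       rho_RS = 0,
                       rho_VS = rho_RS,
                       rho_ID = 0,
                       rho_treat = 0,
                       T_max = 10000,
                       rho_TR = 0.1,
                       rho_TD = 0,
                       v = 0,
                       t_V_on = 0,
                       V_max = 1e5,
                       N0 = 1e5,
                       t_fnl = 100,
                       contact_mode = c("default", "constant", "custom"),
                       treatment_mode = c("default", "constant", "custom"),
                       vaccS_mode = c("default", "constant", "custom"),
                       vaccR_mode = c("default", "constant", "custom"),
                       contact_fn = NULL,
                       treatment_fn = NULL,
                       vaccS_fn = NULL,
                       vaccR_fn = NULL) {
  p <- list(
    kappa0 = kappa0, P_kappa = P_kappa, sigma_kappa = sigma_kappa,
    beta = beta, rho_IR = rho_IR, rho_RS = rho_RS, rho_VS = rho_VS,
    rho_ID = rho_ID, rho_treat = rho_treat, T_max = T_max,
    rho_TR = rho_TR, rho_TD = rho_TD, v = v, t_V_on = t_V_on,
    V_max = V_max, N0 = N0, t_fnl = t_fnl,
    contact_mode = match.arg(contact_mode),
    treatment_mode = match.arg(treatment_mode),
    vaccS_mode = match.arg(vaccS_mode),
    vaccR_mode = match.arg(vaccR_mode),
    contact_fn = contact_fn, treatment_fn = treatment_fn,
    vaccS_fn = vaccS_fn, vaccR_fn = vaccR_fn
  )
  class(p) <- "epi_params"
  validate_params(p)
}

#' Validate an epidemic parameter object
#'
#' Checks every invariant of the parameterization (non-negative rates,
#' positive switching point, integer population of at least 2, horizon and
#' vaccination-onset consistency, custom functions supplied where a mode
#' requires one) and returns the object invisibly unchanged.
#'
#' @param params An [epi_params()] object.
#' @return `params`, invisibly coerced to valid (an error is thrown on any
#'   violation; the object is never silently altered).
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "epi_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  rates <- c("kappa0", "beta", "rho_IR", "rho_RS", "rho_VS", "rho_ID",
             "rho_treat", "rho_TR", "rho_TD", "v")
  for (nm in rates) {
    if (!num1(params[[nm]]) || params[[nm]] < 0) {
      stop(sprintf("invalid parameter '%s': must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (!num1(params$P_kappa) || params$P_kappa <= 0)
    stop("invalid parameter 'P_kappa': must be > 0 (use Inf to disable behavior)",
         call. = FALSE)
  if (!num1(params$sigma_kappa) || params$sigma_kappa < 0)
    stop("invalid parameter 'sigma_kappa': must be >= 0", call. = FALSE)
  if (!num1(params$N0) || params$N0 < 2 || params$N0 != round(params$N0))
    stop("invalid parameter 'N0': must be an integer >= 2", call. = FALSE)
  if (!num1(params$T_max) || params$T_max < 0)
    stop("invalid parameter 'T_max': must be >= 0", call. = FALSE)
  if (!num1(params$V_max) || params$V_max < 0)
    stop("invalid parameter 'V_max': must be >= 0", call. = FALSE)
  if (!num1(params$t_fnl) || params$t_fnl <= 0)
    stop("invalid parameter 't_fnl': must be > 0", call. = FALSE)
  if (!num1(params$t_V_on) || params$t_V_on < 0 || params$t_V_on > params$t_fnl)
    stop("invalid parameter 't_V_on': must satisfy 0 <= t_V_on <= t_fnl",
         call. = FALSE)
  needs_fn <- c(contact_mode = "contact_fn", treatment_mode = "treatment_fn",
                vaccS_mode = "vaccS_fn", vaccR_mode = "vaccR_fn")
  for (mode in names(needs_fn)) {
    if (identical(params[[mode]], "custom") &&
        !is.function(params[[needs_fn[[mode]]]])) {
      stop(sprintf("mode '%s' is \"custom\" but '%s' is not a function",
                   mode, needs_fn[[mode]]), call. = FALSE)
    }
  }
  invisible(params)
}

#' @export
print.epi_params <- function(x, ...) {
  cat("SIRS+DTV parameters\n")
  cat(sprintf("  transmission : kappa0 = %g /day, beta = %g, contact mode = %s\n",
              x$kappa0, x$beta, x$contact_mode))
  if (is.finite(x$P_kappa)) {
    cat(sprintf("  behavior     : P_kappa = %g, sigma_kappa = %g\n",
                x$P_kappa, x$sigma_kappa))
  }
  cat(sprintf("  progression  : rho_IR = %g, rho_RS = %g, rho_ID = %g /day\n",
              x$rho_IR, x$rho_RS, x$rho_ID))
  if (x$rho_treat > 0 || x$treatment_mode != "default") {
    cat(sprintf("  treatment    : rho_treat = %g, T_max = %g, rho_TR = %g, rho_TD = %g (mode %s)\n",
                x$rho_treat, x$T_max, x$rho_TR, x$rho_TD, x$treatment_mode))
  }
  if (x$v > 0) {
    cat(sprintf("  vaccination  : v = %g /day from day %g, V_max = %g, rho_VS = %g\n",
                x$v, x$t_V_on, x$V_max, x$rho_VS))
  }
  cat(sprintf("  population   : N0 = %g, horizon = %g days\n", x$N0, x$t_fnl))
  r0 <- tryCatch(basic_reproduction_number(x), error = function(e) NA_real_)
  if (!is.na(r0)) cat(sprintf("  R0           : %.4g\n", r0))
  invisible(x)
}

# replace selected fields, revalidating
modify_params <- function(params, ...) {
  changes <- list(...)
  for (nm in names(changes)) {
    if (!nm %in% names(params)) {
      stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
    }
    params[[nm]] <- changes[[nm]]
  }
  validate_params(params)
  params
}
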