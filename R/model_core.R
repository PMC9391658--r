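#' Convert a constant per-day rate to a per-interval probability
#'
#' The exponential waiting-time transform `p = 1 - exp(-rho * delta_t)`:
#' the probability that an individual subject to a constant hazard `rho`
#' leaves its class during an interval of length `delta_t`.
#'
#' @param rho Per-day rate (>= 0). Vectorized.
#' @param delta_t Interval length in days (> 0).
#' @return Probability in `[0, 1)`; 0 exactly when `rho = 0`.
#' @examples
#' rate_to_probability(0.25, 1)  # 1 - exp(-0.25)
#' @export
rate_to_probability <- function(rho, delta_t = 1) {
  if (any(!is.finite(delta_t)) || any(delta_t <= 0))
    stop("invalid parameter: delta_t must be > 0", call. = FALSE)
  if (any(is.na(rho)) || any(rho < 0))
    stop("invalid parameter: rates must be >= 0", call. = FALSE)
  -expm1(-rho * delta_t)
}

#' Competing-risk rate-to-probability transform
#'
#' For a class with several simultaneous exit routes at rates `rhos`, the
#' probability of leaving by route i during an interval `delta_t` is
#' `p_i = (rho_i / sum(rhos)) * (1 - exp(-sum(rhos) * delta_t))`. The
#' probabilities sum to `1 - exp(-sum(rhos) * delta_t) < 1`; the residual
#' is the stay-put probability used by the multinomial sampler. Output
#' ratios equal the input rate ratios, and a single-rate input reduces
#' exactly to [rate_to_probability()].
#'
#' @param rhos Numeric vector of per-day exit rates (all >= 0).
#' @param delta_t Interval length in days (> 0).
#' @return Vector of probabilities, same length and names as `rhos`.
#' @examples
#' competing_rates_to_probabilities(c(0.25, 0.005), 1)
#' @export
competing_rates_to_probabilities <- function(rhos, delta_t = 1) {
  if (!is.finite(delta_t) || delta_t <= 0)
    stop("invalid parameter: delta_t must be > 0", call. = FALSE)
  if (length(rhos) == 0) return(numeric(0))
  if (any(is.na(rhos)) || any(rhos < 0))
    stop("invalid parameter: rates must be >= 0", call. = FALSE)
  total <- sum(rhos)
  if (total == 0) return(rhos * 0)
  rhos / total * -expm1(-total * delta_t)
}

#' Instantaneous contact rate kappa(t)
#'
#' In the default (adaptive) mode the per-capita contact rate declines with
#' prevalence `I/N` around a switching point `P_kappa`:
#' `kappa = kappa0 / (1 + ((I/N) / P_kappa)^sigma_kappa)`,
#' so the rate is exactly `kappa0 / 2` when prevalence equals `P_kappa`,
#' for any abruptness exponent `sigma_kappa > 0`. The constant mode returns
#' `kappa0` regardless of state; the custom mode delegates to
#' `params$contact_fn(prevalence, params)`.
#'
#' @param state An [epi_state()].
#' @param params An [epi_params()].
#' @return Contact rate in contacts/day.
#' @export
contact_rate <- function(state, params) {
  if (params$contact_mode == "constant") return(params$kappa0)
  N <- alive_population(state)
  if (N <= 0) stop("degenerate state: living population is 0", call. = FALSE)
  prev <- state$I / N
  if (params$contact_mode == "custom") return(params$contact_fn(prev, params))
  params$kappa0 / (1 + (prev / params$P_kappa)^params$sigma_kappa)
}

#' Per-susceptible transmission hazard rho_SI(t)
#'
#' Frequency-dependent transmission: `rho_SI = kappa(t) * beta * I/N`,
#' where `kappa(t)` comes from [contact_rate()] so that adaptive behavior
#' propagates. Doubling S, I and N together leaves `rho_SI` unchanged.
#'
#' @inheritParams contact_rate
#' @return Per-day rate; 0 exactly when `I = 0`.
#' @export
transmission_rate <- function(state, params) {
  N <- alive_population(state)
  if (N <= 0) stop("degenerate state: living population is 0", call. = FALSE)
  contact_rate(state, params) * params$beta * state$I / N
}

#' Incidence: new infections per day
#'
#' `rho_SI(t) * S(t)`, the instantaneous rate of new infections.
#'
#' @inheritParams contact_rate
#' @return New infections per day.
#' @export
incidence_rate <- function(state, params) {
  transmission_rate(state, params) * state$S
}

#' Treatment entry rate rho_IT(t)
#'
#' Capacity-gated treatment: in the default mode the baseline rate
#' `rho_treat` applies while the treated class is within capacity
#' (`T(t) <= T_max`) and is 0 otherwise. The constant mode applies
#' `rho_treat` with no upper limit; the custom mode delegates to
#' `params$treatment_fn(state, params)`.
#'
#' @inheritParams contact_rate
#' @return Per-day rate.
#' @export
treatment_rate <- function(state, params) {
  switch(params$treatment_mode,
         constant = params$rho_treat,
         custom = params$treatment_fn(state, params),
         if (state$T <= params$T_max) params$rho_treat else 0)
}

#' Vaccination rate rho_SV(t) or rho_RV(t)
#'
#' Regimen-limited rollout: the rate `v` applies once the program has
#' started (`t >= t_V_on`) and while regimens remain
#' (`V_total <= V_max`), and is 0 otherwise. The S and R channels use
#' independently selectable modes but share `v`, `t_V_on` and `V_max` by
#' default. The constant mode always returns `v`; custom modes delegate to
#' `params$vaccS_fn` / `params$vaccR_fn`.
#'
#' @inheritParams contact_rate
#' @param source_class `"S"` or `"R"`: which living class is being
#'   vaccinated.
#' @return Per-day rate.
#' @export
vaccination_rate <- function(state, params, source_class = "S") {
  if (!source_class %in% c("S", "R"))
    stop("source_class must be \"S\" or \"R\"", call. = FALSE)
  mode <- if (source_class == "S") params$vaccS_mode else params$vaccR_mode
  if (mode == "constant") return(params$v)
  if (mode == "custom") {
    fn <- if (source_class == "S") params$vaccS_fn else params$vaccR_fn
    return(fn(state, params))
  }
  if (state$t >= params$t_V_on && state$V_total <= params$V_max) params$v else 0
}

#' Basic reproduction number R0
#'
#' Expected secondary cases from the index case in a fully susceptible
#' population: `R0 = kappa0 * beta / (rho_IR + rho_treat + rho_ID)`. With
#' no treatment and no disease-induced death this reduces to the classical
#' `kappa0 * beta / rho_IR`. Uses the baseline contact rate `kappa0` and
#' the baseline treatment rate, i.e. conditions at the start of the
#' outbreak.
#'
#' @param params An [epi_params()].
#' @return Dimensionless R0.
#' @examples
#' basic_reproduction_number(epi_params(kappa0 = 2, rho_ID = 0.005))
#' @export
basic_reproduction_number <- function(params) {
  denom <- params$rho_IR + params$rho_treat + params$rho_ID
  if (denom <= 0)
    stop("invalid parameter: rho_IR + rho_treat + rho_ID must be > 0",
         call. = FALSE)
  params$kappa0 * params$beta / denom
}

#' Effective reproduction number R_eff(t)
#'
#' The average number of new cases each currently infectious individual
#' causes, given the current susceptible fraction:
#' `R_eff = kappa(t) * beta / (rho_IR + rho_IT(t) + rho_ID) * S/N`.
#' With constant contact mode and no treatment this is exactly
#' `R0 * S(t)/N(t)`; under adaptive contact the instantaneous `kappa(t)`
#' replaces `kappa0`, so behavioral suppression is reflected.
#'
#' @inheritParams contact_rate
#' @return Dimensionless R_eff(t).
#' @export
effective_reproduction_number <- function(state, params) {
  N <- alive_population(state)
  if (N <= 0) stop("degenerate state: living population is 0", call. = FALSE)
  denom <- params$rho_IR + treatment_rate(state, params) + params$rho_ID
  if (denom <= 0)
    stop("invalid parameter: total exit rate from I must be > 0", call. = FALSE)
  contact_rate(state, params) * params$beta / denom * state$S / N
}

#' Probability of infection per contact over a short interval
#'
#' `p = 1 - exp(-kappa * beta * delta_t)`, approximately
#' `kappa * beta * delta_t` for small `delta_t`.
#'
#' @param kappa Contact rate (contacts/day, >= 0).
#' @param beta Force of infection per contact (>= 0).
#' @param delta_t Interval length in days (>= 0).
#' @return Probability in `[0, 1)`.
#' @examples
#' probability_of_infection(2, 0.3, 1)
#' @export
probability_of_infection <- function(kappa, beta, delta_t) {
  if (any(c(kappa, beta, delta_t) < 0))
    stop("invalid parameter: all arguments must be >= 0", call. = FALSE)
  -expm1(-kappa * beta * delta_t)
}

#' Outbreak probability under the classical branching approximation
#'
#' The textbook estimate `p = 1 - 1/R0` of the probability that a single
#' infectious individual introduced into a naive population starts a major
#' outbreak (assuming exponentially distributed infectious periods, i.e.
#' geometric offspring). Clamped to 0 for `R0 <= 1`, where the introduction
#' fails or peters out as a stuttering chain. For the discrete-time
#' chain-binomial model in this package the estimate is known to be biased
#' low; see [estimate_outbreak_probability()].
#'
#' @param R0 Basic reproduction number (> 0). Vectorized.
#' @return Probability in `[0, 1)`.
#' @examples
#' outbreak_probability_dh(2)  # 0.5
#' @export
outbreak_probability_dh <- function(R0) {
  if (any(is.na(R0)) || any(R0 <= 0))
    stop("invalid parameter: R0 must be > 0", call. = FALSE)
  pmax(0, 1 - 1 / R0)
}

#' Mean waiting (residence) time in a class
#'
#' Under constant exit hazards the residence time is exponential with mean
#' `1 / sum(exit_rates)`; additional competing exits shorten it. Returns
#' `Inf` when all rates are 0.
#'
#' @param exit_rates Numeric vector of per-day exit rates (>= 0).
#' @return Mean residence time in days.
#' @examples
#' mean_waiting_time(0.25)          # 4 days in I
#' mean_waiting_time(c(0.25, 0.25)) # two competing exits halve it
#' @export
mean_waiting_time <- function(exit_rates) {
  if (any(is.na(exit_rates)) || any(exit_rates < 0))
    stop("invalid parameter: rates must be >= 0", call. = FALSE)
  total <- sum(exit_rates)
  if (total == 0) return(Inf)
  1 / total
}
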