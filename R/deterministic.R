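# Internal: aggregate a layout vector into a light-weight state view (no
# class, no validation -- RK4 stage evaluations may carry tiny negative
# values, and the rate functions only need field access).
state_from_layout <- function(y, layout, t) {
  list(t = t,
       S = y[[1]],
       I = sum(y[layout$idx$I]),
       R = sum(y[layout$idx$R]),
       T = sum(y[layout$idx$T]),
       V = sum(y[layout$idx$V]),
       D = y[[layout$idx$D]],
       T_total = y[[layout$idx$T_total]],
       V_total = y[[layout$idx$V_total]])
}

# Internal: right-hand side over an expanded layout. Returns the
# derivative of every sub-state plus the accumulators, and (via attr) the
# instantaneous incidence rho_SI * S for the cumulative-incidence slot.
deriv_layout <- function(t, y, params, layout) {
  st <- state_from_layout(y, layout, t)
  rho_SI <- transmission_rate(st, params)
  rho_IT <- treatment_rate(st, params)
  rho_SV <- vaccination_rate(st, params, "S")
  rho_RV <- vaccination_rate(st, params, "R")

  S <- y[[1]]
  Iv <- y[layout$idx$I]; Rv <- y[layout$idx$R]
  Tv <- y[layout$idx$T]; Vv <- y[layout$idx$V]
  rI <- layout$stage_rate[["I"]]; rR <- layout$stage_rate[["R"]]
  rT <- layout$stage_rate[["T"]]; rV <- layout$stage_rate[["V"]]
  kI <- length(Iv); kR <- length(Rv); kT <- length(Tv); kV <- length(Vv)

  inc <- rho_SI * S
  dI <- c(inc, rI * Iv[-kI]) - (rI + rho_IT + params$rho_ID) * Iv
  dT <- c(rho_IT * st$I, rT * Tv[-kT]) - (rT + params$rho_TD) * Tv
  dR <- c(rI * Iv[kI] + rT * Tv[kT], rR * Rv[-kR]) - (rR + rho_RV) * Rv
  dV <- c(rho_SV * S + rho_RV * st$R, rV * Vv[-kV]) - rV * Vv
  dS <- rR * Rv[kR] + rV * Vv[kV] - (rho_SI + rho_SV) * S
  dD <- params$rho_ID * st$I + params$rho_TD * st$T
  dTtot <- rho_IT * st$I
  dVtot <- rho_SV * S + rho_RV * st$R

  dy <- c(dS, dI, dR, dT, dV, dD, dTtot, dVtot)
  attr(dy, "incidence") <- inc
  dy
}

#' Right-hand side of the continuous-time SIRS+DTV system
#'
#' Evaluates the instantaneous rates of change of (S, I, R, T, V, D,
#' T_total, V_total) at a given state. The transmission, treatment and
#' vaccination rates are evaluated through their mode-aware functions, so
#' adaptive contact and the capacity/regimen gates apply. The living-class
#' and death components sum to zero (closed population).
#'
#' @param state An [epi_state()].
#' @param params An [epi_params()].
#' @return Named numeric vector of eight derivatives.
#' @examples
#' derivatives(epi_state(S = 99999, I = 1), epi_params())
#' @export
derivatives <- function(state, params) {
  validate_params(params)
  if (alive_population(state) <= 0)
    stop("halt-integration: living population is 0", call. = FALSE)
  layout <- expand_model(params, NULL)
  y <- pack_state(state, layout)
  dy <- deriv_layout(state$t, y, params, layout)
  attr(dy, "incidence") <- NULL
  names(dy) <- c("S", "I", "R", "T", "V", "D", "T_total", "V_total")
  dy
}

#' Simulate the deterministic continuous-time model
#'
#' Integrates the SIRS+DTV system (the SIRS+D model is the special case
#' with treatment and vaccination off) with a fixed-step classical
#' fourth-order Runge-Kutta scheme. The death, treatment-entry and
#' vaccination accumulators and the cumulative incidence are integrated as
#' part of the state vector, so they share the integrator's order of
#' accuracy. The closed-population sum S+I+R+T+V+D is checked against N0
#' at tolerance `1e-6 * N0`.
#'
#' @param params An [epi_params()].
#' @param dt Integration step in days (0 < dt <= 1). For daily recording
#'   `1/dt` must be a whole number.
#' @param init Initial [epi_state()]; defaults to [initial_state()]
#'   (S = N0 - 1, I = 1).
#' @param boxcar `NULL`, a [boxcar_spec()] or a list of them: Erlang
#'   sub-compartment expansion applied before integration.
#' @param record `"daily"` (one row per integer day, the default, matching
#'   the stochastic engine's cadence) or `"full"` (every RK4 step).
#' @return An `epi_trajectory`: a data frame with columns `t, S, I, R, T,
#'   V, D, T_total, V_total, incidence, new_deaths` (incidence and deaths
#'   are per recording interval), carrying the generating parameters as
#'   attributes. When a boxcar expansion is active the sub-stage series
#'   are available in `attr(x, "substates")`.
#' @examples
#' p <- epi_params(kappa0 = 2, contact_mode = "constant", rho_ID = 0.005)
#' traj <- simulate_deterministic(p, dt = 0.1)
#' tail(traj, 3)
#' @export
simulate_deterministic <- function(params, dt = 0.1, init = NULL,
                                   boxcar = NULL,
                                   record = c("daily", "full")) {
  validate_params(params)
  record <- match.arg(record)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 1)
    stop("dt must satisfy 0 < dt <= 1", call. = FALSE)
  n_steps <- round(params$t_fnl / dt)
  if (abs(n_steps * dt - params$t_fnl) > 1e-8)
    stop("t_fnl must be a whole number of steps dt", call. = FALSE)
  if (record == "daily" && abs(round(1 / dt) - 1 / dt) > 1e-8)
    stop("daily recording requires 1/dt to be a whole number", call. = FALSE)
  if (is.null(init)) init <- initial_state(params)

  layout <- expand_model(params, boxcar)
  y0 <- c(pack_state(init, layout), C = 0)
  m <- length(layout$names)
  times <- seq(0, by = dt, length.out = n_steps + 1)

  rhs <- function(t, y, p) {
    dy <- deriv_layout(t, y[seq_len(m)], params, layout)
    list(c(dy, attr(dy, "incidence")))
  }
  out <- deSolve::rk4(y = y0, times = times, func = rhs, parms = NULL)

  class_cols <- 1 + seq_len(layout$idx$D)   # S..chains..D (skip time col)
  if (min(out[, class_cols]) < -1e-9 * params$N0)
    stop("integration unstable (negative class size); reduce dt", call. = FALSE)

  keep <- if (record == "daily") seq(1, n_steps + 1, by = round(1 / dt)) else
    seq_len(n_steps + 1)
  rec <- out[keep, , drop = FALSE]

  total <- rec[, 1 + 1] +                        # S
    rowSums(rec[, 1 + layout$idx$I, drop = FALSE]) +
    rowSums(rec[, 1 + layout$idx$R, drop = FALSE]) +
    rowSums(rec[, 1 + layout$idx$T, drop = FALSE]) +
    rowSums(rec[, 1 + layout$idx$V, drop = FALSE]) +
    rec[, 1 + layout$idx$D]
  if (max(abs(total - params$N0)) > 1e-6 * params$N0)
    stop("conservation violated beyond tolerance; reduce dt", call. = FALSE)

  cum_inc <- rec[, ncol(rec)]
  deaths <- rec[, 1 + layout$idx$D]
  df <- data.frame(
    t = rec[, 1],
    S = rec[, 2],
    I = rowSums(rec[, 1 + layout$idx$I, drop = FALSE]),
    R = rowSums(rec[, 1 + layout$idx$R, drop = FALSE]),
    T = rowSums(rec[, 1 + layout$idx$T, drop = FALSE]),
    V = rowSums(rec[, 1 + layout$idx$V, drop = FALSE]),
    D = deaths,
    T_total = rec[, 1 + layout$idx$T_total],
    V_total = rec[, 1 + layout$idx$V_total],
    incidence = c(0, diff(cum_inc)),
    new_deaths = c(0, diff(deaths))
  )
  substates <- if (any(layout$K > 1))
    rec[, 1 + seq_len(layout$idx$V_total), drop = FALSE] else NULL
  new_trajectory(df, params = params, engine = "deterministic", dt = dt,
                 boxcar = boxcar, substates = substates)
}

#' Check scale invariance of the deterministic model
#'
#' The continuous-time model is scale free in N0: rescaling the population
#' and initial conditions by a common factor leaves the proportion
#' trajectories unchanged. This utility runs the model at `N0` and at
#' `factor * N0` (initial conditions scaled proportionally) and reports
#' whether the proportion trajectories agree within `tol`. Note the
#' absolute capacities `T_max` and `V_max` are not rescaled, so scenarios
#' in which those gates bind are genuinely not scale free; the stochastic
#' engine is never scale free.
#'
#' @param params An [epi_params()].
#' @param factor Positive scale factor; `factor * N0` must be a whole
#'   number.
#' @param dt Integration step (days).
#' @param tol Tolerance on the maximum absolute difference of the
#'   proportion trajectories.
#' @return `TRUE` or `FALSE`.
#' @export
rescale_check <- function(params, factor, dt = 0.1, tol = 1e-8) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be > 0", call. = FALSE)
  N1 <- params$N0 * factor
  if (abs(N1 - round(N1)) > 1e-8)
    stop("factor * N0 must be a whole number", call. = FALSE)
  base <- simulate_deterministic(params, dt = dt)
  p2 <- modify_params(params, N0 = round(N1))
  init2 <- epi_state(S = (params$N0 - 1) * factor, I = factor)
  scaled <- simulate_deterministic(p2, dt = dt, init = init2)
  cols <- c("S", "I", "R", "T", "V", "D")
  d <- as.matrix(base[cols]) / params$N0 - as.matrix(scaled[cols]) / round(N1)
  max(abs(d)) <= tol
}
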