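#' Per-class exit probabilities for one daily step
#'
#' Converts every class's full set of gated exit rates at the current
#' state into per-day probabilities with the competing-risk transform
#' (interval length 1 day). Exits from S are infection and vaccination;
#' from I recovery, treatment entry and death; from R waning and
#' vaccination; from T discharge and death; from V waning. By
#' construction each class's probabilities sum to strictly less than 1,
#' the residual being the stay-put probability of the multinomial draw.
#'
#' @param state An [epi_state()].
#' @param params An [epi_params()].
#' @return Named list with elements `S`, `I`, `R`, `T`, `V`, each a named
#'   probability vector.
#' @examples
#' step_probabilities(epi_state(S = 999, I = 1), epi_params())
#' @export
step_probabilities <- function(state, params) {
  rho_SI <- transmission_rate(state, params)
  rho_IT <- treatment_rate(state, params)
  rho_SV <- vaccination_rate(state, params, "S")
  rho_RV <- vaccination_rate(state, params, "R")
  list(
    S = stats::setNames(
      competing_rates_to_probabilities(c(rho_SI, rho_SV)), c("SI", "SV")),
    I = stats::setNames(
      competing_rates_to_probabilities(c(params$rho_IR, rho_IT, params$rho_ID)),
      c("IR", "IT", "ID")),
    R = stats::setNames(
      competing_rates_to_probabilities(c(params$rho_RS, rho_RV)), c("RS", "RV")),
    T = stats::setNames(
      competing_rates_to_probabilities(c(params$rho_TR, params$rho_TD)),
      c("TR", "TD")),
    V = stats::setNames(
      competing_rates_to_probabilities(params$rho_VS), "VS")
  )
}

# Multinomial exit draw: how many of X leave by each of the exit routes
# with probabilities `probs` (residual = stay). Returns integer vector.
draw_exits <- function(X, probs) {
  k <- length(probs)
  if (X <= 0 || k == 0 || sum(probs) == 0) return(integer(k))
  stats::rmultinom(1, X, c(probs, 1 - sum(probs)))[seq_len(k), 1]
}

# One daily chain-binomial step over an expanded layout. Gated rates are
# evaluated once on the state at the start of the step.
step_layout <- function(y, t, params, layout) {
  st <- state_from_layout(y, layout, t)
  rho_SI <- transmission_rate(st, params)
  rho_IT <- treatment_rate(st, params)
  rho_SV <- vaccination_rate(st, params, "S")
  rho_RV <- vaccination_rate(st, params, "R")

  rI <- layout$stage_rate[["I"]]; rR <- layout$stage_rate[["R"]]
  rT <- layout$stage_rate[["T"]]; rV <- layout$stage_rate[["V"]]
  iI <- layout$idx$I; iR <- layout$idx$R; iT <- layout$idx$T; iV <- layout$idx$V
  kI <- length(iI); kR <- length(iR); kT <- length(iT); kV <- length(iV)

  pS <- competing_rates_to_probabilities(c(rho_SI, rho_SV))
  pI <- competing_rates_to_probabilities(c(rI, rho_IT, params$rho_ID))
  pR <- competing_rates_to_probabilities(c(rR, rho_RV))
  pT <- competing_rates_to_probabilities(c(rT, params$rho_TD))
  pV <- competing_rates_to_probabilities(rV)

  chain_exits <- function(yv, probs, nex) {
    if (length(yv) == 1L) return(matrix(draw_exits(yv[[1]], probs), ncol = 1))
    res <- vapply(yv, draw_exits, integer(nex), probs = probs)
    if (!is.matrix(res)) res <- matrix(res, nrow = nex)
    res
  }
  dS <- draw_exits(y[[1]], pS)                  # S -> I1, V1
  exI <- chain_exits(y[iI], pI, 3L)             # through, ->T, ->D
  exR <- chain_exits(y[iR], pR, 2L)             # through, ->V
  exT <- chain_exits(y[iT], pT, 2L)             # through, ->D
  exV <- chain_exits(y[iV], pV, 1L)             # through

  y2 <- y
  y2[[1]] <- y[[1]] - sum(dS) + exR[1, kR] + exV[1, kV]
  y2[iI] <- y[iI] - colSums(exI) + c(dS[1], exI[1, -kI])
  y2[iR] <- y[iR] - colSums(exR) + c(exI[1, kI] + exT[1, kT], exR[1, -kR])
  y2[iT] <- y[iT] - colSums(exT) + c(sum(exI[2, ]), exT[1, -kT])
  y2[iV] <- y[iV] - exV[1, ] + c(dS[2] + sum(exR[2, ]), exV[1, -kV])
  y2[[layout$idx$D]] <- y[[layout$idx$D]] + sum(exI[3, ]) + sum(exT[2, ])
  y2[[layout$idx$T_total]] <- y[[layout$idx$T_total]] + sum(exI[2, ])
  y2[[layout$idx$V_total]] <- y[[layout$idx$V_total]] + dS[2] + sum(exR[2, ])

  list(y = y2,
       incidence = dS[1],
       new_deaths = sum(exI[3, ]) + sum(exT[2, ]),
       draws = list(S = dS, I = exI, R = exR, T = exT, V = exV))
}

#' One step of the discrete-time stochastic model
#'
#' Advances the state by one day: each class's exits are drawn from a
#' multinomial distribution with the competing-risk probabilities of
#' [step_probabilities()], and the update equations (including the D,
#' T_total and V_total accumulators) are applied. Conservation
#' S+I+R+T+V+D = N0 holds exactly and all outputs are non-negative
#' integers.
#'
#' @param state An [epi_state()] with integer-valued fields.
#' @param params An [epi_params()].
#' @param seed Optional seed fixing the draws (otherwise the current RNG
#'   stream is used).
#' @return A list with elements `state` (the successor [epi_state()] at
#'   `t + 1`) and `draws` (the per-channel transition counts).
#' @export
stochastic_step <- function(state, params, seed = NULL) {
  fields <- unlist(state[c("S", "I", "R", "T", "V", "D", "T_total", "V_total")])
  if (any(fields != round(fields)))
    stop("contract violation: stochastic state must be integer-valued",
         call. = FALSE)
  if (!is.null(seed)) set.seed(normalize_seed(seed))
  layout <- expand_model(params, NULL)
  res <- step_layout(pack_state(state, layout), state$t, params, layout)
  list(state = unpack_state(res$y, layout, state$t + 1), draws = res$draws)
}

#' Simulate the discrete-time stochastic model
#'
#' Runs the chain-binomial Monte-Carlo process with unit daily steps from
#' `t = 0` to `t_fnl`, recording the full state plus the incidence
#' (new-infection draws) and new-death series. Identical seed and
#' configuration give bit-identical trajectories.
#'
#' @param params An [epi_params()]; `t_fnl` must be a positive integer.
#' @param seed Optional integer seed in `[0, 2^64 - 1]`; when `NULL` the
#'   current RNG stream is used (entropy-seeded behavior).
#' @param init Initial [epi_state()] with integer fields; defaults to
#'   S = N0 - 1, I = 1.
#' @param boxcar `NULL`, a [boxcar_spec()] or a list of them; sub-stage
#'   transitions are drawn per stage.
#' @param early_stop If `TRUE`, stop recording once I = 0 (no process can
#'   reseed infection in this closed model); the extinction day is stored
#'   in `attr(x, "extinction_time")`. Default `FALSE` so ensembles are
#'   rectangular.
#' @return An `epi_trajectory` (see [simulate_deterministic()]).
#' @examples
#' p <- epi_params(N0 = 1000, t_fnl = 50, contact_mode = "constant")
#' simulate_stochastic(p, seed = 1)
#' @export
simulate_stochastic <- function(params, seed = NULL, init = NULL,
                                boxcar = NULL, early_stop = FALSE) {
  validate_params(params)
  if (params$t_fnl != round(params$t_fnl))
    stop("t_fnl must be a positive integer for the stochastic engine",
         call. = FALSE)
  if (!is.null(seed)) set.seed(normalize_seed(seed))
  if (is.null(init)) init <- initial_state(params)

  layout <- expand_model(params, boxcar)
  y <- pack_state(init, layout)
  if (any(y != round(y)))
    stop("contract violation: stochastic state must be integer-valued",
         call. = FALSE)

  t_fnl <- as.integer(params$t_fnl)
  rows <- matrix(0, nrow = t_fnl + 1, ncol = length(y))
  inc <- numeric(t_fnl + 1)
  nd <- numeric(t_fnl + 1)
  rows[1, ] <- y
  extinction <- NA_real_
  last <- t_fnl
  for (t in seq_len(t_fnl) - 1L) {
    res <- step_layout(y, t, params, layout)
    y <- res$y
    rows[t + 2, ] <- y
    inc[t + 2] <- res$incidence
    nd[t + 2] <- res$new_deaths
    if (sum(y[layout$idx$I]) == 0 && is.na(extinction)) {
      extinction <- t + 1
      if (early_stop) { last <- t + 1L; break }
    }
  }
  keep <- seq_len(last + 1)
  rows <- rows[keep, , drop = FALSE]

  df <- data.frame(
    t = keep - 1,
    S = rows[, 1],
    I = rowSums(rows[, layout$idx$I, drop = FALSE]),
    R = rowSums(rows[, layout$idx$R, drop = FALSE]),
    T = rowSums(rows[, layout$idx$T, drop = FALSE]),
    V = rowSums(rows[, layout$idx$V, drop = FALSE]),
    D = rows[, layout$idx$D],
    T_total = rows[, layout$idx$T_total],
    V_total = rows[, layout$idx$V_total],
    incidence = inc[keep],
    new_deaths = nd[keep]
  )
  substates <- if (any(layout$K > 1)) {
    colnames(rows) <- layout$names
    cbind(t = df$t, rows[, seq_len(layout$idx$V_total), drop = FALSE])
  } else NULL
  new_trajectory(df, params = params, engine = "stochastic", seed = seed,
                 boxcar = boxcar, substates = substates,
                 extinction_time = extinction)
}
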