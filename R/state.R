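#' Compartment state of the SIRS+DTV model
#'
#' A snapshot of the population at time `t`: the five living classes S
#' (susceptible), I (infectious), R (recovered/immune), T (under treatment,
#' assumed fully quarantined) and V (vaccinated), the cumulative death toll
#' D, and the running totals of treatment entries and vaccination regimens
#' administered. The closed-population identity `S + I + R + T + V + D =
#' N0` holds along every trajectory (exactly for the stochastic engine,
#' to integrator tolerance for the deterministic one).
#'
#' @param S,I,R,T,V Current class sizes (>= 0).
#' @param D Cumulative disease-induced deaths.
#' @param T_total Cumulative treatment entries.
#' @param V_total Cumulative vaccination regimens administered.
#' @param t Time in days.
#' @return An object of class `"epi_state"` (a named list).
#' @examples
#' epi_state(S = 99999, I = 1)
#' @export
epi_state <- function(S, I, R = 0, T = 0, V = 0, D = 0,
                      T_total = 0, V_total = 0, t = 0) {
  s <- list(t = t, S = S, I = I, R = R, T = T, V = V, D = D,
            T_total = T_total, V_total = V_total)
  bad <- vapply(s, function(x) !is.numeric(x) || length(x) != 1 ||
                  is.na(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("invalid state: fields must be single non-negative numbers (",
         paste(names(s)[bad], collapse = ", "), ")", call. = FALSE)
  }
  class(s) <- "epi_state"
  s
}

#' Living population size N(t)
#'
#' The number of individuals currently alive, `N(t) = S + I + R + T + V`;
#' the cumulative deaths D are excluded. In SIRS-only scenarios (T = V = 0)
#' this reduces to `S + I + R`.
#'
#' @param state An [epi_state()] object.
#' @return A single count.
#' @examples
#' alive_population(epi_state(S = 900, I = 50, R = 40, T = 5, V = 5, D = 10))
#' @export
alive_population <- function(state) {
  state$S + state$I + state$R + state$T + state$V
}

#' @export
print.epi_state <- function(x, ...) {
  cat(sprintf("epi_state @ t = %g: S=%g I=%g R=%g T=%g V=%g D=%g (T_total=%g, V_total=%g)\n",
              x$t, x$S, x$I, x$R, x$T, x$V, x$D, x$T_total, x$V_total))
  invisible(x)
}

#' Default initial state for an outbreak
#'
#' The canonical index-case initial condition `S(0) = N0 - 1`, `I(0) = 1`,
#' all other classes empty.
#'
#' @param params An [epi_params()] object.
#' @return An [epi_state()] at `t = 0`.
#' @export
initial_state <- function(params) {
  epi_state(S = params$N0 - 1, I = 1)
}
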