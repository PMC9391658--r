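#' Boxcar (Erlang) sub-compartment specification
#'
#' Splitting a class into `K` serial sub-compartments, each exited at rate
#' `K * rho`, replaces the exponential residence time (mean `1/rho`) with
#' an Erlang(K, K*rho) residence time: same mean, coefficient of variation
#' `1/sqrt(K)`, and a mode near the mean for `K > 1`. Any of the classes
#' I, R, T or V may be boxed; the class's through-flow rate (`rho_IR`,
#' `rho_RS`, `rho_TR` or `rho_VS`) drives the chain, while competing exits
#' (e.g. `rho_ID` and `rho_IT` on I) act on every sub-stage at their
#' original rates so that total competing risk is preserved.
#'
#' @param class One of `"I"`, `"R"`, `"T"`, `"V"`.
#' @param K Integer number of sub-compartments (>= 1). `K = 1` is the base
#'   model.
#' @param rho Optional through-flow rate (/day) recorded for documentation;
#'   when `NULL` (default) the engines take the rate from the parameter
#'   object at expansion time.
#' @return An object of class `"boxcar_spec"`.
#' @examples
#' boxcar_spec("I", K = 5)
#' @export
boxcar_spec <- function(class = c("I", "R", "T", "V"), K, rho = NULL) {
  class <- match.arg(class)
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K < 1 || K != round(K))
    stop("invalid parameter: K must be an integer >= 1", call. = FALSE)
  if (!is.null(rho) && (!is.numeric(rho) || length(rho) != 1 || rho <= 0))
    stop("invalid parameter: rho must be a single positive rate", call. = FALSE)
  structure(list(class = class, K = as.integer(K), rho = rho),
            class = "boxcar_spec")
}

#' @export
print.boxcar_spec <- function(x, ...) {
  cat(sprintf("boxcar: class %s split into K = %d sub-stages%s\n", x$class,
              x$K, if (is.null(x$rho)) "" else sprintf(" (rho = %g/day)", x$rho)))
  invisible(x)
}

# Normalize the boxcar argument of the engines to a named K vector.
# Accepts NULL, a single boxcar_spec, or a list of them (one per class).
boxcar_K <- function(boxcar) {
  K <- c(I = 1L, R = 1L, T = 1L, V = 1L)
  if (is.null(boxcar)) return(K)
  if (inherits(boxcar, "boxcar_spec")) boxcar <- list(boxcar)
  for (spec in boxcar) {
    if (!inherits(spec, "boxcar_spec"))
      stop("boxcar must be a boxcar_spec or a list of boxcar_spec objects",
           call. = FALSE)
    if (K[[spec$class]] != 1L)
      stop(sprintf("duplicate boxcar specification for class %s", spec$class),
           call. = FALSE)
    K[[spec$class]] <- spec$K
  }
  K
}

#' Expand the model layout for boxcar sub-compartments
#'
#' Returns the internal state layout both engines integrate/sample over:
#' the ordered sub-state names, the index ranges of each class chain, the
#' per-stage through-flow rates (`K * rho`), and the accumulator slots.
#' With `K = 1` for every class the layout is the base eight-variable
#' model and engine trajectories are identical to the unexpanded model.
#'
#' @param params An [epi_params()].
#' @param boxcar `NULL`, a [boxcar_spec()], or a list of them.
#' @return A list with elements `names`, `idx` (named list of integer
#'   index vectors), `K` and `stage_rate` (per-stage through-flow rate per
#'   class).
#' @export
.layout_cache <- new.env(parent = emptyenv())

expand_model <- function(params, boxcar = NULL) {
  K <- boxcar_K(boxcar)
  key <- paste(K, collapse = ",")
  skel <- .layout_cache[[key]]
  if (is.null(skel)) {
    nm <- "S"
    idx <- list(S = 1L)
    pos <- 1L
    for (cl in c("I", "R", "T", "V")) {
      k <- K[[cl]]
      stage_names <- if (k == 1L) cl else paste0(cl, seq_len(k))
      idx[[cl]] <- pos + seq_len(k)
      pos <- pos + k
      nm <- c(nm, stage_names)
    }
    for (acc in c("D", "T_total", "V_total")) {
      pos <- pos + 1L
      idx[[acc]] <- pos
      nm <- c(nm, acc)
    }
    skel <- list(names = nm, idx = idx, K = K)
    .layout_cache[[key]] <- skel
  }
  skel$stage_rate <- K * c(I = params$rho_IR, R = params$rho_RS,
                           T = params$rho_TR, V = params$rho_VS)
  skel
}

# Pack an epi_state into a layout vector (new entrants land in stage 1).
pack_state <- function(state, layout) {
  y <- numeric(length(layout$names))
  names(y) <- layout$names
  y["S"] <- state$S
  for (cl in c("I", "R", "T", "V")) y[layout$idx[[cl]][1]] <- state[[cl]]
  y["D"] <- state$D
  y["T_total"] <- state$T_total
  y["V_total"] <- state$V_total
  y
}

# Aggregate a layout vector back to an epi_state at time t. Construction
# guarantees validity, so the epi_state() checks are skipped.
unpack_state <- function(y, layout, t) {
  structure(list(t = t,
                 S = y[[1]],
                 I = sum(y[layout$idx$I]),
                 R = sum(y[layout$idx$R]),
                 T = sum(y[layout$idx$T]),
                 V = sum(y[layout$idx$V]),
                 D = y[[layout$idx$D]],
                 T_total = y[[layout$idx$T_total]],
                 V_total = y[[layout$idx$V_total]]),
            class = "epi_state")
}

#' Erlang waiting-time density of a boxcar chain
#'
#' Density of the residence time in a class split into `K` sub-stages each
#' exited at rate `K * rho`: Erlang with shape `K` and rate `K * rho`.
#' `K = 1` reduces to the exponential density; the mode is at
#' `(K - 1) / (K * rho)` and the mean is `1 / rho` for every `K`.
#'
#' @param K Integer shape (number of sub-stages, >= 1).
#' @param rho Through-flow rate of the class (/day, > 0).
#' @param t Time(s) in days (>= 0). Vectorized.
#' @return Density value(s).
#' @examples
#' waiting_time_density(4, 0.25, 3)  # mode of the K = 4 chain
#' @export
waiting_time_density <- function(K, rho, t) {
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != round(K))
    stop("invalid parameter: K must be an integer >= 1", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("invalid parameter: rho must be > 0", call. = FALSE)
  if (any(t < 0)) stop("invalid parameter: t must be >= 0", call. = FALSE)
  stats::dgamma(t, shape = K, rate = K * rho)
}

#' Simulate residence times of a cohort passing through a boxcar chain
#'
#' Draws exit times for `n` individuals entering stage 1 of a `K`-stage
#' chain with per-stage exit rate `K * rho`, by summing the K exponential
#' stage durations of the continuous-time chain. The resulting sample is
#' Erlang(K, K*rho) distributed with mean `1/rho` and variance
#' `1/(K * rho^2)`.
#'
#' @param K Integer number of sub-stages (>= 1).
#' @param rho Through-flow rate (/day, > 0).
#' @param n Cohort size.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric vector of `n` residence times (days).
#' @export
simulate_boxcar_cohort <- function(K, rho, n, seed = NULL) {
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != round(K))
    stop("invalid parameter: K must be an integer >= 1", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("invalid parameter: rho must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(normalize_seed(seed))
  times <- numeric(n)
  for (k in seq_len(K)) times <- times + stats::rexp(n, rate = K * rho)
  times
}
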