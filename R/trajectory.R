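# Internal constructor for the trajectory container shared by both engines.
new_trajectory <- function(df, params, engine, dt = NA_real_, seed = NULL,
                           boxcar = NULL, substates = NULL,
                           extinction_time = NA_real_) {
  rownames(df) <- NULL
  structure(df,
            params = params,
            engine = engine,
            dt = dt,
            seed = seed,
            boxcar = boxcar,
            substates = substates,
            extinction_time = extinction_time,
            class = c("epi_trajectory", "data.frame"))
}

#' @export
print.epi_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  eng <- attr(x, "engine")
  n <- nrow(x)
  cat(sprintf("SIRS+DTV %s trajectory: %d records over %g days (N0 = %g)\n",
              eng, n, x$t[n], p$N0))
  if (eng == "stochastic" && !is.null(attr(x, "seed")))
    cat(sprintf("  seed: %s\n", format(attr(x, "seed"))))
  peak <- which.max(x$I)
  cat(sprintf("  peak prevalence: %g infectious on day %g\n",
              x$I[peak], x$t[peak]))
  cat(sprintf("  final: S=%g I=%g R=%g T=%g V=%g D=%g\n",
              x$S[n], x$I[n], x$R[n], x$T[n], x$V[n], x$D[n]))
  invisible(x)
}

#' @export
summary.epi_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  n <- nrow(object)
  Nfin <- object$S[n] + object$I[n] + object$R[n] + object$T[n] + object$V[n]
  peak <- which.max(object$I)
  out <- list(
    engine = attr(object, "engine"),
    horizon = object$t[n],
    N0 = p$N0,
    R0 = tryCatch(basic_reproduction_number(p), error = function(e) NA_real_),
    peak_prevalence = object$I[peak] / (object$S[peak] + object$I[peak] +
                                          object$R[peak] + object$T[peak] +
                                          object$V[peak]),
    peak_day = object$t[peak],
    attack_rate = sum(object$incidence) / p$N0,
    deaths = object$D[n],
    final_susceptible_fraction = object$S[n] / Nfin
  )
  class(out) <- "summary.epi_trajectory"
  out
}

#' @export
print.summary.epi_trajectory <- function(x, ...) {
  cat(sprintf("%s run over %g days, N0 = %g, R0 = %.4g\n",
              x$engine, x$horizon, x$N0, x$R0))
  cat(sprintf("  peak prevalence %.4g on day %g\n", x$peak_prevalence,
              x$peak_day))
  cat(sprintf("  attack rate %.4g, deaths %g\n", x$attack_rate, x$deaths))
  cat(sprintf("  final susceptible fraction %.4g\n",
              x$final_susceptible_fraction))
  invisible(x)
}

#' Prevalence series of a trajectory
#'
#' Infectious proportion over time. The default denominator is the living
#' population N(t) = S+I+R+T+V, matching the transmission terms of the
#' model; `denominator = "initial"` reports against N0 instead.
#'
#' @param traj An `epi_trajectory`.
#' @param denominator `"alive"` (N(t), default) or `"initial"` (N0).
#' @return Numeric vector aligned with `traj$t`.
#' @export
prevalence <- function(traj, denominator = c("alive", "initial")) {
  denominator <- match.arg(denominator)
  if (denominator == "initial") return(traj$I / attr(traj, "params")$N0)
  traj$I / (traj$S + traj$I + traj$R + traj$T + traj$V)
}

#' @export
plot.epi_trajectory <- function(x, variables = c("S", "I", "R"),
                                proportion = TRUE, ...) {
  p <- attr(x, "params")
  N <- if (proportion) x$S + x$I + x$R + x$T + x$V else rep(1, nrow(x))
  cols <- grDevices::hcl.colors(length(variables), "Dark 3")
  y <- as.matrix(as.data.frame(x)[variables]) / N
  graphics::matplot(x$t, y, type = "l", lty = 1, col = cols,
                    xlab = "time (days)",
                    ylab = if (proportion) "proportion of N(t)" else "count",
                    ...)
  graphics::legend("right", legend = variables, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' @export
as.data.frame.epi_trajectory <- function(x, ...) {
  attributes(x) <- list(names = names(unclass(x)),
                        row.names = .row_names_info(x, type = 0),
                        class = "data.frame")
  x
}

# Seeds may span the full unsigned 64-bit range accepted by scenario
# configurations; fold into the signed 32-bit range of set.seed().
normalize_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed < 0 || seed >= 2^64)
    stop("seed must be a single number in [0, 2^64 - 1]", call. = FALSE)
  as.integer(seed %% 2147483647)
}
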