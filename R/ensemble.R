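#' Run a one-parameter sweep
#'
#' Repeats a run for each value of one parameter, all else held fixed.
#' Deterministic sweeps are order-independent; stochastic sweeps use
#' per-run seeds derived as `seed + run index` so each run is
#' reproducible and the streams are independent.
#'
#' @param params Base [epi_params()].
#' @param name Name of the parameter field to vary (e.g. `"kappa0"`).
#' @param values Vector of admissible values.
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param dt Integration step for the deterministic engine.
#' @param seed Base seed for the stochastic engine.
#' @param boxcar Optional boxcar specification passed through.
#' @return Named list of `epi_trajectory` objects (`name=value`).
#' @examples
#' tr <- sweep_parameter(epi_params(t_fnl = 30), "kappa0", c(2, 3))
#' names(tr)
#' @export
sweep_parameter <- function(params, name, values,
                            engine = c("deterministic", "stochastic"),
                            dt = 0.1, seed = NULL, boxcar = NULL) {
  engine <- match.arg(engine)
  if (!is.character(name) || length(name) != 1 || !name %in% names(params) ||
      is.function(params[[name]]))
    stop(sprintf("config error: unknown parameter '%s'", name), call. = FALSE)
  out <- vector("list", length(values))
  names(out) <- paste0(name, "=", values)
  for (i in seq_along(values)) {
    p <- params
    p[[name]] <- values[i]
    validate_params(p)
    out[[i]] <- if (engine == "deterministic") {
      simulate_deterministic(p, dt = dt, boxcar = boxcar)
    } else {
      simulate_stochastic(p, seed = if (is.null(seed)) NULL else seed + i,
                          boxcar = boxcar)
    }
  }
  out
}

# Default major/minor split: cumulative incidence above max(25, 1% of N0).
# The valley between stuttering chains and exponential outbreaks sits well
# inside this band for the parameter ranges the simulators target.
default_threshold <- function(params) max(25, 0.01 * params$N0)

#' Classify a stochastic run as a minor or major outbreak
#'
#' A run is a major outbreak when its cumulative incidence (total
#' new-infection draws) exceeds the threshold; otherwise it is a minor
#' outbreak (a stuttering transmission chain that went extinct before its
#' exponential phase).
#'
#' @param traj A stochastic `epi_trajectory`.
#' @param threshold Cumulative-incidence threshold; defaults to
#'   `max(25, 0.01 * N0)`.
#' @return `"minor"` or `"major"`.
#' @export
classify_outbreak <- function(traj, threshold = NULL) {
  if (!identical(attr(traj, "engine"), "stochastic"))
    stop("not applicable: outbreak classification requires a stochastic run",
         call. = FALSE)
  if (is.null(threshold)) threshold <- default_threshold(attr(traj, "params"))
  if (sum(traj$incidence) > threshold) "major" else "minor"
}

#' Outbreak duration of a stochastic run
#'
#' The first recorded day on which I = 0; the horizon if prevalence never
#' hits zero within the run.
#'
#' @param traj A stochastic `epi_trajectory`.
#' @return Duration in days.
#' @export
outbreak_duration <- function(traj) {
  if (!identical(attr(traj, "engine"), "stochastic"))
    stop("not applicable: outbreak duration requires a stochastic run",
         call. = FALSE)
  hit <- which(traj$I == 0)
  if (length(hit) == 0) traj$t[nrow(traj)] else traj$t[hit[1]]
}

#' Run a stochastic ensemble
#'
#' Repeats the stochastic simulation `n_runs` times with per-run seeds
#' `seed + 1, ..., seed + n_runs`, classifying each run as a minor or
#' major outbreak and recording its duration. By default every run covers
#' the full horizon so the ensemble is rectangular.
#'
#' @param params An [epi_params()].
#' @param n_runs Number of replicate runs (>= 1).
#' @param seed Base seed; per-run seeds are derived from it.
#' @param boxcar Optional boxcar specification.
#' @param early_stop Stop each run at extinction (see
#'   [simulate_stochastic()]).
#' @param threshold Major/minor cumulative-incidence threshold; defaults
#'   to `max(25, 0.01 * N0)`.
#' @return An `epi_ensemble`: list with `trajectories`, `classifications`,
#'   `durations`, `threshold`, `params`, `seed`.
#' @examples
#' ens <- simulate_ensemble(epi_params(N0 = 500, t_fnl = 60,
#'                                     contact_mode = "constant"),
#'                          n_runs = 5, seed = 1)
#' table(ens$classifications)
#' @export
simulate_ensemble <- function(params, n_runs, seed = NULL, boxcar = NULL,
                              early_stop = FALSE, threshold = NULL) {
  if (!is.numeric(n_runs) || length(n_runs) != 1 || n_runs < 1)
    stop("config error: n_runs must be >= 1", call. = FALSE)
  if (is.null(threshold)) threshold <- default_threshold(params)
  runs <- vector("list", n_runs)
  cls <- character(n_runs)
  dur <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    runs[[i]] <- simulate_stochastic(
      params, seed = if (is.null(seed)) NULL else seed + i,
      boxcar = boxcar, early_stop = early_stop)
    cls[i] <- classify_outbreak(runs[[i]], threshold)
    dur[i] <- outbreak_duration(runs[[i]])
  }
  structure(list(trajectories = runs, classifications = cls,
                 durations = dur, threshold = threshold,
                 params = params, seed = seed),
            class = "epi_ensemble")
}

#' @export
print.epi_ensemble <- function(x, ...) {
  n <- length(x$trajectories)
  nm <- sum(x$classifications == "major")
  cat(sprintf("stochastic ensemble: %d runs (N0 = %g)\n", n, x$params$N0))
  cat(sprintf("  %d major / %d minor outbreaks (threshold %g cumulative cases)\n",
              nm, n - nm, x$threshold))
  cat(sprintf("  duration: median %g days, range [%g, %g]\n",
              stats::median(x$durations), min(x$durations), max(x$durations)))
  invisible(x)
}

#' Per-day mean and standard deviation over an ensemble subset
#'
#' Pointwise summary curves of one variable over all runs, or over the
#' major- or minor-outbreak subset only (the subset filter is applied
#' before the statistics). Runs stopped early at extinction are carried
#' forward at their last recorded state.
#'
#' @param ensemble An `epi_ensemble`.
#' @param variable Trajectory column to summarize (default `"I"`).
#' @param subset `"all"`, `"major"` or `"minor"`.
#' @return Data frame with columns `t`, `mean`, `sd`, `n`.
#' @export
ensemble_summary <- function(ensemble, variable = "I",
                             subset = c("all", "major", "minor")) {
  subset <- match.arg(subset)
  keep <- if (subset == "all") seq_along(ensemble$trajectories) else
    which(ensemble$classifications == subset)
  if (length(keep) == 0)
    stop("empty selection: no runs in subset '", subset, "'", call. = FALSE)
  if (length(keep) < 2)
    stop("at least 2 runs are required in subset '", subset, "'",
         call. = FALSE)
  horizon <- max(vapply(ensemble$trajectories, function(tr) tr$t[nrow(tr)],
                        numeric(1)))
  days <- 0:horizon
  mat <- vapply(ensemble$trajectories[keep], function(tr) {
    v <- tr[[variable]]
    c(v, rep(v[length(v)], length(days) - length(v)))
  }, numeric(length(days)))
  data.frame(t = days,
             mean = rowMeans(mat),
             sd = apply(mat, 1, stats::sd),
             n = length(keep))
}

#' Estimate the outbreak probability by Monte Carlo
#'
#' Fraction of major outbreaks among replicate introductions of a single
#' infectious individual, with an exact (Clopper-Pearson) confidence
#' interval, reported alongside the classical branching-process estimate
#' `1 - 1/R0` (which, for this discrete-time chain-binomial model, is
#' biased low). Runs stop at extinction since classification only depends
#' on the infection chain.
#'
#' @param params An [epi_params()].
#' @param n_runs Number of replicate runs.
#' @param seed Base seed.
#' @param threshold Major/minor threshold (default `max(25, 0.01 * N0)`).
#' @param conf Confidence level of the interval.
#' @return An `outbreak_probability` object: `estimate`, `ci`, `n_runs`,
#'   `n_major`, `threshold`, `R0`, `p_dh`.
#' @export
estimate_outbreak_probability <- function(params, n_runs, seed = NULL,
                                          threshold = NULL, conf = 0.95) {
  if (!is.numeric(n_runs) || length(n_runs) != 1 || n_runs < 1)
    stop("config error: n_runs must be >= 1", call. = FALSE)
  if (is.null(threshold)) threshold <- default_threshold(params)
  n_major <- 0L
  for (i in seq_len(n_runs)) {
    tr <- simulate_stochastic(params,
                              seed = if (is.null(seed)) NULL else seed + i,
                              early_stop = TRUE)
    if (classify_outbreak(tr, threshold) == "major") n_major <- n_major + 1L
  }
  ci <- stats::binom.test(n_major, n_runs, conf.level = conf)$conf.int
  R0 <- basic_reproduction_number(params)
  structure(list(estimate = n_major / n_runs,
                 ci = as.numeric(ci), conf = conf,
                 n_runs = as.integer(n_runs), n_major = n_major,
                 threshold = threshold, R0 = R0,
                 p_dh = if (R0 > 0) outbreak_probability_dh(R0) else NA_real_),
            class = "outbreak_probability")
}

#' @export
print.outbreak_probability <- function(x, ...) {
  cat(sprintf("outbreak probability: %.3f (%d/%d major runs)\n",
              x$estimate, x$n_major, x$n_runs))
  cat(sprintf("  %.0f%% CI [%.3f, %.3f], threshold %g cumulative cases\n",
              100 * x$conf, x$ci[1], x$ci[2], x$threshold))
  cat(sprintf("  branching estimate 1 - 1/R0 = %.3f at R0 = %.3f\n",
              x$p_dh, x$R0))
  invisible(x)
}

#' Closed-form final-size oracle for the SIR special case
#'
#' Solves the final-size relation `s = exp(-R0 * (1 - s))` for the
#' asymptotic susceptible fraction of an SIR epidemic (no waning, no
#' disease-induced death) by damped fixed-point iteration to absolute
#' tolerance 1e-10. For `R0 <= 1` the epidemic does not take off and the
#' susceptible fraction stays 1.
#'
#' @param R0 Basic reproduction number (> 0).
#' @return Susceptible fraction `s` in `(0, 1]`.
#' @examples
#' final_size_oracle(2)
#' @export
final_size_oracle <- function(R0) {
  if (!is.numeric(R0) || length(R0) != 1 || is.na(R0) || R0 <= 0)
    stop("invalid parameter: R0 must be > 0", call. = FALSE)
  if (R0 <= 1) return(1)
  s <- 0.5
  for (i in 1:10000) {
    s_new <- 0.5 * s + 0.5 * exp(-R0 * (1 - s))
    if (abs(s_new - s) < 1e-12) return(s_new)
    s <- s_new
  }
  s
}
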