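# Shared scenario constructors and independent oracles used across tests.

# The worked single-outbreak example: constant contact kappa0 = 2,
# beta = 0.3, 4-day infectious period, virulence 0.005, no waning.
sir_example_params <- function(...) {
  args <- utils::modifyList(
    list(kappa0 = 2, contact_mode = "constant", beta = 0.3, rho_IR = 0.25,
         rho_ID = 0.005, rho_RS = 0, N0 = 1e5, t_fnl = 100),
    list(...))
  do.call(epi_params, args)
}

# A scenario exercising every flow of the full model.
dtv_example_params <- function(...) {
  args <- utils::modifyList(
    list(kappa0 = 2, contact_mode = "constant", rho_ID = 0.005,
         rho_RS = 0.01, rho_treat = 0.05, T_max = 500, rho_TR = 0.1,
         rho_TD = 0.002, v = 0.003, t_V_on = 20, V_max = 2e4,
         N0 = 1e5, t_fnl = 60),
    list(...))
  do.call(epi_params, args)
}

# Independent final-size oracle: root of log(s) + R0 (1 - s) = 0 in (0, 1),
# solved by stats::uniroot (a different route than the package's damped
# fixed-point iteration).
final_size_uniroot <- function(R0) {
  if (R0 <= 1) return(1)
  stats::uniroot(function(s) log(s) + R0 * (1 - s),
                 c(1e-12, 1 - 1e-9), tol = 1e-12)$root
}

# Extinction/outbreak probability of the daily chain-binomial branching
# process: one infective infects ~Poisson(kappa*beta) new cases per day
# and survives each day with probability exp(-rho_exit), so the offspring
# pgf is f(s) = p g(s) / (1 - (1-p) g(s)) with g(s) = exp(kb (s-1)) and
# p = 1 - exp(-rho_exit). The outbreak probability is 1 - q, q = f(q).
branching_outbreak_oracle <- function(kappa_beta, rho_exit) {
  p <- 1 - exp(-rho_exit)
  q <- 0.5
  for (i in 1:10000) {
    g <- exp(kappa_beta * (q - 1))
    q_new <- p * g / (1 - (1 - p) * g)
    if (abs(q_new - q) < 1e-12) break
    q <- q_new
  }
  1 - q
}

# One application of the deterministic discrete-time (mean-field) map for
# an SIRS state, written out from the update equations with single-rate
# exponential transforms -- independent of the package's samplers.
mean_field_sirs_step <- function(S, I, R, kappa_beta, rho_IR, rho_RS) {
  N <- S + I + R
  p_SI <- 1 - exp(-kappa_beta * I / N)
  p_IR <- 1 - exp(-rho_IR)
  p_RS <- 1 - exp(-rho_RS)
  c(S = S * (1 - p_SI) + R * p_RS,
    I = I * (1 - p_IR) + S * p_SI,
    R = R * (1 - p_RS) + I * p_IR)
}
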