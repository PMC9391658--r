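---
title: "Methods: the SIRS+DTV simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SIRS+DTV simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirsdtv)
```

## The model family

`sirsdtv` simulates a closed, homogeneous, well-mixed population moving
between six states: susceptible (S), infectious (I), recovered with
immunity (R), under treatment (T), vaccinated (V) and dead from the
disease (D). There are no births, natural deaths or migration, so
`S + I + R + T + V + D = N0` along every trajectory, and the living
population is `N(t) = S + I + R + T + V`. Three running totals are kept
alongside the state: cumulative deaths `D`, cumulative treatment
entries `T_total`, and vaccination regimens administered `V_total`.

All flows are per-capita daily rates. The non-trivial ones:

* **Transmission** is frequency dependent:
  `rho_SI = kappa(t) * beta * I/N`. The contact rate `kappa` and the
  per-contact force of infection `beta` are kept separate (rather than
  folded into a single transmission coefficient) so that behavioral
  change acts on contacts alone. Treated individuals are assumed fully
  quarantined and the dead do not transmit, so neither T nor D appears
  in the infection pressure.
* **Adaptive contact** (the `"default"` contact mode):
  `kappa = kappa0 / (1 + ((I/N)/P_kappa)^sigma_kappa)`. At prevalence
  `P_kappa` the rate is exactly `kappa0/2` for any abruptness exponent
  `sigma_kappa > 0`; `sigma_kappa` near 2 gives gradual suppression, 20
  approximates a step. `P_kappa = Inf` (the default) disables the
  response; the `"constant"` mode pins `kappa = kappa0` regardless of
  state.
* **Treatment** moves infectives to T at `rho_treat` while the ward is
  within capacity (`T(t) <= T_max`), and not at all above it. The
  `"constant"` mode drops the capacity gate.
* **Vaccination** moves S (and, with its own mode selector, R) to V at
  rate `v` from day `t_V_on` while `V_total <= V_max`. Re-vaccination
  of individuals who waned back to S is deliberate: the budget counts
  regimens, not people.

The basic reproduction number uses the initial contact and baseline
treatment rates, `R0 = kappa0 * beta / (rho_IR + rho_treat + rho_ID)`.
`effective_reproduction_number()` evaluates the same expression on the
current state — instantaneous `kappa(t)`, gated `rho_IT(t)` — scaled by
`S/N`; with constant contact and no treatment it reduces exactly to
`R0 * S/N`. Using the instantaneous `kappa(t)` is a deliberate choice:
R_eff is meant to describe transmission conditions *now*, including
behavioral suppression.

### Parameter defaults and units

Defaults describe a fast, directly transmitted respiratory pathogen
with a daily time unit: `beta = 0.3`, infectious period
`1/rho_IR = 4` days, `sigma_kappa = 4`, no waning, no interventions,
`N0 = 1e5`. Capacities default to `T_max = 10^4` individuals and
`V_max = 10^5` regimens but are inert until `rho_treat` or `v` is
positive. The treatment discharge rate defaults to `rho_TR = 0.1`/day
(a ten-day treated stay), a round value in the plausible clinical
range; it only matters once treatment is switched on. `rho_VS`
defaults to `rho_RS` — vaccine- and infection-derived immunity wane
alike unless set apart.

## The deterministic engine

`simulate_deterministic()` integrates the continuous-time balance
equations with a fixed-step classical 4th-order Runge-Kutta scheme
(via `deSolve::rk4`). Design choices:

* **Step size** defaults to `dt = 0.1` day. The fastest rate scale in
  the intended parameter ranges is `kappa0 * beta` of order 1–2/day, so
  0.1 day resolves the dynamics with a wide margin; halving `dt` on the
  worked single-outbreak run moves the endpoint by about `3e-6`
  individuals in `1e5`.
* **Accumulators** (D, `T_total`, `V_total`) and the cumulative
  incidence are integrated as extra state-vector components, so they
  inherit the integrator's order of accuracy. Per-day incidence and
  new deaths are first differences of those integrals at the recording
  cadence — not finite differences of S, which waning re-entries would
  corrupt.
* **Gates** (treatment capacity, vaccination budget/onset) make the
  right-hand side discontinuous. They are evaluated at every
  derivative evaluation on the stage state, and RK4 is applied
  regardless, accepting first-order local error in the step containing
  a switch; users who care about the switching neighborhood can halve
  `dt`. No event detection is attempted.
* **Recording** is once per integer day by default, matching the
  stochastic engine's natural cadence; `record = "full"` returns every
  step.
* **Sanity checks**: any class dipping below `-1e-9 * N0` aborts with
  an instability error, and the population sum is verified to stay
  within `1e-6 * N0` of `N0`.

The continuous-time model is scale free in `N0` (all flows are
per-capita and transmission divides by `N`), which
`rescale_check()` verifies by rescaling runs; the absolute capacities
`T_max` and `V_max` are the only scale-breaking quantities, and the
stochastic engine is never scale free.

Prevalence and other proportions are reported against the living
population `N(t)` — the same denominator the transmission term uses —
with `prevalence(..., denominator = "initial")` exposing the `N0`
reading; with deaths active the two differ by up to a couple of
percent.

## The stochastic engine

`simulate_stochastic()` runs the daily chain binomial. Each day, every
class's full set of exit rates is converted to probabilities with the
competing-risk transform

    p_i = (rho_i / sum(rho)) * (1 - exp(-sum(rho) * dt)),   dt = 1,

and exits are drawn from one multinomial per class (binomial where a
single exit exists), the residual being the stay-put probability —
which the transform guarantees is non-negative. The competing
transform is applied uniformly, including to S (infection versus
vaccination), since its logic covers any multi-exit class and a
single-rate input reduces exactly to `1 - exp(-rho)`. Rates are
re-evaluated from the current state every day, so adaptive contact and
the gates propagate into the probabilities; gate state is read once at
the start of each day, so a multinomial draw may overshoot the
vaccination budget by at most one day's draws before the gate shuts.

The step is exactly conservative in integers by construction. Seeds up
to `2^64 - 1` are accepted in configurations and folded into R's RNG;
identical seed and configuration give bit-identical trajectories.
Early termination at `I = 0` is opt-in (`early_stop = TRUE`): nothing
can reseed infection in this closed model, so classification and
duration are unaffected, but the default keeps full-horizon records so
ensembles stay rectangular.

A systematic note: the daily discrete-time process is not a
discretization error-free copy of the continuous-time model. With
rates of order 0.25/day the one-day transform shifts epidemic timing
by a few days relative to the ODE (peak sizes agree closely). Tests
that pair the engines therefore compare the major-outbreak ensemble
mean to the deterministic curve within three *between-run standard
deviations* per day; standard-error-level agreement is not attainable,
nor claimed.

## Boxcar (Erlang) waiting times

Exponential residence times make departure most likely immediately
after entry. `boxcar_spec(class, K)` splits any of I, R, T, V into `K`
serial sub-stages, each exited at `K * rho`, so the residence time
becomes Erlang(K, K·rho): same mean `1/rho`, coefficient of variation
`1/sqrt(K)`, mode at `(K-1)/(K*rho)`. Only the class's through-flow is
accelerated; competing exits (e.g. death and treatment entry out of I)
act on every sub-stage at their original rates, preserving the total
competing risk — this placement is this package's design choice.
The expansion applies to both engines (extra ODE states; per-stage
multinomials), `K = 1` reproduces the base model bit for bit, and the
observable class total is always the chain sum (sub-stages are
available in `attr(x, "substates")`).

## Ensemble machinery

* `sweep_parameter()` varies one field with everything else fixed;
  stochastic sweeps derive per-run seeds as `seed + index`.
* `classify_outbreak()` splits runs into minor (stuttering chain) and
  major outbreaks by cumulative incidence. No published threshold
  exists for the split, so the default is `max(25, 0.01 * N0)` — far
  above typical stuttering-chain totals (a handful to a few dozen
  cases) and far below major-outbreak totals (a large fraction of
  `N0`) across the intended parameter ranges; it is configurable and
  recorded in ensemble output.
* `estimate_outbreak_probability()` reports the major fraction with an
  exact Clopper-Pearson interval next to the classical branching
  estimate `1 - 1/R0`. For this daily chain the classical value is
  biased low by roughly ten percent for R0 in 3–6: a daily burst of
  roughly Poisson(`kappa*beta`) infections over a geometric lifetime is
  less extinction-prone than the geometric-offspring process behind
  `1 - 1/R0`. The test suite checks the empirical estimate against the
  fixed point of the compound pgf induced by the daily chain.
* `final_size_oracle()` solves `s = exp(-R0 (1 - s))` by damped
  fixed-point iteration (tolerance `1e-10`; damping factor 0.5
  guarantees convergence for all `R0 > 1`, returning 1 for
  `R0 <= 1`). The deterministic engine reproduces it to `1e-3` when
  death and waning are off.

## What the test scenarios emulate

The suite drives the simulators through the canonical qualitative
regimes: a single-outbreak SIR run (final susceptible fraction ~0.128
at `R0 = 2.353`, R_eff crossing 1 at the peak and reaching ~0.3 by day
70); endemic levels increasing with the waning rate over 720 days;
peak flattening as the behavioral switching point drops
(`P_kappa` 0.01 < 0.1 < none, 300 days); treated-class peaks ordered
by the treatment rate; and an early (day-100) versus late (day-250)
vaccination rollout. The rollout scenario's parameters are this
package's own choice (`N0 = 1e6`, `rho_RS = rho_VS = 0.01`,
`rho_ID = 0.005`, `v = 0.003`, `V_max = 1e6`): both programs exhaust
the budget before day 700, the early start suppresses the second
prevalence peak and keeps cumulative deaths lower throughout days
200–700, and the death curves converge once regimens run out.

Problem sizes in the suite (e.g. 1000-run ensembles at `N0 = 1e4` for
outbreak-probability checks, `1e5` replicate one-step draws, 720-day
endemicity runs at `dt = 0.25`) were chosen as the smallest scales at
which the quantities under test are statistically decisive.

## What the generator does and does not emulate

The simulators produce exactly the idealized processes described
above: homogeneous mixing, exponential (or Erlang) residence times,
constant parameters, a closed population. Passing tests demonstrate
internal correctness against closed forms and cross-engine agreement —
not realism about any particular pathogen: real epidemics have age and
household structure, time-varying reporting, latency, asymptomatic
transmission and demographic turnover, all explicitly out of scope
here.

## Numerical and degenerate-input conventions

* `rate_to_probability()` and friends use `expm1`, so tiny rates do
  not lose precision; zero rates give exactly zero probability and an
  all-zero competing set returns all zeros without consuming
  randomness.
* A living population of zero is a degenerate state: rate functions
  refuse it rather than returning NaN.
* `outbreak_probability_dh()` clamps to 0 for `R0 <= 1` (the
  introduction peters out).
* `sigma_kappa = 0` makes the adaptive form constant at `kappa0/2` —
  the formula's honest limit; use the constant mode for `kappa0`.
* CSV exports format numbers at 17 significant digits so a write/read
  round trip is bit-exact; headers are `#`-prefixed key/value lines
  carrying every parameter, mode, seed and the package version.

## Known limitations

Fixed-step integration with discontinuous gates (no event location);
daily-step stochasticity only (no sub-daily steps or continuous-time
event-driven simulation); no demographic processes; the minor/major
threshold, while robust in the intended ranges, is a convention rather
than an estimator.
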