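test_that("rate-to-probability transform matches the exponential closed form", {
  expect_identical(rate_to_probability(0, 1), 0)
  expect_identical(rate_to_probability(0, 17.3), 0)
  expect_equal(rate_to_probability(0.25, 1), 1 - exp(-0.25), tolerance = 1e-12)
  expect_equal(rate_to_probability(0.25, 1), 0.221199, tolerance = 1e-5)
  expect_lte(rate_to_probability(1e9, 1), 1)
  expect_gt(rate_to_probability(1e9, 1), 1 - 1e-12)
  expect_true(all(diff(rate_to_probability(seq(0, 3, 0.1), 1)) > 0))
  expect_true(all(diff(rate_to_probability(0.3, seq(0.5, 5, 0.5))) > 0))
  expect_error(rate_to_probability(-0.1), "invalid")
  expect_error(rate_to_probability(0.1, 0), "invalid")
})

test_that("rate/probability round trip is the identity", {
  set.seed(42)
  p <- runif(200)
  expect_equal(rate_to_probability(-log(1 - p), 1), p, tolerance = 1e-12)
  rho <- rexp(200)
  expect_equal(-log(1 - rate_to_probability(rho, 1)), rho, tolerance = 1e-9)
})

test_that("competing-risk split preserves the joint exit mass and rate ratios", {
  pr <- competing_rates_to_probabilities(c(0.25, 0.005), 1)
  expect_equal(sum(pr), 1 - exp(-0.255), tolerance = 1e-12)
  expect_equal(unname(pr), c(0.220670, 0.004413), tolerance = 1e-4)
  expect_equal(pr[[1]] / pr[[2]], 50, tolerance = 1e-12)
  expect_equal(competing_rates_to_probabilities(0.3, 1.7),
               rate_to_probability(0.3, 1.7))
  expect_identical(competing_rates_to_probabilities(c(0, 0)), c(0, 0))
  set.seed(7)
  for (i in 1:25) {
    rhos <- rexp(sample(1:5, 1))
    dt <- runif(1, 0.1, 2)
    pr <- competing_rates_to_probabilities(rhos, dt)
    expect_equal(sum(pr), 1 - exp(-sum(rhos) * dt), tolerance = 1e-12)
    expect_equal(pr / sum(pr), rhos / sum(rhos), tolerance = 1e-12)
    expect_lt(sum(pr), 1)
  }
  expect_error(competing_rates_to_probabilities(c(0.1, -0.2)), "invalid")
})

test_that("living population excludes the dead", {
  expect_identical(alive_population(epi_state(S = 99999, I = 1)), 100000)
  expect_identical(alive_population(epi_state(S = 0, I = 0)), 0)
  st <- epi_state(S = 900, I = 50, R = 40, T = 5, V = 5, D = 10)
  expect_identical(alive_population(st), 1000)
})

test_that("adaptive contact halves at the switching prevalence and never increases with prevalence", {
  p <- epi_params(kappa0 = 2, P_kappa = 0.1, sigma_kappa = 4)
  expect_equal(contact_rate(epi_state(S = 1000, I = 0), p), 2)
  for (sig in c(0.5, 2, 5, 20)) {
    psig <- epi_params(kappa0 = 2, P_kappa = 0.1, sigma_kappa = sig)
    expect_equal(contact_rate(epi_state(S = 900, I = 100), psig), 1,
                 tolerance = 1e-12)
    prev <- seq(0.001, 0.9, length.out = 50)
    kap <- vapply(prev, function(q)
      contact_rate(epi_state(S = 1000 * (1 - q), I = 1000 * q), psig),
      numeric(1))
    expect_true(all(diff(kap) < 0))
  }
  pc <- epi_params(kappa0 = 2, contact_mode = "constant")
  expect_identical(contact_rate(epi_state(S = 500, I = 500), pc), 2)
  pcu <- epi_params(kappa0 = 2, contact_mode = "custom",
                    contact_fn = function(prev, params) params$kappa0 * (1 - prev))
  expect_equal(contact_rate(epi_state(S = 750, I = 250), pcu), 1.5)
  expect_error(contact_rate(epi_state(S = 0, I = 0), p), "degenerate")
})

test_that("transmission is frequency dependent and vanishes without infectives", {
  p <- epi_params(kappa0 = 2, beta = 0.3, contact_mode = "constant")
  expect_identical(transmission_rate(epi_state(S = 1000, I = 0), p), 0)
  st <- epi_state(S = 900, I = 100)
  expect_equal(transmission_rate(st, p), 0.06, tolerance = 1e-12)
  expect_equal(incidence_rate(st, p), 0.06 * 900, tolerance = 1e-12)
  st2 <- epi_state(S = 1800, I = 200)
  expect_equal(transmission_rate(st2, p), transmission_rate(st, p),
               tolerance = 1e-12)
  expect_equal(incidence_rate(st2, p), 2 * incidence_rate(st, p),
               tolerance = 1e-12)
})

test_that("treatment entry is gated by ward capacity", {
  p <- epi_params(rho_treat = 0.08, T_max = 100)
  expect_identical(treatment_rate(epi_state(S = 1, I = 1, T = 0), p), 0.08)
  expect_identical(treatment_rate(epi_state(S = 1, I = 1, T = 100), p), 0.08)
  expect_identical(treatment_rate(epi_state(S = 1, I = 1, T = 101), p), 0)
  pc <- epi_params(rho_treat = 0.08, T_max = 100, treatment_mode = "constant")
  expect_identical(treatment_rate(epi_state(S = 1, I = 1, T = 1000), pc), 0.08)
})

test_that("vaccination rollout respects onset time and the regimen budget", {
  p <- epi_params(v = 0.003, t_V_on = 100, V_max = 500, t_fnl = 400)
  expect_identical(vaccination_rate(epi_state(S = 1, I = 1, t = 99), p), 0)
  expect_identical(vaccination_rate(epi_state(S = 1, I = 1, t = 100), p), 0.003)
  st_cap <- epi_state(S = 1, I = 1, V_total = 501, t = 200)
  expect_identical(vaccination_rate(st_cap, p), 0)
  expect_identical(vaccination_rate(st_cap, p, "R"), 0)
  expect_identical(vaccination_rate(epi_state(S = 1, I = 1, V_total = 500,
                                              t = 200), p), 0.003)
})

test_that("R0 matches kappa*beta over the total exit rate from I", {
  p <- epi_params(kappa0 = 2, beta = 0.3, rho_IR = 0.25, rho_ID = 0.005)
  expect_equal(round(basic_reproduction_number(p), 3), 2.353)
  p2 <- epi_params(kappa0 = 2, beta = 0.3, rho_IR = 0.25)
  expect_equal(basic_reproduction_number(p2), 2 * 0.3 / 0.25, tolerance = 1e-15)
  p3 <- epi_params(kappa0 = 2, beta = 0.3, rho_IR = 0.25, rho_ID = 0.005,
                   rho_treat = 0.1)
  expect_equal(basic_reproduction_number(p3), 0.6 / 0.355, tolerance = 1e-12)
  p0 <- epi_params(rho_IR = 0, rho_ID = 0, rho_treat = 0)
  expect_error(basic_reproduction_number(p0), "invalid")
})

test_that("R_eff scales R0 by the susceptible fraction and follows kappa(t)", {
  p <- epi_params(kappa0 = 2, beta = 0.3, rho_IR = 0.25, rho_ID = 0.005,
                  contact_mode = "constant")
  R0 <- basic_reproduction_number(p)
  expect_equal(effective_reproduction_number(epi_state(S = 1000, I = 0), p), R0)
  expect_equal(effective_reproduction_number(epi_state(S = 500, I = 0, R = 500), p),
               R0 / 2)
  # adaptive mode: at prevalence P_kappa the instantaneous kappa is kappa0/2
  pa <- epi_params(kappa0 = 2, beta = 0.3, rho_IR = 0.25, P_kappa = 0.1,
                   sigma_kappa = 4)
  st <- epi_state(S = 900, I = 100)
  expect_equal(effective_reproduction_number(st, pa),
               basic_reproduction_number(pa) / 2 * 0.9, tolerance = 1e-12)
  expect_error(effective_reproduction_number(epi_state(S = 0, I = 0), p),
               "degenerate")
})

test_that("per-contact infection probability has the exponential form", {
  expect_identical(probability_of_infection(2, 0.3, 0), 0)
  expect_equal(probability_of_infection(2, 0.3, 1), 1 - exp(-0.6),
               tolerance = 1e-12)
  expect_equal(probability_of_infection(2, 0.3, 1), 0.451188, tolerance = 1e-5)
  expect_equal(probability_of_infection(2, 0.3, 0.001), 0.0006,
               tolerance = 1e-3)
  expect_error(probability_of_infection(-1, 0.3, 1), "invalid")
})

test_that("branching outbreak probability is clamped below threshold and increasing above", {
  expect_identical(outbreak_probability_dh(1), 0)
  expect_identical(outbreak_probability_dh(0.3), 0)
  expect_equal(outbreak_probability_dh(2), 0.5)
  expect_equal(outbreak_probability_dh(4), 0.75)
  r0s <- c(0.2, 0.9, 1, 1.5, 2, 4, 10, 100)
  pv <- outbreak_probability_dh(r0s)
  expect_true(all(pv >= 0 & pv < 1))
  expect_true(all(diff(pv[r0s > 1]) > 0))
  expect_error(outbreak_probability_dh(0), "invalid")
  expect_error(outbreak_probability_dh(-2), "invalid")
})

test_that("mean waiting time is the inverse total exit rate", {
  expect_equal(round(mean_waiting_time(0.03), 1), 33.3)
  expect_equal(mean_waiting_time(0.25), 4)
  expect_equal(mean_waiting_time(c(0.25, 0.25)), 2)
  expect_identical(mean_waiting_time(c(0, 0)), Inf)
  expect_error(mean_waiting_time(-0.1), "invalid")
})

test_that("parameter validation rejects each invariant violation by name", {
  expect_error(epi_params(rho_IR = -0.1), "rho_IR")
  expect_error(epi_params(P_kappa = 0), "P_kappa")
  expect_error(epi_params(sigma_kappa = -1), "sigma_kappa")
  expect_error(epi_params(N0 = 1.5), "N0")
  expect_error(epi_params(N0 = 1), "N0")
  expect_error(epi_params(t_fnl = 0), "t_fnl")
  expect_error(epi_params(t_V_on = 200, t_fnl = 100), "t_V_on")
  expect_error(epi_params(contact_mode = "custom"), "contact_fn")
  expect_error(epi_state(S = -1, I = 0), "invalid state")
})
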