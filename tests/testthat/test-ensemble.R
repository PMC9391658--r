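test_that("parameter sweeps vary one field and reproduce the single-run case", {
  p <- epi_params(kappa0 = 2, contact_mode = "constant", N0 = 1e4,
                  t_fnl = 80)
  runs <- sweep_parameter(p, "kappa0", c(2, 2.5, 3, 3.5, 4, 4.5), dt = 0.25)
  expect_named(runs, paste0("kappa0=", c(2, 2.5, 3, 3.5, 4, 4.5)))
  peaks <- vapply(runs, function(tr) max(prevalence(tr)), numeric(1))
  expect_true(all(diff(peaks) > 0))
  single <- sweep_parameter(p, "kappa0", 2, dt = 0.25)[[1]]
  direct <- simulate_deterministic(p, dt = 0.25)
  expect_identical(as.data.frame(single), as.data.frame(direct))
  expect_error(sweep_parameter(p, "nonsense", 1:2), "unknown parameter")
  # stochastic sweeps are reproducible through derived seeds
  ps <- epi_params(N0 = 1000, t_fnl = 40, contact_mode = "constant")
  s1 <- sweep_parameter(ps, "beta", c(0.2, 0.4), engine = "stochastic",
                        seed = 9)
  s2 <- sweep_parameter(ps, "beta", c(0.2, 0.4), engine = "stochastic",
                        seed = 9)
  expect_identical(lapply(s1, as.data.frame), lapply(s2, as.data.frame))
})

test_that("outbreak classification separates stuttering chains from epidemics", {
  p <- epi_params(beta = 0, N0 = 1000, t_fnl = 30)
  tiny <- simulate_stochastic(p, init = epi_state(S = 997, I = 3), seed = 4)
  expect_equal(classify_outbreak(tiny), "minor")
  expect_lte(outbreak_duration(tiny), 30)
  pb <- epi_params(kappa0 = 2, beta = 0.5, contact_mode = "constant",
                   N0 = 1000, t_fnl = 200)
  big <- simulate_stochastic(pb, seed = 1205)
  expect_gt(sum(big$incidence), 800)  # >80% of N0 infected
  expect_equal(classify_outbreak(big), "major")
  det <- simulate_deterministic(epi_params(t_fnl = 10), dt = 0.5)
  expect_error(classify_outbreak(det), "not applicable")
  expect_error(outbreak_duration(det), "not applicable")
})

test_that("ensembles classify, record durations, and reproduce under a base seed", {
  p <- epi_params(kappa0 = 2, beta = 0.5, contact_mode = "constant",
                  N0 = 1000, t_fnl = 150)
  ens <- simulate_ensemble(p, 40, seed = 17)
  expect_length(ens$trajectories, 40)
  expect_equal(sum(ens$classifications == "major") +
                 sum(ens$classifications == "minor"), 40)
  expect_true(all(ens$durations <= 150))
  expect_true(any(ens$classifications == "minor"))
  expect_true(any(ens$classifications == "major"))
  ens2 <- simulate_ensemble(p, 40, seed = 17)
  expect_identical(ens$classifications, ens2$classifications)
  expect_identical(ens$durations, ens2$durations)
  expect_output(print(ens), "major")
})

test_that("ensemble summaries average the requested subset only", {
  p <- epi_params(kappa0 = 2, beta = 0.5, contact_mode = "constant",
                  N0 = 1000, t_fnl = 150)
  ens <- simulate_ensemble(p, 40, seed = 17)
  all_s <- ensemble_summary(ens, "I", "all")
  maj_s <- ensemble_summary(ens, "I", "major")
  expect_equal(all_s$n[1], 40)
  expect_equal(maj_s$n[1], sum(ens$classifications == "major"))
  # minor runs dilute the peak of the all-runs average
  expect_lt(max(all_s$mean), max(maj_s$mean))
  # identical runs have zero spread
  twin <- ens
  twin$trajectories <- ens$trajectories[c(1, 1)]
  twin$classifications <- ens$classifications[c(1, 1)]
  sm <- ensemble_summary(twin, "I", "all")
  expect_true(all(sm$sd == 0))
  none <- ens
  none$classifications <- rep("major", 40)
  expect_error(ensemble_summary(none, "I", "minor"), "empty selection")
})

test_that("empirical outbreak probability exceeds the 1 - 1/R0 estimate and matches the chain-binomial branching oracle", {
  p <- epi_params(kappa0 = 2, beta = 0.5, rho_IR = 0.25,
                  contact_mode = "constant", N0 = 10000, t_fnl = 365)
  est <- estimate_outbreak_probability(p, 300, seed = 2)
  expect_equal(est$p_dh, 0.75)
  expect_gt(est$ci[1], est$p_dh)
  oracle <- branching_outbreak_oracle(kappa_beta = 1, rho_exit = 0.25)
  expect_gt(oracle, est$ci[1])
  expect_lt(oracle, est$ci[2])
  # no transmission, no outbreaks
  p0 <- epi_params(beta = 0, N0 = 1000, t_fnl = 50)
  expect_equal(estimate_outbreak_probability(p0, 20, seed = 1)$estimate, 0)
})

test_that("outbreak probability estimates rise with R0", {
  ests <- vapply(c(1.5, 3, 6), function(R0) {
    p <- epi_params(kappa0 = 2, beta = R0 * 0.125, rho_IR = 0.25,
                    contact_mode = "constant", N0 = 2000, t_fnl = 365)
    estimate_outbreak_probability(p, 150, seed = 7)$estimate
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("outbreak durations at R0 near 3 are bimodal across minor and major runs", {
  p <- epi_params(kappa0 = 2, beta = 0.375, rho_IR = 0.25,
                  contact_mode = "constant", N0 = 1000, t_fnl = 250)
  ens <- simulate_ensemble(p, 200, seed = 23, early_stop = TRUE)
  minor <- ens$durations[ens$classifications == "minor"]
  major <- ens$durations[ens$classifications == "major"]
  expect_gt(length(minor), 20)
  expect_gt(length(major), 100)
  # Ashman-style separation of the two duration modes
  D <- abs(mean(major) - mean(minor)) /
    sqrt((var(major) + var(minor)) / 2)
  expect_gt(D, 2)
})

test_that("final-size oracle solves the implicit equation and matches the engine", {
  expect_identical(final_size_oracle(0.8), 1)
  expect_identical(final_size_oracle(1), 1)
  for (R0 in c(1.2, 2, 2.353, 4)) {
    s <- final_size_oracle(R0)
    expect_equal(s, exp(-R0 * (1 - s)), tolerance = 1e-9)
    expect_equal(s, final_size_uniroot(R0), tolerance = 1e-8)
  }
  expect_equal(final_size_oracle(2), 0.2032, tolerance = 1e-4)
  expect_error(final_size_oracle(0), "invalid")
  p <- epi_params(kappa0 = 2, beta = 0.3, rho_IR = 0.25,
                  contact_mode = "constant", N0 = 1e5, t_fnl = 400)
  tr <- simulate_deterministic(p, dt = 0.1)
  n <- nrow(tr)
  expect_equal(tr$S[n] / (tr$S[n] + tr$I[n] + tr$R[n]),
               final_size_oracle(2.4), tolerance = 1e-3)
})
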