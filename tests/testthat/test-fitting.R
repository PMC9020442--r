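# The 3-step fitting protocol: round trips, constraints, diagnostics.

test_that("population fit recovers the gas-phase parameters exactly", {
  truth <- pathway_model(c(0.16, 0.84), c(0.013, 0.688))
  t <- seq(0, 1, 0.01)
  pop <- time_series(t, ground_state_population(t, truth), "population")
  res <- fit_population(pop, 2)
  expect_true(res$fit$converged)
  expect_equal(res$model$weights, c(0.16, 0.84), tolerance = 1e-4)
  expect_equal(res$model$time_constants, c(0.013, 0.688), tolerance = 1e-4)
  # pathways come back sorted by ascending time constant
  expect_true(!is.unsorted(res$model$time_constants))
  expect_lt(res$fit$residual_rms, 1e-7)
})

test_that("population fit tolerates ensemble noise", {
  truth <- pathway_model(c(0.3, 0.7), c(0.05, 0.8))
  t <- seq(0, 1.5, length.out = 150)
  set.seed(1)
  y <- ground_state_population(t, truth) + stats::rnorm(150, sd = 0.02)
  pop <- time_series(t, pmin(pmax(y, -0.05), 1.05), "population")
  res <- fit_population(pop, 2)
  expect_rel_error(res$model$time_constants[2], 0.8, 0.15)
})

test_that("flat population series is flagged degenerate", {
  t <- seq(0, 1, 0.02)
  pop <- time_series(t, rep(0, length(t)), "population")
  res <- fit_population(pop, 2, sum_to_one = FALSE)
  expect_true(all(res$model$weights < 1e-6) || !res$fit$converged)
  expect_false(res$fit$converged && all(res$model$weights > 0.01))
})

test_that("population fit refuses too-few points and bad windows", {
  t <- seq(0, 1, 0.5)  # 3 points < 2 * n_pathways + 1
  pop <- time_series(t, ground_state_population(
    t, pathway_model(1, 0.3)), "population")
  expect_error(fit_population(pop, 2), "at least")
  expect_error(fit_population(pop, 1, window = c(2, 1)), "window")
})

test_that("solvent amplitude is fixed by the analytic constraint", {
  fx <- argon_fixture()
  t <- seq(0, 3, 0.01)
  es <- time_series(t, solvent_energy(t, fx$solvent), "energy")
  res <- fit_solvent(es, fx$system, 1)
  # kappa_1 = E0_s - E_inf_s regardless of the data
  expect_equal(res$model$channel_weights, -2.576, tolerance = 1e-3)
  expect_equal(res$fit$parameters[["e_inf_solvent"]], 3.46604,
               tolerance = 1e-5)
  expect_rel_error(res$model$channel_times, 15.49, 1e-3)
})

test_that("solvent fit recovers the water time constant to 3 s.f.", {
  fx <- water_fixture()
  t <- seq(0, 1.5, 0.005)
  es <- time_series(t, solvent_energy(t, fx$solvent), "energy")
  res <- fit_solvent(es, fx$system, 1)
  expect_true(res$fit$converged)
  expect_rel_error(res$model$channel_times, 0.15, 5e-4)
})

test_that("zero-amplitude solvent channel is flagged unidentifiable", {
  sys <- system_spec(13, 684, 0, 1.46, 0.89)  # no photon: E_inf_s = E0_s
  t <- seq(0, 3, 0.05)
  es <- time_series(t, rep(0.89, length(t)), "energy")
  res <- fit_solvent(es, sys, 1)
  expect_false(res$fit$converged)
  expect_true("tau_s_1" %in% res$fit$weakly_identified)
})

test_that("chromophore fit recovers tau_C far beyond the window", {
  # the argon case: tau_C = 24.9 ps from a 3 ps window, leaning on the
  # analytic boundary conditions
  fx <- argon_fixture()
  t <- seq(0, 3, 0.005)
  ec <- time_series(t, chromophore_energy(t, fx$chromophore, fx$pathways,
                                          fx$solvent), "energy")
  res <- fit_chromophore(ec, fx$pathways, fx$solvent, fx$system)
  expect_true(res$fit$converged)
  expect_rel_error(res$model$cooling_time, 24.9, 0.10)
})

test_that("chromophore fit handles noise and the pinned-zero amplitude", {
  fx <- water_fixture()  # truth has kappa_2 = 0 (published A_2 = 0 case)
  t <- seq(0, 1.5, 0.005)
  set.seed(7)
  y <- chromophore_energy(t, fx$chromophore, fx$pathways, fx$solvent) +
    stats::rnorm(length(t), sd = 0.05)
  ec <- time_series(t, y, "energy")
  res <- fit_chromophore(ec, fx$pathways, fx$solvent, fx$system)
  expect_rel_error(res$model$cooling_time, 1.3, 0.20)
  expect_true(all(res$model$heating_amplitudes >= 0))
})

test_that("flat chromophore series is flagged unidentifiable", {
  fx <- water_fixture()
  sys0 <- system_spec(13, 900, 0, 1.43, 34.66)  # no photon energy
  t <- seq(0, 1.5, 0.01)
  ec <- time_series(t, rep(1.43, length(t)), "energy")
  res <- fit_chromophore(ec, fx$pathways, fx$solvent, sys0)
  expect_false(res$fit$converged)
})

test_that("noiseless round trip recovers all free parameters (randomized)", {
  # scaled down from 50 to 12 randomized sets for runtime; see vignette
  set.seed(23)
  for (i in 1:12) {
    fx <- random_setup()
    t <- seq(0, 3, 0.01)
    pop <- time_series(t, ground_state_population(t, fx$pathways),
                       "population")
    es <- time_series(t, solvent_energy(t, fx$solvent), "energy")
    cm <- chromophore_model(fx$heating, fx$cooling, fx$pathways,
                            fx$solvent, fx$system)
    ec <- time_series(t, chromophore_energy(t, cm, fx$pathways, fx$solvent),
                      "energy")
    r1 <- fit_population(pop, 2)
    r2 <- fit_solvent(es, fx$system, 1)
    r3 <- fit_chromophore(ec, r1$model, r2$model, fx$system)
    expect_equal(r1$model$weights, fx$pathways$weights, tolerance = 1e-3)
    expect_equal(r1$model$time_constants, fx$pathways$time_constants,
                 tolerance = 1e-3)
    expect_equal(r2$model$channel_times, fx$solvent$channel_times,
                 tolerance = 1e-3)
    expect_equal(r3$model$cooling_time, fx$cooling, tolerance = 1e-3)
    expect_equal(r3$model$heating_amplitudes, fx$heating, tolerance = 1e-3)
    # constraint preservation, machine-checked post-fit
    eq <- equilibrium_energies(fx$system)
    expect_equal(sum(r2$model$channel_weights),
                 fx$system$e0_solvent - eq[["e_inf_solvent"]],
                 tolerance = 1e-9)
    expect_true(all(r3$model$heating_amplitudes >= 0))
    expect_gt(r3$model$cooling_time, 0)
  }
})

test_that("tau_C recovery error grows with noise level", {
  fx <- water_fixture()
  t <- seq(0, 1.5, 0.01)
  clean <- chromophore_energy(t, fx$chromophore, fx$pathways, fx$solvent)
  errs <- sapply(c(0.01, 0.05, 0.1), function(sigma) {
    per_seed <- sapply(1:20, function(s) {
      set.seed(1000 + s)
      ec <- time_series(t, clean + stats::rnorm(length(t), sd = sigma),
                        "energy")
      res <- fit_chromophore(ec, fx$pathways, fx$solvent, fx$system)
      abs(res$model$cooling_time - 1.3) / 1.3
    })
    mean(per_seed)
  })
  expect_true(all(diff(errs) > 0))
})

test_that("run_protocol chains the stages and reports derived times", {
  fx <- water_fixture()
  t <- seq(0, 1.5, 0.01)
  pop <- time_series(t, ground_state_population(t, fx$pathways),
                     "population")
  es <- time_series(t, solvent_energy(t, fx$solvent), "energy")
  ec <- time_series(t, chromophore_energy(t, fx$chromophore, fx$pathways,
                                          fx$solvent), "energy")
  rep <- run_protocol(pop, ec, es, fx$system)
  expect_s3_class(rep, "protocol_report")
  expect_equal(rep$tau_h, mean_lifetime(fx$pathways), tolerance = 1e-3)
  expect_equal(rep$tau_c, 1.3, tolerance = 1e-3)
  # in water the kinetic-energy peak precedes the mean excited-state
  # lifetime: cooling starts while still photoexcited
  expect_lt(rep$peak_time, rep$tau_h)
  # stage failures carry the stage identity
  bad <- time_series(c(0, 1), c(0, 0.1), "population")
  expect_error(run_protocol(bad, ec, es, fx$system), "step 1")
})
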