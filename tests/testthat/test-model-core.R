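# Closed-form evaluators and coefficient algebra.

test_that("ground-state population evaluates the pathway kinetics", {
  gas <- pathway_model(c(0.16, 0.84), c(0.013, 0.688))
  expect_identical(ground_state_population(0, gas), 0)
  expect_equal(ground_state_population(1e4, gas), 1.00, tolerance = 1e-10)
  # direct scalar arithmetic oracle at t = 0.688 ps
  direct <- 0.16 * (1 - exp(-0.688 / 0.013)) + 0.84 * (1 - exp(-1))
  expect_equal(ground_state_population(0.688, gas), direct,
               tolerance = 1e-12)
  expect_error(ground_state_population(-0.1, gas), "non-negative")
  # nondecreasing and bounded by sum(a) for incomplete decay
  part <- pathway_model(c(0.2, 0.5), c(0.05, 0.7))
  p <- ground_state_population(seq(0, 10, 0.01), part)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p <= 0.7 + 1e-12))
})

test_that("population rates are the exact pathway derivatives", {
  one <- pathway_model(1, 2)
  expect_equal(population_rate(0, one), 0.5)
  # integral of each dp_i/dt over [0, Inf) is a_i
  two <- pathway_model(c(0.3, 0.6), c(0.05, 0.8))
  for (i in 1:2) {
    got <- stats::integrate(function(t) population_rate(t, two)[, i],
                            0, Inf, rel.tol = 1e-10)$value
    expect_equal(got, two$weights[i], tolerance = 1e-8)
  }
  # finite differences of the population match the summed rates
  t <- seq(0.01, 3, 1e-4)
  fd <- diff(ground_state_population(t, two)) / diff(t)
  mid <- (t[-1] + t[-length(t)]) / 2
  expect_lt(max(abs(fd - rowSums(population_rate(mid, two)))), 1e-6)
  expect_true(all(population_rate(c(0, 1, 5), two) >= 0))
})

test_that("solvent energy reproduces the argon channel values", {
  ar <- solvent_model(3.466, -2.576, 15.49)
  expect_equal(solvent_energy(0, ar), 0.89, tolerance = 1e-12)
  expect_equal(round(solvent_energy(1e4, ar), 2), 3.47)
  # at t = tau the channel has decayed by exactly 1/e
  expect_equal(solvent_energy(15.49, ar), 3.466 - 2.576 / exp(1),
               tolerance = 1e-12)
})

test_that("virial partition fixes the equilibrium energies", {
  argon <- system_spec(13, 684, 5.25, 1.46, 0.89)
  eq <- equilibrium_energies(argon)
  expect_equal(unname(eq), c(1.50896, 3.46604), tolerance = 1e-6)
  water <- system_spec(13, 900, 5.25, 1.43, 34.66)
  eqw <- equilibrium_energies(water)
  expect_equal(round(unname(eqw), 2), c(1.47, 37.25))
  # no photon, no excess energy
  cold <- system_spec(13, 684, 0, 1.46, 0.89)
  expect_equal(unname(equilibrium_energies(cold)), c(1.46, 0.89))
})

test_that("energy-budget identity holds for randomized systems", {
  set.seed(11)
  for (i in 1:200) {
    sys <- system_spec(sample(1:40, 1), sample(1:3000, 1),
                       stats::runif(1, 0, 8), stats::runif(1, 0, 3),
                       stats::runif(1, 0, 100))
    eq <- equilibrium_energies(sys)
    gain <- (eq[["e_inf_chromophore"]] - sys$e0_chromophore) +
      (eq[["e_inf_solvent"]] - sys$e0_solvent)
    expect_equal(gain, sys$photon_energy / 2, tolerance = 1e-13)
  }
})

test_that("coefficients A, B, C follow the closed-form algebra", {
  fx <- water_fixture()
  # zero heating amplitude on pathway 2 kills A_2 (the published water case)
  a_cf <- coefficients_A(fx$pathways, c(5.028, 0), 1.3)
  expect_identical(a_cf[2], 0)
  expect_true(all(coefficients_A(fx$pathways, c(0, 0), 1.3) == 0))
  # algebraic inversion oracle: recover kappa from the printed argon A_1
  a1 <- -0.97; w1 <- 0.16; tc1 <- 0.0070; tauC <- 24.9
  kappa1 <- a1 * (tc1 - tauC) / (w1 * tauC)
  ar <- argon_fixture()
  back <- coefficients_A(ar$pathways, c(kappa1, 1), tauC)[1]
  expect_equal(back, a1, tolerance = 1e-12)
  # A_i < 0 whenever kappa > 0 and tau_i < tau_C
  expect_true(all(coefficients_A(ar$pathways, c(1, 1), tauC) < 0))

  # B_1 for argon and water against the printed 2-3 d.p. values
  b_ar <- coefficients_B(solvent_model(3.466, -2.576, 15.49),
                         ar$system, 24.9)
  expect_equal(round(as.numeric(b_ar), 2), 0.08)
  b_w <- coefficients_B(solvent_model(37.25, -2.59, 0.15),
                        fx$system, 1.3)
  expect_equal(round(as.numeric(b_w), 3), 0.005)
  zero <- coefficients_B(solvent_model(3.466, 0, 15.49), ar$system, 24.9)
  expect_identical(as.numeric(zero), 0)

  # C from the printed argon column, and the water cross-check
  expect_equal(coefficient_C(ar$system, 1.50, c(-0.97, -1.55), 0.08), 2.40,
               tolerance = 1e-12)
  expect_equal(coefficient_C(fx$system, 1.47, c(-1.72, 0), 0.005), 1.675,
               tolerance = 1e-12)
  flat <- system_spec(13, 684, 0, 1.46, 0.89)
  expect_equal(coefficient_C(flat, 1.46, c(0, 0), 0), 0)
})

test_that("closed-form energy honours its boundaries (randomized)", {
  set.seed(7)
  for (i in 1:300) {
    fx <- random_setup()
    cm <- chromophore_model(fx$heating, fx$cooling, fx$pathways,
                            fx$solvent, fx$system)
    e0 <- chromophore_energy(0, cm, fx$pathways, fx$solvent)
    expect_equal(e0, fx$system$e0_chromophore, tolerance = 1e-9)
    einf <- chromophore_energy(5e4, cm, fx$pathways, fx$solvent)
    expect_equal(einf, cm$e_inf_chromophore, tolerance = 1e-7)
  }
})

test_that("closed form matches term-by-term summation", {
  pm <- printed_argon_model()
  t <- seq(0, 50, length.out = 1000)
  cm <- pm$chromophore
  manual <- 1.50 +
    (-0.97) * exp(-t / 0.0070) + (-1.55) * exp(-t / 0.760) +
    0.08 * exp(-t / 15.49) + 2.40 * exp(-t / 24.9)
  got <- chromophore_energy(t, cm, pm$pathways, pm$solvent)
  expect_lt(max(abs(got - manual)), 1e-12)
  # asymptote: at 10 tau_C the argon model sits on E_inf_c
  expect_lt(abs(chromophore_energy(249, cm, pm$pathways, pm$solvent) - 1.50),
            0.01)
})

test_that("confluent time constants collapse to the analytic limit", {
  sys <- system_spec(13, 684, 5.25, 1.46, 0.89)
  eq <- equilibrium_energies(sys)
  pw <- pathway_model(c(0.3, 0.7), c(0.05, 2.0))  # tau_2 == tau_C below
  sv <- solvent_model(eq[["e_inf_solvent"]],
                      sys$e0_solvent - eq[["e_inf_solvent"]], 5)
  cm <- chromophore_model(c(2, 1), 2.0, pw, sv, sys)
  expect_true(cm$confluent_a[2])
  t <- seq(0, 10, 0.01)
  e_conf <- chromophore_energy(t, cm, pw, sv)
  expect_true(all(is.finite(e_conf)))
  # perturbing tau_C off the collision reproduces the limit continuously
  cm_eps <- chromophore_model(c(2, 1), 2.0 * (1 + 1e-5), pw, sv, sys)
  e_eps <- chromophore_energy(t, cm_eps, pw, sv)
  expect_lt(max(abs(e_conf - e_eps)), 1e-3)
  expect_equal(chromophore_energy(0, cm, pw, sv), 1.46, tolerance = 1e-9)
})

test_that("mean lifetime reproduces the published heating times", {
  cols <- list(
    list(a = c(0.16, 0.84), tau = c(0.013, 0.688), th = 0.58),
    list(a = c(0.16, 0.84), tau = c(0.0070, 0.760), th = 0.64),
    list(a = c(0.24, 0.76), tau = c(0.024, 0.651), th = 0.50),
    list(a = c(0.33, 0.67), tau = c(0.046, 0.903), th = 0.62))
  for (col in cols) {
    expect_equal(round(mean_lifetime(pathway_model(col$a, col$tau)), 2),
                 col$th)
  }
  expect_equal(mean_lifetime(pathway_model(1, 0.37)), 0.37)
  expect_error(pathway_model(numeric(), numeric()), "at least one")
})

test_that("peak time finds the transient heating/cooling equilibrium", {
  pw <- printed_water_model()
  tp_w <- peak_time(pw$chromophore, pw$pathways, pw$solvent)
  expect_equal(round(tp_w, 2), 0.16)
  pa <- printed_argon_model()
  tp_a <- peak_time(pa$chromophore, pa$pathways, pa$solvent)
  # dense-grid argmax oracle
  t <- seq(1e-4, 30, 1e-4)
  oracle <- t[which.max(chromophore_energy(t, pa$chromophore, pa$pathways,
                                           pa$solvent))]
  expect_equal(tp_a, oracle, tolerance = 1e-3)
  expect_lt(abs(tp_a - 2.38), 0.05)

  # pure cooling (no heating, negligible back transfer) is monotone: none
  sys <- system_spec(13, 10000, 2, 2.0, 10)
  eq <- equilibrium_energies(sys)
  pwm <- pathway_model(c(0.2, 0.8), c(0.05, 0.7))
  sv <- solvent_model(eq[["e_inf_solvent"]],
                      sys$e0_solvent - eq[["e_inf_solvent"]], 5)
  cool <- chromophore_model(c(0, 0), 3, pwm, sv, sys)
  expect_true(is.na(peak_time(cool, pwm, sv)))
})

test_that("analytic derivative matches central finite differences", {
  fx <- argon_fixture()
  t <- seq(0.05, 20, 0.05)
  h <- 1e-5
  fd <- (chromophore_energy(t + h, fx$chromophore, fx$pathways, fx$solvent) -
         chromophore_energy(t - h, fx$chromophore, fx$pathways,
                            fx$solvent)) / (2 * h)
  an <- chromophore_energy_rate(t, fx$chromophore, fx$pathways, fx$solvent)
  expect_lt(max(abs(fd - an)), 1e-6)
})

test_that("no-cooling limit reduces to pure internal-conversion heating", {
  fx <- water_fixture()
  cm <- chromophore_model(fx$heating, 1e6, fx$pathways, fx$solvent,
                          fx$system)
  t <- seq(0, 10, 0.01)
  got <- chromophore_energy(t, cm, fx$pathways, fx$solvent)
  pure <- fx$system$e0_chromophore +
    as.vector((1 - exp(-outer(t, 1 / fx$pathways$time_constants))) %*%
                (fx$heating * fx$pathways$weights))
  expect_lt(max(abs(got - pure)), 1e-3)
})

test_that("type validators reject malformed inputs", {
  expect_error(system_spec(0, 684, 5.25, 1.46, 0.89), "integer >= 1")
  expect_error(pathway_model(c(0.5, 0.7), c(0.1, 1)), "sum to <= 1")
  expect_error(pathway_model(0.5, -1), "positive")
  expect_error(solvent_model(3.46, -2.576, 15.49, e0_solvent = 5),
               "must equal")
  expect_error(time_series(c(0, 1, 1), c(0, 0.5, 0.6), "population"),
               "strictly increasing")
  expect_error(time_series(c(0, 1), c(0, 1.2), "population"), "within")
  expect_error(chromophore_model(c(-1, 1), 2, water_fixture()$pathways,
                                 water_fixture()$solvent,
                                 water_fixture()$system), ">= 0")
})
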