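# Forward simulation and synthetic ensembles.
#
# integrate_forward() is the package's independent numerical oracle: it
# integrates the driven-cooling ODE with a classical fixed-step 4th-order
# scheme and must agree with the closed form to tight tolerance.
# generate_ensemble() emulates the statistical shape of surface-hopping
# ensemble observables (stochastic hop times, indicator populations,
# per-trajectory energy curves) so the fitting protocol can be validated
# without any real trajectory data.

#' Synthetic ensemble specification
#'
#' @param n_trajectories Number of trajectories (>= 1).
#' @param time_grid Strictly increasing sampling grid in ps, starting at 0.
#' @param noise_sd_energy I.i.d. Gaussian noise added per grid point to the
#'   ensemble-mean energies, in eV (>= 0).
#' @param noise_sd_population Same, for the population fraction (>= 0).
#' @param seed Master RNG seed (integer). Per-trajectory substreams are
#'   derived from it by counter, so enlarging the ensemble does not
#'   reshuffle earlier trajectories.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_trajectories, time_grid, noise_sd_energy = 0,
                          noise_sd_population = 0, seed = 1L) {
  if (!is.numeric(n_trajectories) || n_trajectories < 1) {
    stop("n_trajectories must be >= 1", call. = FALSE)
  }
  if (any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing", call. = FALSE)
  }
  if (noise_sd_energy < 0 || noise_sd_population < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(
    list(n_trajectories = as.integer(n_trajectories),
         time_grid = as.numeric(time_grid),
         noise_sd_energy = as.numeric(noise_sd_energy),
         noise_sd_population = as.numeric(noise_sd_population),
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' Numerically integrate the driven-cooling equation
#'
#' Integrates
#' `dE_c/dt = sum_i kappa_i dp_i/dt
#'  - (1/tau_C) [E_c - E_inf_c - (N_c/N_s)(E_s(t) - E_inf_s)]`
#' with a classical 4-stage fixed-step scheme from E_c(0) = E0_c. This
#' "anchored" form relaxes towards the virial-partition equilibrium and its
#' exact solution is the closed form evaluated by [chromophore_energy()];
#' the integrator exists as an independent oracle for that closed form.
#'
#' `form = "literal"` instead uses the bare thermal-contact term
#' `-(1/tau_C) [E_c - (N_c/N_s) E_s(t)]`, which drives E_c to the much
#' lower per-atom solvent energy; it is kept available for comparison but
#' does not reproduce the published parameter tables.
#'
#' @param system A [system_spec()].
#' @param pathways A [pathway_model()].
#' @param heating_amplitudes kappa_i in eV, one per pathway, >= 0.
#' @param cooling_time tau_C in ps.
#' @param solvent A [solvent_model()].
#' @param grid Output time grid in ps, starting at 0, strictly increasing.
#' @param dt Integration substep in ps; default `min(all time constants)/20`.
#'   A user-supplied step coarser than `min(tau)/5` is accepted but flagged
#'   in the result's `"coarse_step"` attribute.
#' @param form `"anchored"` (default) or `"literal"`, see above.
#' @return An energy [time_series()] on `grid`, with attribute
#'   `"coarse_step"` = TRUE when the step-size warning fired.
#' @export
integrate_forward <- function(system, pathways, heating_amplitudes,
                              cooling_time, solvent, grid, dt = NULL,
                              form = c("anchored", "literal")) {
  form <- match.arg(form)
  stopifnot(inherits(system, "system_spec"),
            inherits(pathways, "pathway_model"),
            inherits(solvent, "solvent_model"))
  .check_scalar(cooling_time, "cooling_time", lower = 0, strict = TRUE)
  if (grid[1L] != 0) {
    stop("integration grid must start at t = 0", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("integration grid must be strictly increasing", call. = FALSE)
  }
  taus <- c(pathways$time_constants, solvent$channel_times, cooling_time)
  if (is.null(dt)) dt <- min(taus) / 20
  coarse <- dt > min(taus) / 5
  if (coarse) {
    warning(sprintf(
      "integration step %.3g ps is coarser than min(tau)/5 = %.3g ps",
      dt, min(taus) / 5), call. = FALSE)
  }

  eq <- equilibrium_energies(system)
  ratio <- system$n_chromophore_atoms / system$n_solvent_atoms
  a <- pathways$weights
  tau_p <- pathways$time_constants
  kap <- heating_amplitudes
  heat <- function(tt) sum(kap * a / tau_p * exp(-tt / tau_p))
  cool <- if (form == "anchored") {
    function(tt, e) {
      -(e - eq[["e_inf_chromophore"]] -
          ratio * (solvent_energy(tt, solvent) - eq[["e_inf_solvent"]])) /
        cooling_time
    }
  } else {
    function(tt, e) {
      -(e - ratio * solvent_energy(tt, solvent)) / cooling_time
    }
  }
  f <- function(tt, e) heat(tt) + cool(tt, e)

  out <- numeric(length(grid))
  e <- system$e0_chromophore
  out[1L] <- e
  for (i in seq_len(length(grid) - 1L)) {
    t0 <- grid[i]
    t1 <- grid[i + 1L]
    nsub <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / nsub
    tt <- t0
    for (s in seq_len(nsub)) {
      k1 <- f(tt, e)
      k2 <- f(tt + h / 2, e + h / 2 * k1)
      k3 <- f(tt + h / 2, e + h / 2 * k2)
      k4 <- f(tt + h, e + h * k3)
      e <- e + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + h
    }
    out[i + 1L] <- e
  }
  res <- time_series(grid, out, kind = "energy")
  attr(res, "coarse_step") <- coarse
  res
}

#' Generate a synthetic surface-hopping ensemble
#'
#' Emulates ensemble-averaged observables with the model's stochastic
#' structure. Per trajectory k: a decay pathway is drawn with probability
#' a_i (any weight deficit 1 - sum(a_i) leaves the trajectory excited
#' forever), a hop time is drawn from Exponential(mean tau_i), the
#' ground-state indicator is 1\[t >= t_k\], and the energy curve is the
#' closed-form solution of the cooling equation conditioned on that hop
#' time (cooling acts from t = 0; the internal-conversion heat kappa_i is
#' deposited at the hop). The ensemble mean of these curves equals the
#' closed-form E_c(t) exactly, which is what makes the generator a valid
#' oracle for the fitting protocol. I.i.d. Gaussian noise is then added
#' per grid point, and standard errors of the ensemble means are stored.
#'
#' @inheritParams integrate_forward
#' @param ens An [ensemble_spec()].
#' @return `list(pop = , e_chromo = , e_solv = )` of [time_series()].
#' @export
generate_ensemble <- function(system, pathways, heating_amplitudes,
                              cooling_time, solvent, ens) {
  stopifnot(inherits(ens, "ensemble_spec"))
  grid <- ens$time_grid
  n <- ens$n_trajectories
  np <- pathways$n_pathways
  a <- pathways$weights
  tau_p <- pathways$time_constants
  # base curve: cooling-only conditional solution (kappa = 0 closed form)
  base_model <- chromophore_model(
    heating_amplitudes = rep(0, np), cooling_time = cooling_time,
    pathways = pathways, solvent = solvent, system = system)
  base <- chromophore_energy(grid, base_model, pathways, solvent)

  pop_sum <- numeric(length(grid)); pop_sq <- numeric(length(grid))
  ec_sum <- numeric(length(grid));  ec_sq <- numeric(length(grid))
  for (k in seq_len(n)) {
    set.seed(.traj_seed(ens$seed, k))
    u <- stats::runif(1L)
    edges <- cumsum(a)
    path <- findInterval(u, c(0, edges), left.open = TRUE)
    if (path > np) {       # weight deficit: trajectory never decays
      t_k <- Inf
      jump <- 0
    } else {
      t_k <- stats::rexp(1L, rate = 1 / tau_p[path])
      jump <- heating_amplitudes[path]
    }
    ind <- as.numeric(grid >= t_k)
    ec <- base + jump * ind * exp(-(grid - t_k) / cooling_time)
    pop_sum <- pop_sum + ind; pop_sq <- pop_sq + ind^2
    ec_sum <- ec_sum + ec;    ec_sq <- ec_sq + ec^2
  }
  pop_mean <- pop_sum / n
  ec_mean <- ec_sum / n
  sd_of <- function(s, sq, m) sqrt(pmax(sq / n - m^2, 0) * n / max(n - 1, 1))
  pop_se <- sd_of(pop_sum, pop_sq, pop_mean) / sqrt(n)
  ec_se <- sd_of(ec_sum, ec_sq, ec_mean) / sqrt(n)

  es_mean <- solvent_energy(grid, solvent)
  set.seed(.traj_seed(ens$seed, 0L))  # noise substream
  if (ens$noise_sd_population > 0) {
    pop_mean <- pop_mean + stats::rnorm(length(grid),
                                        sd = ens$noise_sd_population)
    pop_se <- sqrt(pop_se^2 + ens$noise_sd_population^2)
  }
  if (ens$noise_sd_energy > 0) {
    ec_mean <- ec_mean + stats::rnorm(length(grid),
                                      sd = ens$noise_sd_energy)
    es_mean <- es_mean + stats::rnorm(length(grid),
                                      sd = ens$noise_sd_energy)
    ec_se <- sqrt(ec_se^2 + ens$noise_sd_energy^2)
  }
  pop_mean <- pmin(pmax(pop_mean, -0.05), 1.05)  # keep within series band
  list(
    pop = time_series(grid, pop_mean, "population", stderr = pop_se),
    e_chromo = time_series(grid, ec_mean, "energy", stderr = ec_se),
    e_solv = time_series(grid, es_mean, "energy",
                         stderr = if (ens$noise_sd_energy > 0)
                           rep(ens$noise_sd_energy, length(grid)) else NULL)
  )
}

#' Generate-then-refit recovery experiment
#'
#' Generates a synthetic ensemble from a known parameter set, runs the full
#' 3-step protocol on it, and reports the relative recovery error of every
#' free parameter plus the derived heating/cooling times.
#'
#' @inheritParams generate_ensemble
#' @param windows Optional fit windows, passed to [run_protocol()].
#' @return An object of class `recovery_report`: list with the fitted
#'   `report`, the `truth` parameters and a named `rel_errors` vector.
#' @export
recovery_experiment <- function(system, pathways, heating_amplitudes,
                                cooling_time, solvent, ens,
                                windows = NULL) {
  data <- generate_ensemble(system, pathways, heating_amplitudes,
                            cooling_time, solvent, ens)
  report <- run_protocol(data$pop, data$e_chromo, data$e_solv, system,
                         n_pathways = pathways$n_pathways,
                         n_channels = solvent$n_channels,
                         windows = windows)
  np <- pathways$n_pathways
  nd <- solvent$n_channels
  rel <- function(est, truth) {
    ifelse(abs(truth) > 1e-12, abs(est - truth) / abs(truth), abs(est))
  }
  errs <- c(
    stats::setNames(rel(report$pathways$weights, pathways$weights),
                    paste0("a_", seq_len(np))),
    stats::setNames(rel(report$pathways$time_constants,
                        pathways$time_constants),
                    paste0("tau_c_", seq_len(np))),
    stats::setNames(rel(report$solvent$channel_times,
                        solvent$channel_times),
                    paste0("tau_s_", seq_len(nd))),
    stats::setNames(rel(report$chromophore$heating_amplitudes,
                        heating_amplitudes),
                    paste0("kappa_c_", seq_len(np))),
    tau_C = rel(report$tau_c, cooling_time),
    tau_H = rel(report$tau_h, mean_lifetime(pathways))
  )
  structure(
    list(report = report,
         truth = list(pathways = pathways, solvent = solvent,
                      heating_amplitudes = heating_amplitudes,
                      cooling_time = cooling_time),
         rel_errors = errs),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment (relative errors):\n")
  for (nm in names(x$rel_errors)) {
    cat(sprintf("  %-10s %.3g\n", nm, x$rel_errors[[nm]]))
  }
  invisible(x)
}

# deterministic per-trajectory substream; k = 0 is the noise stream
.traj_seed <- function(seed, k) {
  as.integer(((abs(as.numeric(seed)) %% 97777) * 21001 +
                as.numeric(k) * 7919) %% 2147483629) + 1L
}
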