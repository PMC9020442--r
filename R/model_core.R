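# Closed-form evaluators and coefficient algebra for the energy-transfer
# model. Pure computation; fitting and simulation build on these.
#
# Model sketch: photoexcitation deposits h*nu at t = 0; internal conversion
# releases heat into the chromophore with the ground-state filling kinetics,
# while Newton-type cooling (time constant tau_C) drains heat to the solvent:
#   dE_c/dt = sum_i kappa_i dp_i/dt
#             - (1/tau_C) [E_c - E_inf_c - (N_c/N_s)(E_s(t) - E_inf_s)]
# With exponential p_i and E_s the solution is a four-family exponential sum
# whose coefficients are computed here.

# threshold below which two decay rates are treated as equal (confluent)
.CONFLUENT_TOL <- 1e-8

#' Ground-state population of the pathway model
#'
#' Evaluates p_0(t) = sum_i a_i (1 - exp(-t / tau_i)): the fraction of the
#' ensemble that has returned to the electronic ground state by time t.
#'
#' @param t Time(s) in ps, >= 0 (vectorised).
#' @param pathways A [pathway_model()].
#' @return Population fraction(s), same length as `t`; nondecreasing in t
#'   and bounded by `sum(pathways$weights)`.
#' @export
ground_state_population <- function(t, pathways) {
  stopifnot(inherits(pathways, "pathway_model"))
  .check_time(t)
  a <- pathways$weights
  tau <- pathways$time_constants
  as.vector((1 - exp(-outer(t, 1 / tau))) %*% a)
}

#' Per-pathway population transfer rate
#'
#' dp_i/dt = (a_i / tau_i) exp(-t / tau_i); this is the driving term of the
#' chromophore heating, one column per pathway.
#'
#' @param t Time(s) in ps, >= 0.
#' @param pathways A [pathway_model()].
#' @return For scalar `t`, a numeric vector of length `n_pathways`;
#'   otherwise a matrix `[length(t), n_pathways]`. All entries >= 0.
#' @export
population_rate <- function(t, pathways) {
  stopifnot(inherits(pathways, "pathway_model"))
  .check_time(t)
  a <- pathways$weights
  tau <- pathways$time_constants
  out <- outer(t, seq_along(a),
               function(tt, i) (a[i] / tau[i]) * exp(-tt / tau[i]))
  if (length(t) == 1L) drop(out) else out
}

#' Solvent kinetic energy
#'
#' E_s(t) = E_inf_s + sum_n kappa_n exp(-t / tau_n).
#'
#' @param t Time(s) in ps, >= 0.
#' @param solvent A [solvent_model()].
#' @return Energy value(s) in eV.
#' @export
solvent_energy <- function(t, solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  .check_time(t)
  k <- solvent$channel_weights
  tau <- solvent$channel_times
  solvent$e_inf_solvent + as.vector(exp(-outer(t, 1 / tau)) %*% k)
}

#' Equilibrium kinetic energies from the virial partition
#'
#' At t -> infinity chromophore and solvent thermalise and (for harmonic
#' motion) half of the photon energy ends up kinetic, shared per atom:
#' `E_inf_c = E0_c + N_c/(N_c+N_s) * hv/2` and
#' `E_inf_s = E0_s + N_s/(N_c+N_s) * hv/2`.
#' The two kinetic-energy gains always sum to exactly hv/2.
#'
#' @param system A [system_spec()].
#' @return Named numeric vector `c(e_inf_chromophore, e_inf_solvent)` in eV.
#' @export
equilibrium_energies <- function(system) {
  stopifnot(inherits(system, "system_spec"))
  nc <- system$n_chromophore_atoms
  ns <- system$n_solvent_atoms
  half <- system$photon_energy / 2
  c(e_inf_chromophore = system$e0_chromophore + nc / (nc + ns) * half,
    e_inf_solvent = system$e0_solvent + ns / (nc + ns) * half)
}

#' Heating coefficients A_i of the closed-form solution
#'
#' A_i = kappa_i a_i tau_C / (tau_i - tau_C) multiplies exp(-t / tau_i) in
#' the closed form. A_i is negative whenever the pathway is faster than the
#' cooling (tau_i < tau_C) and its heating amplitude is positive; the sign
#' reflects the balance of heat gain and loss at that time constant.
#'
#' When a pathway time constant collides with tau_C (rates within 1e-8 per
#' ps) the exponential pair is confluent: the returned entry then holds the
#' amplitude kappa_i * a_i of the limiting term (t / tau_C) exp(-t / tau_C)
#' and is flagged in the `"confluent"` attribute. Confluent entries do not
#' enter the boundary coefficient C (the limiting term vanishes at t = 0).
#'
#' @param pathways A [pathway_model()].
#' @param heating_amplitudes kappa_i in eV, one per pathway, >= 0.
#' @param cooling_time tau_C in ps, > 0.
#' @return Numeric vector of A_i (eV) with logical attribute `"confluent"`.
#' @export
coefficients_A <- function(pathways, heating_amplitudes, cooling_time) {
  stopifnot(inherits(pathways, "pathway_model"))
  .check_scalar(cooling_time, "cooling_time", lower = 0, strict = TRUE)
  if (length(heating_amplitudes) != pathways$n_pathways) {
    stop("need one heating amplitude per pathway", call. = FALSE)
  }
  if (any(!is.finite(heating_amplitudes)) || any(heating_amplitudes < 0)) {
    stop("heating amplitudes are constrained to be >= 0", call. = FALSE)
  }
  a <- pathways$weights
  tau <- pathways$time_constants
  confluent <- abs(1 / tau - 1 / cooling_time) < .CONFLUENT_TOL
  out <- numeric(length(tau))
  out[!confluent] <- heating_amplitudes[!confluent] * a[!confluent] *
    cooling_time / (tau[!confluent] - cooling_time)
  out[confluent] <- heating_amplitudes[confluent] * a[confluent]
  attr(out, "confluent") <- confluent
  out
}

#' Solvent cross-term coefficients B_n of the closed-form solution
#'
#' B_n = (N_c / N_s) kappa_n tau_n / (tau_n - tau_C) multiplies
#' exp(-t / tau_s_n). These terms carry the (small) back-coupling of the
#' solvent temperature into the chromophore cooling. Confluent time
#' constants are handled as in [coefficients_A()], with the limiting
#' amplitude (N_c / N_s) kappa_n.
#'
#' @param solvent A [solvent_model()].
#' @param system A [system_spec()].
#' @param cooling_time tau_C in ps, > 0.
#' @return Numeric vector of B_n (eV) with logical attribute `"confluent"`.
#' @export
coefficients_B <- function(solvent, system, cooling_time) {
  stopifnot(inherits(solvent, "solvent_model"),
            inherits(system, "system_spec"))
  .check_scalar(cooling_time, "cooling_time", lower = 0, strict = TRUE)
  k <- solvent$channel_weights
  tau <- solvent$channel_times
  ratio <- system$n_chromophore_atoms / system$n_solvent_atoms
  confluent <- abs(1 / tau - 1 / cooling_time) < .CONFLUENT_TOL
  out <- numeric(length(tau))
  out[!confluent] <- ratio * k[!confluent] * tau[!confluent] /
    (tau[!confluent] - cooling_time)
  out[confluent] <- ratio * k[confluent]
  attr(out, "confluent") <- confluent
  out
}

#' Boundary coefficient C of the closed-form solution
#'
#' Fixed by the boundary values E_c(0) = E0_c and E_c(inf) = E_inf_c:
#' C = E0_c - E_inf_c - sum_i A_i - sum_n B_n, where confluent entries are
#' excluded from the sums (their limiting terms vanish at t = 0).
#'
#' @param system A [system_spec()] (supplies E0_c).
#' @param e_inf_chromophore Equilibrium chromophore energy in eV.
#' @param coeff_a,coeff_b Coefficient vectors as returned by
#'   [coefficients_A()] / [coefficients_B()] (the `"confluent"` attribute,
#'   if present, is honoured).
#' @return C in eV.
#' @export
coefficient_C <- function(system, e_inf_chromophore, coeff_a, coeff_b) {
  stopifnot(inherits(system, "system_spec"))
  .check_scalar(e_inf_chromophore, "e_inf_chromophore")
  ca <- .drop_confluent(coeff_a)
  cb <- .drop_confluent(coeff_b)
  system$e0_chromophore - e_inf_chromophore - sum(ca) - sum(cb)
}

#' Chromophore kinetic energy (closed form)
#'
#' Evaluates
#' `E_c(t) = E_inf + sum_i A_i exp(-t/tau_i) + sum_n B_n exp(-t/tau_s_n)
#'  + C exp(-t/tau_C)`,
#' with confluent entries contributing `amp * (t/tau_C) exp(-t/tau_C)`.
#'
#' @param t Time(s) in ps, >= 0.
#' @param model A [chromophore_model()].
#' @param pathways The companion [pathway_model()] (supplies tau_i).
#' @param solvent The companion [solvent_model()] (supplies tau_s_n).
#' @return Energy value(s) in eV; equals E0_c at t = 0 and tends to E_inf_c.
#' @export
chromophore_energy <- function(t, model, pathways, solvent) {
  stopifnot(inherits(model, "chromophore_model"),
            inherits(pathways, "pathway_model"),
            inherits(solvent, "solvent_model"))
  .check_time(t)
  .ec_terms(t, model, pathways$time_constants, solvent$channel_times)
}

#' Analytic time derivative of the chromophore energy
#'
#' dE_c/dt from term-by-term differentiation of the closed form; used by
#' [peak_time()] and available for diagnostics.
#'
#' @inheritParams chromophore_energy
#' @return Rate(s) in eV per ps.
#' @export
chromophore_energy_rate <- function(t, model, pathways, solvent) {
  stopifnot(inherits(model, "chromophore_model"),
            inherits(pathways, "pathway_model"),
            inherits(solvent, "solvent_model"))
  .check_time(t)
  .ec_terms(t, model, pathways$time_constants, solvent$channel_times,
            deriv = TRUE)
}

#' Mean excited-state lifetime (heating time)
#'
#' tau_H = sum_i a_i tau_i: the population-weighted mean lifetime of the
#' excited state, i.e. the time scale on which internal conversion deposits
#' heat into the chromophore.
#'
#' @param pathways A [pathway_model()].
#' @return tau_H in ps.
#' @examples
#' mean_lifetime(pathway_model(c(0.33, 0.67), c(0.046, 0.903))) # 0.62
#' @export
mean_lifetime <- function(pathways) {
  stopifnot(inherits(pathways, "pathway_model"))
  sum(pathways$weights * pathways$time_constants)
}

#' Time of the chromophore kinetic-energy maximum
#'
#' Locates the global maximum of the closed-form E_c(t) on t > 0: the
#' transient equilibrium where internal-conversion heating balances
#' solvent cooling. The analytic derivative is scanned on a 512-point
#' log-spaced grid over \[1e-6, 20 * max(time constant)\] ps; each sign
#' change is refined by bracketed root finding (tolerance 1e-6 ps) and the
#' candidate with the largest E_c wins. When the derivative never changes
#' sign the energy is monotone and `NA_real_` is returned.
#'
#' @inheritParams chromophore_energy
#' @return Peak time in ps, or `NA_real_` for a monotone energy curve.
#' @export
peak_time <- function(model, pathways, solvent) {
  stopifnot(inherits(model, "chromophore_model"),
            inherits(pathways, "pathway_model"),
            inherits(solvent, "solvent_model"))
  taus <- c(pathways$time_constants, solvent$channel_times,
            model$cooling_time)
  lo <- 1e-6
  hi <- 20 * max(taus)
  grid <- exp(seq(log(lo), log(hi), length.out = 512L))
  d <- chromophore_energy_rate(grid, model, pathways, solvent)
  sgn <- sign(d)
  flips <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0L) {
    return(NA_real_)
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(function(tt)
      chromophore_energy_rate(tt, model, pathways, solvent),
      lower = grid[i], upper = grid[i + 1L], tol = 1e-6)$root
  }, numeric(1L))
  vals <- chromophore_energy(roots, model, pathways, solvent)
  # only a genuine interior maximum counts: it must beat both boundaries
  best <- which.max(vals)
  e0 <- model$e0_chromophore
  einf <- model$e_inf_chromophore
  if (vals[best] <= max(e0, einf) + 1e-12) {
    return(NA_real_)
  }
  roots[best]
}

# -- internal ----------------------------------------------------------------

.drop_confluent <- function(x) {
  cf <- attr(x, "confluent")
  if (is.null(cf)) as.numeric(x) else as.numeric(x)[!cf]
}

# vectorised evaluation of the exponential sum (or its derivative)
.ec_terms <- function(tt, model, tau_p, tau_s, deriv = FALSE) {
  tc <- model$cooling_time
  fa <- model$confluent_a
  fb <- model$confluent_b
  if (is.null(fa)) fa <- rep(FALSE, length(model$coeff_a))
  if (is.null(fb)) fb <- rep(FALSE, length(model$coeff_b))
  acc <- if (deriv) numeric(length(tt)) else
    rep(model$e_inf_chromophore, length(tt))
  add <- function(acc, amp, tau, conf) {
    if (any(!conf)) {
      coef <- amp[!conf] * (if (deriv) -1 / tau[!conf] else 1)
      acc <- acc + as.vector(exp(-outer(tt, 1 / tau[!conf])) %*% coef)
    }
    if (any(conf)) {
      # confluent pair limit: amp * (t/tau_C) exp(-t/tau_C)
      s <- sum(amp[conf])
      e <- exp(-tt / tc)
      acc <- acc + if (deriv) s * e * (1 / tc - tt / tc^2) else
        s * (tt / tc) * e
    }
    acc
  }
  acc <- add(acc, model$coeff_a, tau_p, fa)
  acc <- add(acc, model$coeff_b, tau_s, fb)
  acc + model$coeff_c * (if (deriv) -1 / tc else 1) * exp(-tt / tc)
}
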