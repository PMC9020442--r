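#' System descriptor for a solvated chromophore
#'
#' Bundles the static quantities the energy-transfer model needs about one
#' chromophore/solvent system: atom counts, the photon energy deposited at
#' t = 0, and the initial (t = 0) ensemble mean kinetic energies of solute
#' and solvent. Units are fixed package-wide: energies in eV, times in ps.
#'
#' @param n_chromophore_atoms Number of atoms in the chromophore (N_c >= 1).
#' @param n_solvent_atoms Number of atoms in the solvent (N_s >= 1).
#' @param photon_energy Photon energy h*nu in eV (> 0; 0 is allowed and
#'   means no excitation, useful for degenerate checks).
#' @param e0_chromophore Chromophore mean kinetic energy at t = 0, in eV.
#' @param e0_solvent Solvent mean kinetic energy at t = 0, in eV.
#'
#' @return An object of class `system_spec`.
#' @examples
#' argon <- system_spec(13, 684, 5.25, 1.46, 0.89)
#' equilibrium_energies(argon)
#' @export
system_spec <- function(n_chromophore_atoms, n_solvent_atoms, photon_energy,
                        e0_chromophore, e0_solvent) {
  nc <- n_chromophore_atoms
  ns <- n_solvent_atoms
  if (!is.numeric(nc) || length(nc) != 1L || !is.finite(nc) || nc < 1 ||
      nc != round(nc)) {
    stop("n_chromophore_atoms must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(ns) || length(ns) != 1L || !is.finite(ns) || ns < 1 ||
      ns != round(ns)) {
    stop("n_solvent_atoms must be a single integer >= 1", call. = FALSE)
  }
  .check_scalar(photon_energy, "photon_energy", lower = 0)
  .check_scalar(e0_chromophore, "e0_chromophore", lower = 0)
  .check_scalar(e0_solvent, "e0_solvent", lower = 0)
  structure(
    list(n_chromophore_atoms = as.integer(nc),
         n_solvent_atoms = as.integer(ns),
         photon_energy = as.numeric(photon_energy),
         e0_chromophore = as.numeric(e0_chromophore),
         e0_solvent = as.numeric(e0_solvent)),
    class = "system_spec"
  )
}

#' Ground-state decay pathway model
#'
#' Describes the multi-exponential filling of the electronic ground state:
#' each pathway i carries a weight a_i and a time constant tau_i (ps), and
#' contributes a_i * (1 - exp(-t / tau_i)) to the ground-state population.
#' Pathways are kinetic channels fitted to the ensemble population, not
#' individual electronic states.
#'
#' @param weights Pathway weights a_i, each in \[0, 1\], sum <= 1 (sum = 1
#'   when the chromophore decays completely).
#' @param time_constants Pathway time constants tau_i in ps, all > 0.
#'
#' @return An object of class `pathway_model` with fields `weights`,
#'   `time_constants`, `n_pathways`.
#' @examples
#' gas <- pathway_model(c(0.16, 0.84), c(0.013, 0.688))
#' mean_lifetime(gas) # 0.58 ps
#' @export
pathway_model <- function(weights, time_constants) {
  if (length(weights) != length(time_constants)) {
    stop("weights and time_constants must have equal length", call. = FALSE)
  }
  if (length(weights) < 1L) {
    stop("at least one pathway is required", call. = FALSE)
  }
  if (!is.numeric(weights) || any(!is.finite(weights)) ||
      any(weights < -1e-12) || any(weights > 1 + 1e-12)) {
    stop("pathway weights must lie in [0, 1]", call. = FALSE)
  }
  if (sum(weights) > 1 + 1e-8) {
    stop("pathway weights must sum to <= 1", call. = FALSE)
  }
  if (!is.numeric(time_constants) || any(!is.finite(time_constants)) ||
      any(time_constants <= 0)) {
    stop("pathway time constants must be positive", call. = FALSE)
  }
  structure(
    list(weights = pmin(pmax(as.numeric(weights), 0), 1),
         time_constants = as.numeric(time_constants),
         n_pathways = length(weights)),
    class = "pathway_model"
  )
}

#' Solvent heating model
#'
#' The solvent mean kinetic energy is modelled as
#' E_s(t) = E_s_inf + sum_n kappa_n * exp(-t / tau_n), with the amplitude
#' constraint sum_n kappa_n = E_s(0) - E_s_inf so that the curve starts at
#' the observed initial energy. Amplitudes kappa_n are negative when the
#' solvent heats up.
#'
#' @param e_inf_solvent Equilibrium solvent kinetic energy in eV.
#' @param channel_weights Channel amplitudes kappa_n in eV.
#' @param channel_times Channel time constants tau_n in ps, all > 0.
#' @param e0_solvent Optional initial solvent energy used to verify the
#'   amplitude constraint; checked to `tol` when supplied.
#' @param tol Tolerance for the amplitude constraint check (eV).
#'
#' @return An object of class `solvent_model`.
#' @examples
#' ar <- solvent_model(3.466, -2.576, 15.49)
#' solvent_energy(0, ar) # 0.89 eV
#' @export
solvent_model <- function(e_inf_solvent, channel_weights, channel_times,
                          e0_solvent = NULL, tol = 1e-6) {
  if (length(channel_weights) != length(channel_times)) {
    stop("channel_weights and channel_times must have equal length",
         call. = FALSE)
  }
  if (length(channel_weights) < 1L) {
    stop("at least one solvent channel is required", call. = FALSE)
  }
  .check_scalar(e_inf_solvent, "e_inf_solvent")
  if (!is.numeric(channel_weights) || any(!is.finite(channel_weights))) {
    stop("channel_weights must be finite numbers", call. = FALSE)
  }
  if (!is.numeric(channel_times) || any(!is.finite(channel_times)) ||
      any(channel_times <= 0)) {
    stop("channel_times must be positive", call. = FALSE)
  }
  if (!is.null(e0_solvent)) {
    gap <- e0_solvent - e_inf_solvent
    if (abs(sum(channel_weights) - gap) > tol) {
      stop(sprintf(
        "sum of channel_weights (%.6g) must equal e0_solvent - e_inf_solvent (%.6g)",
        sum(channel_weights), gap), call. = FALSE)
    }
  }
  structure(
    list(e_inf_solvent = as.numeric(e_inf_solvent),
         channel_weights = as.numeric(channel_weights),
         channel_times = as.numeric(channel_times),
         n_channels = length(channel_weights)),
    class = "solvent_model"
  )
}

#' Chromophore energy model (closed-form solution coefficients)
#'
#' Holds everything needed to evaluate the closed-form chromophore kinetic
#' energy
#' `E_c(t) = E_inf + sum_i A_i exp(-t/tau_i) + sum_n B_n exp(-t/tau_s_n)
#'  + C exp(-t/tau_C)`.
#' Two calling patterns are supported:
#'
#' * **Derived** (the normal route): supply `heating_amplitudes` (kappa_i,
#'   one per pathway, >= 0), `cooling_time` (tau_C, ps), plus the companion
#'   `pathways`, `solvent` and `system`; the coefficients A_i, B_n, C and
#'   the equilibrium energy E_inf are computed from the model algebra and
#'   the virial-partition boundary conditions.
#' * **Explicit**: supply `cooling_time`, `e_inf_chromophore`, `coeff_a`,
#'   `coeff_b`, `coeff_c` directly (e.g. printed table values); the implied
#'   initial energy is E_inf + sum(A) + sum(B) + C.
#'
#' Near-degenerate time constants (|1/tau_x - 1/tau_C| < 1e-8 per ps) are
#' handled by the confluent limit: the pair of exponentials collapses to an
#' amplitude times (t/tau_C) exp(-t/tau_C). Confluent entries are flagged in
#' the `confluent_a` / `confluent_b` fields, where `coeff_a`/`coeff_b` then
#' store the confluent amplitude instead of a plain coefficient.
#'
#' @param heating_amplitudes Heating amplitudes kappa_i in eV, >= 0.
#' @param cooling_time Cooling time constant tau_C in ps, > 0.
#' @param pathways A [pathway_model()]; required for the derived pattern.
#' @param solvent A [solvent_model()]; required for the derived pattern.
#' @param system A [system_spec()]; required for the derived pattern.
#' @param e_inf_chromophore,coeff_a,coeff_b,coeff_c Explicit coefficients
#'   for the second calling pattern.
#'
#' @return An object of class `chromophore_model`.
#' @examples
#' sys <- system_spec(13, 684, 5.25, 1.46, 0.89)
#' pw <- pathway_model(c(0.16, 0.84), c(0.0070, 0.760))
#' sv <- solvent_model(3.466, -2.576, 15.49)
#' cm <- chromophore_model(heating_amplitudes = c(2.5, 0.9),
#'                         cooling_time = 24.9,
#'                         pathways = pw, solvent = sv, system = sys)
#' chromophore_energy(0, cm, pw, sv) # returns e0_chromophore
#' @export
chromophore_model <- function(heating_amplitudes = NULL, cooling_time,
                              pathways = NULL, solvent = NULL, system = NULL,
                              e_inf_chromophore = NULL, coeff_a = NULL,
                              coeff_b = NULL, coeff_c = NULL) {
  .check_scalar(cooling_time, "cooling_time", lower = 0, strict = TRUE)
  if (!is.null(heating_amplitudes)) {
    if (is.null(pathways) || is.null(solvent) || is.null(system)) {
      stop(paste("derived construction needs pathways, solvent and system",
                 "alongside heating_amplitudes"), call. = FALSE)
    }
    stopifnot(inherits(pathways, "pathway_model"),
              inherits(solvent, "solvent_model"),
              inherits(system, "system_spec"))
    if (length(heating_amplitudes) != pathways$n_pathways) {
      stop("need one heating amplitude per pathway", call. = FALSE)
    }
    if (any(!is.finite(heating_amplitudes)) || any(heating_amplitudes < 0)) {
      stop("heating amplitudes are constrained to be >= 0", call. = FALSE)
    }
    eq <- equilibrium_energies(system)
    a_cf <- coefficients_A(pathways, heating_amplitudes, cooling_time)
    b_cf <- coefficients_B(solvent, system, cooling_time)
    c_cf <- coefficient_C(system, eq[["e_inf_chromophore"]], a_cf, b_cf)
    obj <- structure(
      list(heating_amplitudes = as.numeric(heating_amplitudes),
           cooling_time = as.numeric(cooling_time),
           e_inf_chromophore = eq[["e_inf_chromophore"]],
           coeff_a = as.numeric(a_cf),
           coeff_b = as.numeric(b_cf),
           coeff_c = c_cf,
           confluent_a = attr(a_cf, "confluent"),
           confluent_b = attr(b_cf, "confluent"),
           e0_chromophore = system$e0_chromophore),
      class = "chromophore_model"
    )
    # boundary invariant: reconstructed E_c(0) must hit the data's t = 0 value
    e0_check <- .ec_terms(0, obj,
                          pathways$time_constants, solvent$channel_times)
    if (abs(e0_check - system$e0_chromophore) > 1e-9) {
      stop("internal error: E_c(0) does not reproduce e0_chromophore",
           call. = FALSE)
    }
    return(obj)
  }
  if (is.null(e_inf_chromophore) || is.null(coeff_a) || is.null(coeff_b) ||
      is.null(coeff_c)) {
    stop(paste("supply either heating_amplitudes (+ companions) or the",
               "explicit coefficients e_inf_chromophore, coeff_a, coeff_b,",
               "coeff_c"), call. = FALSE)
  }
  structure(
    list(heating_amplitudes = NULL,
         cooling_time = as.numeric(cooling_time),
         e_inf_chromophore = as.numeric(e_inf_chromophore),
         coeff_a = as.numeric(coeff_a),
         coeff_b = as.numeric(coeff_b),
         coeff_c = as.numeric(coeff_c),
         confluent_a = rep(FALSE, length(coeff_a)),
         confluent_b = rep(FALSE, length(coeff_b)),
         e0_chromophore = as.numeric(e_inf_chromophore) + sum(coeff_a) +
           sum(coeff_b) + as.numeric(coeff_c)),
    class = "chromophore_model"
  )
}

#' Sampled ensemble observable versus time
#'
#' Container for one ensemble-averaged time series: a strictly increasing
#' time grid (ps), values (fraction for `kind = "population"`, eV for
#' `kind = "energy"`), and optional per-point standard errors.
#'
#' @param times Time grid in ps, strictly increasing, first value >= 0.
#' @param values Observable values; population series must stay within
#'   \[-0.05, 1.05\] (a small band tolerating ensemble noise).
#' @param kind `"population"` or `"energy"`.
#' @param stderr Optional per-point standard errors (same length, >= 0).
#'
#' @return An object of class `time_series`.
#' @export
time_series <- function(times, values, kind = c("energy", "population"),
                        stderr = NULL) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a time series needs at least two points", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite (no NA/NaN)", call. = FALSE)
  }
  if (times[1L] < 0) {
    stop("times must start at >= 0 ps", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (kind == "population" &&
      (any(values < -0.05) || any(values > 1.05))) {
    stop("population values must lie within [-0.05, 1.05]", call. = FALSE)
  }
  if (!is.null(stderr)) {
    if (length(stderr) != length(values) || any(!is.finite(stderr)) ||
        any(stderr < 0)) {
      stop("stderr must be non-negative and match the series length",
           call. = FALSE)
    }
    stderr <- as.numeric(stderr)
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         kind = kind, stderr = stderr),
    class = "time_series"
  )
}

#' @export
print.system_spec <- function(x, ...) {
  cat("System: N_c =", x$n_chromophore_atoms,
      "| N_s =", x$n_solvent_atoms,
      "| h*nu =", x$photon_energy, "eV\n")
  cat(sprintf("  E0_c = %.4g eV, E0_s = %.4g eV\n",
              x$e0_chromophore, x$e0_solvent))
  invisible(x)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Ground-state decay pathways (N_p =", x$n_pathways, ")\n")
  for (i in seq_len(x$n_pathways)) {
    cat(sprintf("  a_%d = %.4g, tau_%d = %.4g ps\n",
                i, x$weights[i], i, x$time_constants[i]))
  }
  cat(sprintf("  mean lifetime tau_H = %.4g ps\n", mean_lifetime(x)))
  invisible(x)
}

#' @export
print.solvent_model <- function(x, ...) {
  cat("Solvent heating model (N_d =", x$n_channels, ")\n")
  cat(sprintf("  E_inf_s = %.4g eV\n", x$e_inf_solvent))
  for (n in seq_len(x$n_channels)) {
    cat(sprintf("  kappa_%d = %.4g eV, tau_%d = %.4g ps\n",
                n, x$channel_weights[n], n, x$channel_times[n]))
  }
  invisible(x)
}

#' @export
print.chromophore_model <- function(x, ...) {
  cat("Chromophore energy model\n")
  cat(sprintf("  tau_C = %.4g ps, E_inf_c = %.4g eV, E0_c = %.4g eV\n",
              x$cooling_time, x$e_inf_chromophore, x$e0_chromophore))
  if (!is.null(x$heating_amplitudes)) {
    cat("  kappa_c =", paste(signif(x$heating_amplitudes, 4), collapse = ", "),
        "eV\n")
  }
  cat("  A =", paste(signif(x$coeff_a, 4), collapse = ", "), "eV\n")
  cat("  B =", paste(signif(x$coeff_b, 4), collapse = ", "), "eV\n")
  cat(sprintf("  C = %.4g eV\n", x$coeff_c))
  invisible(x)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series (%s): %d points, t in [%.4g, %.4g] ps%s\n",
              x$kind, length(x$times), x$times[1L],
              x$times[length(x$times)],
              if (is.null(x$stderr)) "" else ", with stderr"))
  invisible(x)
}

# -- internal helpers --------------------------------------------------------

.check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop(sprintf("%s must be a single finite number %s %g",
                 name, if (strict) ">" else ">=", lower), call. = FALSE)
  }
  invisible(TRUE)
}

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative and finite", call. = FALSE)
  }
  invisible(TRUE)
}
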