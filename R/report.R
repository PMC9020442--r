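# Protocol report: the assembled result of the 3-step fit, mirroring the
# layout of the parameter tables (pathways / solvent / chromophore) plus the
# derived heating time, cooling time and kinetic-energy peak time.

#' Assemble a protocol report
#'
#' Normally produced by [run_protocol()]. The derived quantities (tau_H,
#' tau_C, peak time) are recomputed here from the stored models, so a
#' report is self-consistent by construction.
#'
#' @param system A [system_spec()].
#' @param pathways A [pathway_model()].
#' @param solvent A [solvent_model()].
#' @param chromophore A [chromophore_model()].
#' @param fits Named list of [fit_result()]s per stage (`population`,
#'   `solvent`, `chromophore`), possibly empty for reports built from
#'   known parameters.
#' @param checksums Optional named character vector of input-file md5 sums.
#' @return An object of class `protocol_report`.
#' @export
protocol_report <- function(system, pathways, solvent, chromophore,
                            fits = list(), checksums = NULL) {
  stopifnot(inherits(system, "system_spec"),
            inherits(pathways, "pathway_model"),
            inherits(solvent, "solvent_model"),
            inherits(chromophore, "chromophore_model"))
  structure(
    list(system = system, pathways = pathways, solvent = solvent,
         chromophore = chromophore, fits = fits,
         tau_h = mean_lifetime(pathways),
         tau_c = chromophore$cooling_time,
         peak_time = peak_time(chromophore, pathways, solvent),
         version = as.character(utils::packageVersion("chromocool")),
         checksums = checksums),
    class = "protocol_report"
  )
}

#' @describeIn protocol_report Fixed-width human-readable summary mirroring
#'   the pathway / solvent / chromophore parameter tables.
#' @param x A `protocol_report`.
#' @param ... Unused.
#' @export
print.protocol_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Format a protocol report as fixed-width text
#'
#' @param report A `protocol_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "protocol_report"))
  pw <- report$pathways
  sv <- report$solvent
  cm <- report$chromophore
  sys <- report$system
  row <- function(label, value) sprintf("  %-16s %s", label, value)
  num <- function(v) paste(formatC(v, digits = 4, format = "g", width = 10),
                           collapse = " ")
  lines <- c(
    "Energy-transfer protocol report",
    sprintf("  package version %s", report$version),
    row("N_c / N_s", sprintf("%d / %d", sys$n_chromophore_atoms,
                             sys$n_solvent_atoms)),
    row("h*nu (eV)", num(sys$photon_energy)),
    "Pathways (ground-state population)",
    row("a_i", num(pw$weights)),
    row("tau_c_i (ps)", num(pw$time_constants)),
    row("tau_H (ps)", num(report$tau_h)),
    "Solvent heating",
    row("kappa_s_n (eV)", num(sv$channel_weights)),
    row("tau_s_n (ps)", num(sv$channel_times)),
    row("E_inf_s (eV)", num(sv$e_inf_solvent)),
    "Chromophore energy transfer",
    row("E0_c (eV)", num(cm$e0_chromophore)),
    row("E_inf_c (eV)", num(cm$e_inf_chromophore)),
    row("kappa_c_i (eV)", if (is.null(cm$heating_amplitudes)) "-"
        else num(cm$heating_amplitudes)),
    row("A_i (eV)", num(cm$coeff_a)),
    row("B_n (eV)", num(cm$coeff_b)),
    row("C (eV)", num(cm$coeff_c)),
    row("tau_C (ps)", num(report$tau_c)),
    "Derived",
    row("peak time (ps)", if (is.na(report$peak_time)) "none (monotone)"
        else num(report$peak_time))
  )
  for (stage in names(report$fits)) {
    f <- report$fits[[stage]]
    lines <- c(lines, sprintf(
      "  [%s] rms %.4g over %d points, %s%s", stage, f$residual_rms,
      f$n_points, if (f$converged) "converged" else "NOT converged",
      if (length(f$weakly_identified))
        paste0("; weakly identified: ",
               paste(f$weakly_identified, collapse = ", ")) else ""))
  }
  lines
}

#' Serialize a protocol report to structured JSON
#'
#' Writes every model parameter, fit diagnostic and derived quantity.
#' Before writing, the derived quantities are recomputed from the stored
#' parameters and compared with the stored values (self-consistency
#' guard, 1e-9 tolerance).
#'
#' @param report A `protocol_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "protocol_report"))
  tau_h_check <- sum(report$pathways$weights *
                       report$pathways$time_constants)
  if (abs(tau_h_check - report$tau_h) > 1e-9) {
    stop("report self-consistency violated: stored tau_H does not match ",
         "its pathway parameters", call. = FALSE)
  }
  payload <- list(
    tool = "chromocool", version = report$version,
    system = unclass(report$system),
    pathways = list(weights = report$pathways$weights,
                    time_constants = report$pathways$time_constants),
    solvent = list(e_inf_solvent = report$solvent$e_inf_solvent,
                   channel_weights = report$solvent$channel_weights,
                   channel_times = report$solvent$channel_times),
    chromophore = list(
      heating_amplitudes = report$chromophore$heating_amplitudes,
      cooling_time = report$chromophore$cooling_time,
      e_inf_chromophore = report$chromophore$e_inf_chromophore,
      coeff_a = report$chromophore$coeff_a,
      coeff_b = report$chromophore$coeff_b,
      coeff_c = report$chromophore$coeff_c),
    derived = list(tau_h = report$tau_h, tau_c = report$tau_c,
                   peak_time = if (is.na(report$peak_time)) NULL
                   else report$peak_time),
    fits = lapply(report$fits, function(f) {
      list(parameters = as.list(f$parameters),
           residual_rms = f$residual_rms, n_points = f$n_points,
           converged = f$converged, fit_window = f$fit_window,
           bound_hits = I(f$bound_hits),
           weakly_identified = I(f$weakly_identified))
    }),
    checksums = as.list(report$checksums)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized protocol report back into model objects
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return A `protocol_report` (fit diagnostics are restored as plain
#'   lists, not refitted).
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sys <- do.call(system_spec, j$system[c(
    "n_chromophore_atoms", "n_solvent_atoms", "photon_energy",
    "e0_chromophore", "e0_solvent")])
  pw <- pathway_model(j$pathways$weights, j$pathways$time_constants)
  sv <- solvent_model(j$solvent$e_inf_solvent, j$solvent$channel_weights,
                      j$solvent$channel_times)
  cm <- if (!is.null(j$chromophore$heating_amplitudes)) {
    chromophore_model(heating_amplitudes = j$chromophore$heating_amplitudes,
                      cooling_time = j$chromophore$cooling_time,
                      pathways = pw, solvent = sv, system = sys)
  } else {
    chromophore_model(cooling_time = j$chromophore$cooling_time,
                      e_inf_chromophore = j$chromophore$e_inf_chromophore,
                      coeff_a = j$chromophore$coeff_a,
                      coeff_b = j$chromophore$coeff_b,
                      coeff_c = j$chromophore$coeff_c)
  }
  protocol_report(sys, pw, sv, cm)
}
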