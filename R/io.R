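# Delimited time-series readers/writers and flat-key configuration files.
# Format contract: a header row naming the columns (time_ps plus p0 for
# population series or value_ev for energy series, optional stderr),
# comment lines starting with '#', comma or tab delimited (auto-detected
# on read, comma on write).

#' Read a time series from a delimited text file
#'
#' @param path File path.
#' @param kind `"population"` (expects a `p0` column) or `"energy"`
#'   (expects `value_ev`).
#' @return A validated [time_series()].
#' @export
read_timeseries <- function(path, kind = c("energy", "population")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- raw[keep]
  if (length(rows) < 2L) {
    stop(sprintf("%s: need a header and at least one data row", path),
         call. = FALSE)
  }
  delim <- if (grepl("\t", rows[1L])) "\t" else ","
  header <- trimws(strsplit(rows[1L], delim, fixed = TRUE)[[1L]])
  value_col <- if (kind == "population") "p0" else "value_ev"
  if (!"time_ps" %in% header) {
    stop(sprintf("%s:%d: header must name a 'time_ps' column (units fixed)",
                 path, lineno[1L]), call. = FALSE)
  }
  if (!value_col %in% header) {
    stop(sprintf("%s:%d: header must name a '%s' column for %s series",
                 path, lineno[1L], value_col, kind), call. = FALSE)
  }
  it <- match("time_ps", header)
  iv <- match(value_col, header)
  is_ <- match("stderr", header)
  n <- length(rows) - 1L
  times <- numeric(n); values <- numeric(n)
  stderr <- if (is.na(is_)) NULL else numeric(n)
  for (r in seq_len(n)) {
    fields <- trimws(strsplit(rows[r + 1L], delim, fixed = TRUE)[[1L]])
    if (length(fields) < length(header)) {
      stop(sprintf("%s:%d: expected %d fields, found %d",
                   path, lineno[r + 1L], length(header), length(fields)),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(!is.finite(vals[c(it, iv)]))) {
      stop(sprintf("%s:%d: non-numeric or missing value", path,
                   lineno[r + 1L]), call. = FALSE)
    }
    times[r] <- vals[it]
    values[r] <- vals[iv]
    if (!is.null(stderr)) {
      if (!is.finite(vals[is_])) {
        stop(sprintf("%s:%d: non-numeric stderr", path, lineno[r + 1L]),
             call. = FALSE)
      }
      stderr[r] <- vals[is_]
    }
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("%s:%d: time values must be strictly increasing",
                 path, lineno[bad + 1L]), call. = FALSE)
  }
  tryCatch(time_series(times, values, kind, stderr),
           error = function(e) {
             stop(sprintf("%s: %s", path, conditionMessage(e)),
                  call. = FALSE)
           })
}

#' Write a time series to a delimited text file
#'
#' Deterministic ASCII output: fixed column order
#' (`time_ps`, value, optional `stderr`), comma delimited, 12 significant
#' digits, so identical series produce byte-identical files.
#'
#' @param series A [time_series()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "time_series"))
  value_col <- if (series$kind == "population") "p0" else "value_ev"
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  cols <- c("time_ps", value_col)
  body <- paste(fmt(series$times), fmt(series$values), sep = ",")
  if (!is.null(series$stderr)) {
    cols <- c(cols, "stderr")
    body <- paste(body, fmt(series$stderr), sep = ",")
  }
  con <- file(path, open = "wb")  # binary mode: fixed '\n' on any platform
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","), body), con, sep = "\n")
  invisible(path)
}

# mandatory system keys and their system_spec argument names
.CONFIG_KEYS <- c(
  n_chromophore_atoms = "n_chromophore_atoms",
  n_solvent_atoms = "n_solvent_atoms",
  photon_energy_ev = "photon_energy",
  e0_chromophore_ev = "e0_chromophore",
  e0_solvent_ev = "e0_solvent"
)

#' Load a flat-key configuration file
#'
#' Parses `key = value` (or `key: value`) lines, `#` comments. Mandatory
#' keys describe the system: `n_chromophore_atoms`, `n_solvent_atoms`,
#' `photon_energy_ev`, `e0_chromophore_ev`, `e0_solvent_ev`. Optional keys:
#' `n_pathways` (default 2), `n_channels` (default 1), `fit_window_ps`
#' (either `t_max` or `t_min,t_max`), and comma-separated model-parameter
#' lists used by the `simulate`/`generate` CLI commands
#' (`pathway_weights`, `pathway_times_ps`, `heating_amplitudes_ev`,
#' `cooling_time_ps`, `solvent_times_ps`).
#'
#' @param path Config file path.
#' @return `list(system = system_spec, n_pathways, n_channels,
#'   fit_window, params = list(...))`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  kv <- list()
  for (line in raw) {
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$",
                                  line))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("%s: cannot parse config line: %s", path, line),
           call. = FALSE)
    }
    kv[[m[2L]]] <- trimws(m[3L])
  }
  missing_keys <- setdiff(names(.CONFIG_KEYS), names(kv))
  if (length(missing_keys)) {
    stop(sprintf("%s: missing mandatory config keys: %s", path,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  num <- function(key, default = NULL) {
    if (!key %in% names(kv)) return(default)
    v <- suppressWarnings(as.numeric(strsplit(kv[[key]], ",")[[1L]]))
    if (any(!is.finite(v))) {
      stop(sprintf("%s: non-numeric value for key '%s'", path, key),
           call. = FALSE)
    }
    v
  }
  sys_args <- lapply(names(.CONFIG_KEYS), num)
  names(sys_args) <- unname(.CONFIG_KEYS)
  system <- do.call(system_spec, sys_args)
  window <- num("fit_window_ps")
  if (!is.null(window) && length(window) == 1L) window <- c(0, window)
  params <- list(
    pathway_weights = num("pathway_weights"),
    pathway_times = num("pathway_times_ps"),
    heating_amplitudes = num("heating_amplitudes_ev"),
    cooling_time = num("cooling_time_ps"),
    solvent_times = num("solvent_times_ps"),
    solvent_amplitudes = num("solvent_amplitudes_ev")
  )
  list(system = system,
       n_pathways = as.integer(num("n_pathways", 2)),
       n_channels = as.integer(num("n_channels", 1)),
       fit_window = window,
       params = params[!vapply(params, is.null, logical(1L))])
}
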