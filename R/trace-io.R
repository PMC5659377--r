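# Trace container and CSV/JSON I/O.  Traces are plain data frames (class
# "clamp_trace") whose column units are fixed by convention and written into
# the CSV header (t_ms, Vm_mV, I_DC_pA, ...); metadata travels in a JSON
# sidecar.

trace_units <- function() {
  c(t = "ms", Vm = "mV", Vm_read = "mV", V = "mV", I = "pA", I_CC = "pA",
    I_DC = "pA", I_AMP = "pA", dt_cycle = "us")
}

#' Construct a clamp trace
#'
#' @param df Data frame of channels; must contain a strictly increasing
#'   time column `t` (ms).
#' @param meta Named list of metadata (mode, seed, divergence flag, units).
#' @return The data frame with class `clamp_trace` and a `meta` attribute.
#' @name clamp_trace
#' @export
new_clamp_trace <- function(df, meta = list()) {
  stopifnot("t" %in% names(df), !is.unsorted(df$t, strictly = TRUE))
  structure(df, meta = meta, class = c("clamp_trace", "data.frame"))
}

#' Metadata of a clamp trace
#'
#' @param trace A [clamp_trace].
#' @return The metadata list (may be empty).
#' @export
trace_meta <- function(trace) attr(trace, "meta") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_suffix <- function(nm) {
  u <- trace_units()
  vapply(nm, function(x) {
    if (x %in% names(u)) paste0(x, "_", u[[x]])
    else if (startsWith(x, "g_")) paste0(x, "_nS")
    else x
  }, "")
}

strip_unit_suffix <- function(nm) sub("_(ms|mV|pA|us|nS)$", "", nm)

#' Write / read a trace as CSV with a JSON metadata sidecar
#'
#' Column names carry units (`t_ms`, `Vm_mV`, `I_AMP_pA`, `dt_cycle_us`,
#' `g_<label>_nS`).  Values are written with full precision (15 significant
#' digits) so a write/read round trip preserves them.  Metadata (mode, seed,
#' divergence flag) is written to `<path>.json`.
#'
#' @param trace A [clamp_trace].
#' @param path Output CSV path.
#' @return `write_trace()`: the path, invisibly. `read_trace()`: a
#'   `clamp_trace`.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df) <- unit_suffix(names(df))
  df[] <- lapply(df, function(x)
    if (is.numeric(x)) formatC(x, digits = 15, format = "g") else x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trace_meta(trace)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- strip_unit_suffix(names(df))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  new_clamp_trace(df, meta = meta)
}

# -- run configuration ------------------------------------------------------

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

config_gates <- function(g, base_dir = ".") {
  lapply(g, function(spec) {
    if (!is.null(spec$kinetics_csv)) {
      path <- spec$kinetics_csv
      if (!file.exists(path)) path <- file.path(base_dir, spec$kinetics_csv)
      tabulated_gate(utils::read.csv(path), exponent = spec$exponent %||% 1L,
                     name = spec$name %||% "s")
    } else {
      check_keys(spec, c("type", "v_half", "slope", "tau_min", "tau_amp",
                         "v_peak", "sigma", "exponent", "name"),
                 "gate spec")
      boltzmann_gate(spec$v_half, spec$slope,
                     tau_min = spec$tau_min %||% 5,
                     tau_amp = spec$tau_amp %||% 50,
                     v_peak = spec$v_peak %||% spec$v_half,
                     sigma = spec$sigma %||% 20,
                     exponent = spec$exponent %||% 1L,
                     name = spec$name %||% "s")
    }
  })
}

config_conductance <- function(cs, base_dir = ".") {
  check_keys(cs, c("kind", "g_max", "E_rev", "label", "gates", "synapse",
                   "ou", "v_shift", "phi"), "conductance spec")
  kind <- cs$kind %||% stop("conductance spec needs a kind")
  custom_gates <- !is.null(cs$gates) && !identical(cs$gates, "default")
  switch(kind,
    shunt = shunt_conductance(cs$g_max, cs$E_rev %||% -70,
                              label = cs$label %||% "shunt"),
    hcn = hcn_conductance(cs$g_max %||% 2, cs$E_rev %||% -30,
                          gates = if (custom_gates)
                            config_gates(cs$gates, base_dir)
                          else list(hcn_gate()),
                          label = cs$label %||% "hcn"),
    na = na_conductance(cs$g_max %||% 20, cs$E_rev %||% 50,
                        v_shift = cs$v_shift %||% 0, phi = cs$phi %||% 3,
                        gates = if (custom_gates)
                          config_gates(cs$gates, base_dir)
                        else na_gates(cs$v_shift %||% 0, cs$phi %||% 3),
                        label = cs$label %||% "na"),
    gated = gated_conductance(cs$g_max, cs$E_rev,
                              gates = config_gates(cs$gates, base_dir),
                              label = cs$label %||% "gated"),
    epsc = {
      syn <- cs$synapse %||% list()
      epsc_conductance(cs$g_max %||% 2, cs$E_rev %||% 0,
                       tau_x = syn$tau_x %||% 1, tau_s = syn$tau_s %||% 10,
                       alpha_s = syn$alpha_s %||% 1,
                       label = cs$label %||% "epsc")
    },
    ou_pair = {
      p <- cs$ou %||% list()
      check_keys(p, c("gE0", "gI0", "sE", "sI", "DE", "DI", "tauE", "tauI",
                      "EE", "EI", "rectify"), "ou params")
      ou_background(gE0 = p$gE0 %||% 4, gI0 = p$gI0 %||% 4,
                    sE = p$sE, sI = p$sI, DE = p$DE, DI = p$DI,
                    tauE = p$tauE %||% 2.7, tauI = p$tauI %||% 10.5,
                    EE = p$EE %||% 0, EI = p$EI %||% -75,
                    rectify = p$rectify %||% FALSE,
                    label = cs$label %||% "ou")
    },
    stop("unknown conductance kind: ", kind))
}

config_protocol <- function(p) {
  check_keys(p, c("kind", "amplitudes", "duration", "start", "gap", "rate",
                  "count", "f0", "f1", "amplitude", "waveform",
                  "baseline_current", "tail"), "protocol spec")
  args <- p
  if (!is.null(args$waveform)) args$waveform <- as.data.frame(args$waveform)
  do.call(build_protocol, args)
}

#' Read and validate a run configuration
#'
#' JSON schema with fail-fast validation: unknown keys anywhere in the file
#' are rejected with the offending key named.  Returns fully constructed
#' parameter objects ready for [run_closed_loop()].
#'
#' @param path Path to a JSON configuration file.
#' @return List with `cell`, `conductances`, `protocol`, `timing`, `adc`,
#'   `dac`, `calib`, `seed`, `duration`, `clamp_gates`, `ou_method`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  check_keys(cfg, c("cell", "conductances", "protocol", "timing", "adc",
                    "dac", "calibration", "seed", "duration", "clamp_gates",
                    "ou_method"), "config")
  if (is.null(cfg$cell) || is.null(cfg$protocol))
    stop("config needs at least 'cell' and 'protocol'")
  check_keys(cfg$cell, c("R_m", "C_m", "E_rest", "R_series", "C_stray"),
             "cell")
  cell <- do.call(membrane_params, cfg$cell)
  base_dir <- dirname(path)
  conductances <- lapply(cfg$conductances %||% list(), config_conductance,
                         base_dir = base_dir)
  protocol <- config_protocol(cfg$protocol)
  tm <- cfg$timing %||% list()
  check_keys(tm, c("mean_cycle", "jitter_sd", "latency_cycles"), "timing")
  timing <- do.call(clamp_timing, tm)
  mk_q <- function(q, where) {
    q <- q %||% list()
    check_keys(q, c("bits", "v_min", "v_max"), where)
    do.call(quantizer_spec, q)
  }
  calib <- cfg$calibration %||% "ideal"
  if (identical(calib, "ideal")) calib <- ideal_calibration_map()
  else {
    check_keys(calib, c("input_slope", "input_intercept", "output_slope",
                        "output_intercept", "amp_mV_per_V", "amp_pA_per_V",
                        "input_residual_sd", "output_residual_sd"),
               "calibration")
    calib <- do.call(calibration_map, calib)
  }
  list(cell = cell, conductances = conductances, protocol = protocol,
       timing = timing, adc = mk_q(cfg$adc, "adc"), dac = mk_q(cfg$dac, "dac"),
       calib = calib, seed = cfg$seed %||% 1L, duration = cfg$duration,
       clamp_gates = isTRUE(cfg$clamp_gates),
       ou_method = cfg$ou_method %||% "exact")
}

#' Run a closed-loop simulation from a configuration file
#'
#' @param config Path to a JSON config, or the list returned by
#'   [read_run_config()].
#' @param seed Optional seed override.
#' @param out Optional CSV output path (sidecar JSON written alongside).
#' @return The [clamp_trace], invisibly if written to file.
#' @export
run_from_config <- function(config, seed = NULL, out = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  tr <- run_closed_loop(cfg$cell, cfg$conductances, cfg$protocol,
                        timing = cfg$timing, adc = cfg$adc, dac = cfg$dac,
                        calib = cfg$calib, seed = cfg$seed,
                        duration = cfg$duration,
                        clamp_gates = cfg$clamp_gates,
                        ou_method = cfg$ou_method)
  if (!is.null(out)) {
    write_trace(tr, out)
    return(invisible(tr))
  }
  tr
}
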