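# Deterministic synthetic-input generator: calibration voltage pairs with
# component tolerance and measurement noise, model-cell calibration sweeps,
# and ready-made closed-loop configurations for the package's reference
# experiments.  Every file is accompanied by a manifest recording the seed,
# the true generating parameters and file hashes, so parameter-recovery
# tests can assert against the generating truth.

perturbed_resistors <- function(perturbation_fraction, rng) {
  r <- circuit_resistors()
  if (perturbation_fraction > 0) {
    for (nm in paste0("R", 1:17)) {
      # component-tolerance model: each resistor off by exactly +-fraction
      r[[nm]] <- r[[nm]] * (1 + perturbation_fraction * sign(rng(1L)))
    }
  }
  structure(r, class = "circuit_resistors")
}

#' Generate a synthetic test fixture
#'
#' Kinds:
#' \describe{
#'   \item{calibration_pairs}{Input/output voltage pairs of the input stage:
#'     a grid of known `V_IN` values and measured `V_OUT` values generated
#'     from the ideal input map with resistors perturbed by
#'     `perturbation_fraction` (component tolerance, each resistor off by
#'     exactly that fraction with a seeded random sign) plus additive
#'     Gaussian noise of SD `noise_sd` volts.  Writes `pairs.csv`.}
#'   \item{cell_recording}{A model-cell calibration sweep: DAC commands,
#'     DAQ-recorded steady-state Vm and controller ADC readings generated
#'     from a known (perturbed) pair of maps plus noise.  Writes
#'     `cell_recording.csv`.}
#'   \item{figure_experiment}{A ready-to-run closed-loop JSON configuration;
#'     `experiment` selects one of `fig4_shunt`, `fig5_hcn`, `fig6_na`,
#'     `fig7_epsc`, `fig8_ou`.  Writes `config.json`.}
#' }
#' Every call writes `manifest.json` with the seed, the true generating
#' parameters and MD5 hashes of the files; identical seeds produce
#' hash-identical files.
#'
#' @param kind Fixture kind (see Details).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param noise_sd Additive noise SD in the units of the generated quantity.
#' @param perturbation_fraction Component tolerance (e.g. 0.02).
#' @param n Number of calibration points.
#' @param experiment Experiment name for `figure_experiment`.
#' @param cell Model cell used for `cell_recording`.
#' @return The manifest, invisibly.
#' @export
make_fixture <- function(kind = c("calibration_pairs", "cell_recording",
                                  "figure_experiment"),
                         dir, seed = 1L, noise_sd = 0,
                         perturbation_fraction = 0, n = 50L,
                         experiment = "fig4_shunt",
                         cell = membrane_params(507.7, 35.9, -70)) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- gaussian_stream(seed)
  manifest <- list(kind = kind, seed = seed, noise_sd = noise_sd,
                   perturbation_fraction = perturbation_fraction)
  files <- character(0)

  if (kind == "calibration_pairs") {
    r <- perturbed_resistors(perturbation_fraction, rng)
    V_IN <- seq(-9, 9, length.out = n)
    V_OUT <- ideal_input_map(V_IN, r) + noise_sd * rng(n)
    path <- file.path(dir, "pairs.csv")
    utils::write.csv(data.frame(V_IN_V = V_IN, V_OUT_V = V_OUT), path,
                     row.names = FALSE)
    files <- path
    manifest$truth <- list(
      slope = ideal_input_map(1, r) - ideal_input_map(0, r),
      intercept = ideal_input_map(0, r),
      resistors = unclass(r)[paste0("R", 1:6)])
  }

  if (kind == "cell_recording") {
    r <- perturbed_resistors(perturbation_fraction, rng)
    true_map <- ideal_calibration_map(r)
    V_DAC <- seq(1.7, 2.15, length.out = max(n, 3L))  # modest commands
    I_inj <- (true_map$output_slope * V_DAC + true_map$output_intercept) *
      true_map$amp_pA_per_V
    Vm <- cell$E_rest + I_inj * cell$R_m * 1e-3 + noise_sd * rng(length(V_DAC))
    V_ADC <- true_map$input_slope * (Vm / true_map$amp_mV_per_V) +
      true_map$input_intercept + noise_sd / 100 * rng(length(V_DAC))
    path <- file.path(dir, "cell_recording.csv")
    utils::write.csv(data.frame(V_DAC_V = V_DAC, Vm_mV = Vm, V_ADC_V = V_ADC),
                     path, row.names = FALSE)
    files <- path
    manifest$truth <- list(input_slope = true_map$input_slope,
                           input_intercept = true_map$input_intercept,
                           output_slope = true_map$output_slope,
                           output_intercept = true_map$output_intercept,
                           cell = unclass(cell))
  }

  if (kind == "figure_experiment") {
    cfg <- figure_experiment_config(experiment, seed)
    path <- file.path(dir, "config.json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- path
    manifest$experiment <- experiment
    manifest$truth <- cfg
  }

  manifest$files <- as.list(unname(tools::md5sum(files)))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Closed-loop configurations for the package's reference experiments, at
# desk scale (durations and cycle times chosen so each runs in seconds).
figure_experiment_config <- function(experiment, seed = 1L) {
  cell <- list(R_m = 507.7, C_m = 35.9, E_rest = -70)
  base <- list(cell = cell, seed = seed,
               timing = list(mean_cycle = 10, jitter_sd = 1.5,
                             latency_cycles = 1))
  switch(experiment,
    fig4_shunt = utils::modifyList(base, list(
      conductances = list(list(kind = "shunt", g_max = 5, E_rev = -70)),
      protocol = list(kind = "step",
                      amplitudes = c(-50, -25, 0, 25, 50),
                      duration = 120, start = 20, gap = 60))),
    fig5_hcn = utils::modifyList(base, list(
      conductances = list(list(kind = "hcn", g_max = 4, E_rev = -30)),
      timing = list(mean_cycle = 50, jitter_sd = 1.5, latency_cycles = 1),
      protocol = list(kind = "chirp", f0 = 0, f1 = 15, amplitude = 20,
                      duration = 8000, start = 200))),
    fig6_na = utils::modifyList(base, list(
      conductances = list(list(kind = "na", g_max = 20, E_rev = 50)),
      protocol = list(kind = "ramp", rate = 20, duration = 2000,
                      start = 50))),
    fig7_epsc = utils::modifyList(base, list(
      conductances = list(list(kind = "epsc", g_max = 2, E_rev = 0,
                               synapse = list(tau_x = 1, tau_s = 10,
                                              alpha_s = 1))),
      protocol = list(kind = "train", rate = 50, count = 10, start = 50,
                      tail = 150))),
    fig8_ou = utils::modifyList(base, list(
      conductances = list(list(kind = "ou_pair",
                               ou = list(gE0 = 4, gI0 = 4, sE = 0.25,
                                         sI = 0.25, tauE = 2.7, tauI = 10.5,
                                         EE = 0, EI = -75))),
      protocol = list(kind = "step", amplitudes = -20, duration = 500,
                      start = 100, tail = 50))),
    stop("unknown figure experiment: ", experiment))
}
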