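# Linear voltage maps between the amplifier domain (+-9 V) and the
# controller domain (0-3.3 V), the summing stage, and the calibration
# procedures that replace the ideal circuit equations with empirically
# fitted slopes and intercepts.

#' Breadboard circuit resistor values
#'
#' Resistors of the input divider/differential stage (R1-R6), the output
#' stage (R7-R10) and the summing stage (R11-R17), plus the power rails.
#' Defaults are the reference design values.
#'
#' @param R1,R2,R3,R4,R5,R6,R7,R8,R9,R10,R11,R12,R13,R14,R15,R16,R17
#'   Resistances (Ohm), all positive.
#' @param V_plus,V_minus Positive / negative rail voltages (V).
#' @return An object of class `circuit_resistors`.
#' @export
circuit_resistors <- function(R1 = 2200, R2 = 470, R3 = 4700, R4 = 22000,
                              R5 = 10000, R6 = 100, R7 = 4700, R8 = 22000,
                              R9 = 10000, R10 = 10000, R11 = 10000,
                              R12 = 10000, R13 = 10000, R14 = 3300,
                              R15 = 10000, R16 = 10000, R17 = 4700,
                              V_plus = 9, V_minus = -9) {
  r <- list(R1 = R1, R2 = R2, R3 = R3, R4 = R4, R5 = R5, R6 = R6, R7 = R7,
            R8 = R8, R9 = R9, R10 = R10, R11 = R11, R12 = R12, R13 = R13,
            R14 = R14, R15 = R15, R16 = R16, R17 = R17,
            V_plus = V_plus, V_minus = V_minus)
  stopifnot(all(vapply(r[1:17], function(x) is.finite(x) && x > 0, TRUE)))
  structure(r, class = "circuit_resistors")
}

#' Ideal amplifier-to-controller input map
#'
#' Voltage-divider plus differential-amplifier stage that maps the amplifier
#' output (+-9 V, representing membrane potential) into the controller's ADC
#' range, assuming exact resistors and ideal op-amps:
#' `V_OUT = (1 + R6/R5) * (R4 R2 / ((R3+R4)(R1+R2)) * V_IN
#'          + R3/(R3+R4) * V_plus)`.
#'
#' @param V_IN Amplifier-side voltage (V), vectorized.
#' @param r A [circuit_resistors()] object.
#' @return Controller-side voltage (V).
#' @examples
#' ideal_input_map(0)   # 1.6001 V with default resistors
#' @export
ideal_input_map <- function(V_IN, r = circuit_resistors()) {
  (1 + r$R6 / r$R5) *
    (r$R4 * r$R2 / ((r$R3 + r$R4) * (r$R1 + r$R2)) * V_IN +
       r$R3 / (r$R3 + r$R4) * r$V_plus)
}

#' Ideal controller-to-amplifier output map
#'
#' Differential-amplifier stage that maps the controller's DAC output
#' (0-3.3 V) onto the amplifier command range:
#' `V_DC = (1 + R10/R9) * (R8/(R7+R8) * V_DAC + R7/(R7+R8) * V_minus)`.
#'
#' @param V_DAC DAC output voltage (V), vectorized.
#' @param r A [circuit_resistors()] object.
#' @return Amplifier-command voltage (V).
#' @examples
#' ideal_output_map(0)  # -3.1685 V with default resistors
#' @export
ideal_output_map <- function(V_DAC, r = circuit_resistors()) {
  (1 + r$R10 / r$R9) *
    (r$R8 / (r$R7 + r$R8) * V_DAC + r$R7 / (r$R7 + r$R8) * r$V_minus)
}

#' Summing stage
#'
#' Two cascaded inverting amplifiers sum the dynamic-clamp command `V_DC`
#' and the DAQ current-clamp command `V_DAQ` and restore polarity.  Default
#' unit weights; resistor-derived gains may be supplied.
#'
#' @param V_DC,V_DAQ Input voltages (V), vectorized.
#' @param weights Numeric pair of gains `(w1, w2)`.
#' @return `w1 * V_DC + w2 * V_DAQ` (V).
#' @export
summing_map <- function(V_DC, V_DAQ, weights = c(1, 1)) {
  stopifnot(length(weights) == 2L, all(is.finite(weights)))
  weights[1] * V_DC + weights[2] * V_DAQ
}

#' Calibration map between amplifier and controller domains
#'
#' Bundles the fitted (or ideal) input/output line parameters with the
#' amplifier scale factors.  Forward and inverse maps compose to identity to
#' machine precision.
#'
#' @param input_slope,input_intercept `V_OUT = slope * V_IN + intercept`.
#' @param output_slope,output_intercept `V_DC = slope * V_DAC + intercept`.
#' @param amp_mV_per_V Membrane mV represented per amplifier output volt
#'   (default 10, i.e. 0.1 V per mV).
#' @param amp_pA_per_V Injected pA per volt at the amplifier command input
#'   (default 400).
#' @param input_residual_sd,output_residual_sd Residual SDs of the fits (V),
#'   0 for ideal maps.
#' @return An object of class `calibration_map`.
#' @export
calibration_map <- function(input_slope, input_intercept, output_slope,
                            output_intercept, amp_mV_per_V = 10,
                            amp_pA_per_V = 400, input_residual_sd = 0,
                            output_residual_sd = 0) {
  stopifnot(input_slope != 0, output_slope != 0, amp_mV_per_V != 0,
            amp_pA_per_V != 0)
  structure(list(input_slope = input_slope,
                 input_intercept = input_intercept,
                 output_slope = output_slope,
                 output_intercept = output_intercept,
                 amp_mV_per_V = amp_mV_per_V,
                 amp_pA_per_V = amp_pA_per_V,
                 input_residual_sd = input_residual_sd,
                 output_residual_sd = output_residual_sd),
            class = "calibration_map")
}

#' Calibration map from the ideal circuit equations
#'
#' @param r A [circuit_resistors()] object.
#' @param amp_mV_per_V,amp_pA_per_V Amplifier scale factors, see
#'   [calibration_map()].
#' @return A `calibration_map` whose slopes/intercepts are those of
#'   [ideal_input_map()] and [ideal_output_map()].
#' @export
ideal_calibration_map <- function(r = circuit_resistors(),
                                  amp_mV_per_V = 10, amp_pA_per_V = 400) {
  calibration_map(
    input_slope = ideal_input_map(1, r) - ideal_input_map(0, r),
    input_intercept = ideal_input_map(0, r),
    output_slope = ideal_output_map(1, r) - ideal_output_map(0, r),
    output_intercept = ideal_output_map(0, r),
    amp_mV_per_V = amp_mV_per_V, amp_pA_per_V = amp_pA_per_V)
}

#' Membrane-potential resolution of the input chain
#'
#' The ADC voltage increment divided by the combined gain from membrane mV
#' to ADC volts (amplifier scaling times input-map slope): the smallest
#' change in membrane potential the controller can resolve.
#'
#' @param calib A [calibration_map()].
#' @param adc A [quantizer_spec()].
#' @return Resolution in mV.
#' @export
vm_resolution <- function(calib = ideal_calibration_map(),
                          adc = quantizer_spec()) {
  step <- (adc$v_max - adc$v_min) / 2^adc$bits
  step / (calib$input_slope / calib$amp_mV_per_V)
}

#' Fit a calibration line to measured input/output voltage pairs
#'
#' Ordinary least squares, as used when replacing the ideal circuit
#' equations with the empirically measured (strictly linear) input-output
#' relation of the physical stage.
#'
#' @param pairs Data frame (or two-column matrix) with known inputs in the
#'   first column and measured outputs in the second.
#' @return List with `slope`, `intercept` and `residual_sd`.
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3L) stop("need at least 3 calibration pairs")
  x <- pairs[[1]]; y <- pairs[[2]]
  if (stats::var(x) == 0) stop("calibration inputs must span a nonzero range")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = stats::sd(stats::residuals(fit)))
}

#' Calibrate both maps from model-cell responses
#'
#' Emulates the model-cell calibration procedure: a model cell of known
#' resistance is attached, a set of DAC command values is played out, and
#' the DAQ system independently records the true steady-state membrane
#' potential while the controller records its own ADC reading.  The known
#' Ohmic relation of the cell then identifies both maps by least squares:
#' the ADC reading against the amplifier representation of Vm (input map),
#' and the command voltage implied by the cell's steady-state current
#' against the DAC value (output map).
#'
#' @param sim Data frame with columns `V_DAC` (commanded DAC volts), `Vm`
#'   (steady-state membrane potential recorded by the DAQ, mV) and `V_ADC`
#'   (voltage measured at the controller input, V).
#' @param cell The known [membrane_params()] of the model cell.
#' @param amp_mV_per_V,amp_pA_per_V Amplifier scale factors (known settings).
#' @return A [calibration_map()] with fitted slopes/intercepts and residual
#'   SDs.
#' @export
model_cell_calibration <- function(sim, cell, amp_mV_per_V = 10,
                                   amp_pA_per_V = 400) {
  stopifnot(all(c("V_DAC", "Vm", "V_ADC") %in% names(sim)))
  if (nrow(sim) < 3L) stop("need responses to at least 3 commands")
  if (length(unique(sim$V_DAC)) < 2L)
    stop("commands must span at least 2 distinct amplitudes")
  inp <- fit_calibration(data.frame(x = sim$Vm / amp_mV_per_V,
                                    y = sim$V_ADC))
  I_ss <- (sim$Vm - cell$E_rest) / (cell$R_m * 1e-3)   # pA
  out <- fit_calibration(data.frame(x = sim$V_DAC,
                                    y = I_ss / amp_pA_per_V))
  calibration_map(input_slope = inp$slope, input_intercept = inp$intercept,
                  output_slope = out$slope, output_intercept = out$intercept,
                  amp_mV_per_V = amp_mV_per_V, amp_pA_per_V = amp_pA_per_V,
                  input_residual_sd = inp$residual_sd,
                  output_residual_sd = out$residual_sd)
}
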