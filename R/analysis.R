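# Analyses of simulated recordings: input resistance and membrane time
# constant from step responses, impedance/resonance from chirp responses,
# measured-vs-reference current error statistics, and subthreshold
# membrane-potential statistics with spike clipping.

#' Fit input resistance and time constant from a current-step response
#'
#' Single-exponential least-squares fit of the voltage response to a
#' constant-current step, `V(t) = V_ss + (V_0 - V_ss) exp(-(t - t0)/tau)`,
#' initialized from a log-linear regression and refined with
#' Levenberg-Marquardt.  Input resistance is the steady deflection divided
#' by the step amplitude.
#'
#' @param trace A [clamp_trace] (needs columns `t` and `Vm`).
#' @param step List with `onset` (ms), `duration` (ms) and `amplitude` (pA,
#'   nonzero).
#' @param baseline Length (ms) of the pre-onset window used for the baseline
#'   potential.
#' @return List with `R_in` (MOhm), `tau` (ms), `V0`, `V_ss` (mV).
#' @examples
#' cell <- membrane_params(507.7, 35.9, -70)
#' prot <- build_protocol("step", amplitudes = -50, start = 20,
#'                        duration = 120)
#' tr <- simulate_open_loop(cell, prot, dt = 0.05)
#' fit_rin_tau(tr, list(onset = 20, duration = 120, amplitude = -50))
#' @export
fit_rin_tau <- function(trace, step, baseline = 10) {
  stopifnot(all(c("t", "Vm") %in% names(trace)),
            all(c("onset", "duration", "amplitude") %in% names(step)))
  if (step$amplitude == 0) stop("step amplitude must be nonzero")
  t <- trace$t; v <- trace$Vm
  pre <- t >= step$onset - baseline & t < step$onset
  if (!any(pre)) pre <- t < step$onset
  if (!any(pre)) stop("no baseline samples before the step onset")
  v0 <- mean(v[pre])
  win <- t >= step$onset & t < step$onset + step$duration
  if (sum(win) < 10L) stop("too few samples in the step window")
  tt <- t[win] - step$onset; vv <- v[win]
  # initial guesses: steady state from the last 10%, tau from log-linear fit
  vss0 <- mean(vv[tt >= 0.9 * max(tt)])
  dev <- vv - vss0
  usable <- which(abs(dev) > 0.02 * abs(v0 - vss0) & sign(dev) ==
                    sign(v0 - vss0))
  tau0 <- if (length(usable) > 5L) {
    fit0 <- stats::lm(log(abs(dev[usable])) ~ tt[usable])
    max(-1 / stats::coef(fit0)[2], 1e-3)
  } else max(tt) / 5
  fit <- minpack.lm::nlsLM(
    vv ~ vss + (v0f - vss) * exp(-tt / tau),
    start = list(vss = vss0, v0f = v0, tau = tau0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  R_in <- (cf[["vss"]] - v0) / step$amplitude * 1e3   # mV/pA -> MOhm
  list(R_in = unname(R_in), tau = unname(cf[["tau"]]),
       V0 = v0, V_ss = unname(cf[["vss"]]))
}

#' Impedance profile from broadband voltage/current records
#'
#' `|Z(f)| = |FFT(V - mean) / FFT(I - mean)|`, smoothed with a moving
#' average of bandwidth `smooth_bw`, restricted to `band`.  Because closed-
#' loop traces are sampled at jittered cycle times, records are first
#' interpolated onto a uniform grid at the mean sample interval.  A
#' resonance frequency is reported only when an interior maximum exceeds
#' the low-frequency magnitude by the factor `min_gain`; the margin keeps
#' estimation ripple on a flat low-pass profile from masquerading as a
#' resonance.
#'
#' @param trace A [clamp_trace]; voltage channel `Vm`, current channel
#'   `I_CC` by default (the experimenter's command current -- dividing by
#'   the total injected current `I_AMP` would instead return the impedance
#'   of the bare RC plant, since the dynamic-clamp current is part of the
#'   system under study).
#' @param band Frequency band (Hz), length 2.
#' @param smooth_bw Moving-average bandwidth (Hz).
#' @param v_col,i_col Channel names.
#' @param min_gain Minimum ratio of the interior maximum to the
#'   low-frequency magnitude for a resonance to be reported.
#' @return List of class `impedance_profile` with `f` (Hz), `magnitude`
#'   (MOhm) and `resonance_f` (Hz or `NULL`).
#' @export
impedance_profile <- function(trace, band = c(0.5, 15), smooth_bw = 0.5,
                              v_col = "Vm", i_col = "I_CC",
                              min_gain = 1.05) {
  stopifnot(all(c("t", v_col, i_col) %in% names(trace)), length(band) == 2L)
  t <- trace$t
  dt <- mean(diff(t))
  tu <- seq(min(t), max(t), by = dt)
  V <- stats::approx(t, trace[[v_col]], xout = tu)$y
  I <- stats::approx(t, trace[[i_col]], xout = tu)$y
  n <- length(tu)
  fs <- 1000 / dt                       # Hz (dt in ms)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop("no frequency bins inside the requested band")
  FI <- stats::fft(I - mean(I))
  if (all(Mod(FI[keep]) == 0)) stop("stimulus has no power in the band")
  Z <- stats::fft(V - mean(V))[keep] / FI[keep]
  mag <- Mod(Z) * 1e3                   # mV/pA = GOhm -> MOhm
  fb <- f[keep]
  df <- fs / n
  w <- max(1L, round(smooth_bw / df))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    mag <- as.numeric(stats::filter(mag, kern, sides = 2))
    ok <- !is.na(mag)
    mag <- mag[ok]; fb <- fb[ok]
  }
  imax <- which.max(mag)
  ref_lo <- mean(mag[fb <= fb[1L] + smooth_bw])
  res_f <- NULL
  if (imax > 1L && imax < length(mag) && mag[imax] > min_gain * ref_lo)
    res_f <- fb[imax]
  structure(list(f = fb, magnitude = mag, resonance_f = res_f),
            class = "impedance_profile")
}

#' Error statistics between measured and reference currents
#'
#' Statistics of the sample-wise difference `measured - reference` (the
#' reference is typically a high-order integration of the same equations):
#' mean, SD and maximum of the absolute error, plus a probability histogram.
#'
#' @param measured,reference Equal-length numeric series (pA).
#' @param breaks Histogram breaks (passed to [hist()]).
#' @return List of class `error_stats` with `mean_abs`, `sd_abs`, `max_abs`
#'   (pA) and `histogram` (`breaks`, `counts`).
#' @export
error_stats <- function(measured, reference, breaks = 50) {
  if (length(measured) != length(reference))
    stop("measured and reference must have equal length")
  d <- measured - reference
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(mean_abs = mean(abs(d)),
                 sd_abs = stats::sd(abs(d)),
                 max_abs = max(abs(d)),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "error_stats")
}

#' Subthreshold membrane-potential statistics
#'
#' Mean, SD and histogram of Vm.  If a spike threshold is given, samples
#' within `clip_window` ms of an upward threshold crossing are clipped out
#' before computing the statistics, so only the subthreshold trajectory
#' contributes.
#'
#' @param trace A [clamp_trace] (columns `t`, `Vm`).
#' @param spike_threshold Threshold (mV) or `NULL` for no clipping.
#' @param clip_window Half-width (ms) of the clipped window around each
#'   crossing.
#' @param breaks Histogram breaks.
#' @return List with `mean`, `sd` (mV), `n_spikes`, `histogram`.
#' @export
vm_stats <- function(trace, spike_threshold = NULL, clip_window = 2,
                     breaks = 50) {
  stopifnot(all(c("t", "Vm") %in% names(trace)), nrow(trace) > 0L)
  v <- trace$Vm; t <- trace$t
  keep <- rep(TRUE, length(v))
  n_spikes <- 0L
  if (!is.null(spike_threshold)) {
    up <- which(v[-1L] >= spike_threshold & v[-length(v)] < spike_threshold)
    n_spikes <- length(up)
    for (ix in up)
      keep[t >= t[ix] - clip_window & t <= t[ix] + clip_window] <- FALSE
  }
  if (!any(keep)) stop("all samples were clipped")
  vv <- v[keep]
  h <- graphics::hist(vv, breaks = breaks, plot = FALSE)
  list(mean = mean(vv), sd = stats::sd(vv), n_spikes = n_spikes,
       histogram = list(breaks = h$breaks, counts = h$counts))
}
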