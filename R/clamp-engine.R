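# The closed loop: each cycle the engine advances the plant (model cell)
# under the currently applied current, reads a quantized calibrated estimate
# of Vm, Euler-updates every conductance state with the measured (jittered)
# elapsed time, and commands I_AMP = I_CC + I_DC through the DAC with a
# one-cycle latency.

#' Real-time loop timing contract
#'
#' @param mean_cycle Mean cycle time (microseconds), positive.
#' @param jitter_sd Gaussian SD of the cycle time (microseconds), >= 0.
#' @param latency_cycles Whole-cycle latency between a computed command and
#'   its effect (integer >= 0, default 1).
#' @return An object of class `clamp_timing`.
#' @export
clamp_timing <- function(mean_cycle = 10, jitter_sd = 1.5,
                         latency_cycles = 1L) {
  stopifnot(mean_cycle > 0, jitter_sd >= 0, latency_cycles >= 0,
            latency_cycles == round(latency_cycles))
  structure(list(mean_cycle = mean_cycle, jitter_sd = jitter_sd,
                 latency_cycles = as.integer(latency_cycles)),
            class = "clamp_timing")
}

#' ADC/DAC quantizer specification
#'
#' @param bits Bit depth (default 12, i.e. 4096 levels).
#' @param v_min,v_max Voltage span (V), `v_max > v_min`.
#' @return An object of class `quantizer_spec`.
#' @export
quantizer_spec <- function(bits = 12L, v_min = 0, v_max = 3.3) {
  stopifnot(bits >= 1, bits == round(bits), v_max > v_min)
  structure(list(bits = as.integer(bits), v_min = v_min, v_max = v_max),
            class = "quantizer_spec")
}

#' Voltage increment of a quantizer
#'
#' @param spec A [quantizer_spec()].
#' @return `(v_max - v_min) / 2^bits` in volts (e.g. 3.3/4096 = 0.8057 mV
#'   for the 12-bit default).
#' @export
quantizer_step <- function(spec) (spec$v_max - spec$v_min) / 2^spec$bits

#' Quantize a voltage
#'
#' Clips to the converter span and rounds to the nearest representable
#' level: codes `k = 0 .. 2^bits - 1` at `v_min + k * step` with
#' `step = (v_max - v_min)/2^bits`.
#'
#' @param v Voltage(s) (V), vectorized.
#' @param spec A [quantizer_spec()].
#' @return Quantized voltage(s) (V).
#' @export
quantize <- function(v, spec = quantizer_spec()) {
  step <- quantizer_step(spec)
  code <- round((pmin(pmax(v, spec$v_min), spec$v_max) - spec$v_min) / step)
  spec$v_min + pmin(code, 2^spec$bits - 1) * step
}

#' Sample jittered cycle times
#'
#' Gaussian draws (mean `mean_cycle`, SD `jitter_sd`) truncated below at
#' half the mean cycle (re-drawn on violation); with zero jitter the nominal
#' cycle time is returned exactly.
#'
#' @param n Number of cycles.
#' @param timing A [clamp_timing()].
#' @param rng A [gaussian_stream()] generator.
#' @return Vector of `n` cycle durations (microseconds), all positive.
#' @export
sample_cycle_dt <- function(n, timing, rng = gaussian_stream(1L)) {
  if (timing$jitter_sd == 0) return(rep(timing$mean_cycle, n))
  dt <- timing$mean_cycle + rng(n) * timing$jitter_sd
  bad <- which(dt <= timing$mean_cycle / 2)
  while (length(bad)) {
    dt[bad] <- timing$mean_cycle + rng(length(bad)) * timing$jitter_sd
    bad <- bad[dt[bad] <= timing$mean_cycle / 2]
  }
  dt
}

#' Holding current for a target baseline potential
#'
#' Constant current that holds the cell at `V_hold` given the steady-state
#' conductance load (gates at steady state for `V_hold`, OU conductances at
#' their means).
#'
#' @param cell A [membrane_params()].
#' @param conductances List of [conductance_spec()]s.
#' @param V_hold Target potential (mV).
#' @return Current (pA).
#' @export
holding_current <- function(cell, conductances = list(), V_hold) {
  I_leak <- (V_hold - cell$E_rest) / (cell$R_m * 1e-3)
  I_dc <- 0
  for (spec in conductances) {
    st <- init_conductance_state(spec, V_hold)
    I_dc <- I_dc + conductance_current(spec, st, V_hold)
  }
  I_leak - I_dc
}

# Scalar fast path for protocol evaluation inside the engine loop (the
# vectorized protocol_current() costs too much per single-time call).
make_current_fun <- function(protocol) {
  base <- protocol$baseline_current
  segs <- protocol$segments
  ns <- length(segs)
  if (ns == 0L) return(function(t) base)
  st <- vapply(segs, `[[`, 0, "start")
  du <- vapply(segs, `[[`, 0, "duration")
  en <- st + du
  kind <- vapply(segs, `[[`, "", "kind")
  amp <- rate <- f0 <- f1 <- A <- numeric(ns)
  wf <- vector("list", ns)
  for (j in seq_len(ns)) {
    p <- segs[[j]]$params
    switch(kind[j],
      step = amp[j] <- p$amplitude,
      ramp = rate[j] <- p$rate,
      chirp = { f0[j] <- p$f0; f1[j] <- p$f1; A[j] <- p$amplitude },
      custom = wf[j] <- list(p$waveform))
  }
  function(t) {
    I <- base
    for (j in seq_len(ns)) {
      if (t >= st[j] && t < en[j]) {
        tt <- t - st[j]
        I <- I + switch(kind[j],
          step = amp[j],
          ramp = rate[j] * tt / 1000,
          chirp = {
            ts <- tt / 1000; Tt <- du[j] / 1000
            A[j] * sin(2 * pi * (f0[j] * ts +
                                   (f1[j] - f0[j]) * ts^2 / (2 * Tt)))
          },
          custom = stats::approx(wf[[j]]$t_ms, wf[[j]]$I_pA, xout = t,
                                 rule = 2)$y)
      }
    }
    I
  }
}

#' Run the dynamic-clamp closed loop
#'
#' Per cycle: (1) draw the cycle duration; (2) advance the plant exactly
#' under the currently applied total current; (3) read Vm through the
#' amplifier scaling, the input map and the ADC, then invert the map to get
#' the controller's estimate `Vm_read`; (4) forward-Euler-update every gate
#' and synapse state (OU conductances use the exact stochastic update) with
#' `Vm_read` and the measured cycle time; (5) sum the conductance currents
#' into `I_DC`; (6) pass `I_DC` through the output map and DAC quantizer;
#' (7) the command `I_AMP = I_CC + I_DC` takes effect `latency_cycles`
#' later.  If `|Vm|` exceeds 500 mV the run halts and the partial trace is
#' returned with `diverged = TRUE` in its metadata.
#'
#' @param cell A [membrane_params()].
#' @param conductances List of [conductance_spec()]s (may be empty).
#' @param protocol A [build_protocol()] protocol supplying `I_CC(t)` and
#'   spike times.
#' @param timing A [clamp_timing()].
#' @param adc,dac [quantizer_spec()]s for input and output converters.
#' @param calib A [calibration_map()]; defaults to the ideal circuit maps.
#' @param seed Integer seed driving jitter and OU noise.
#' @param duration Total time (ms); defaults to the protocol duration.
#' @param v_init Initial Vm (mV); defaults to `E_rest`.
#' @param clamp_gates Clamp gate variables into [0,1]?
#' @param ou_method `"exact"` (default) or `"euler"` stepping for OU
#'   conductances.
#' @return A [clamp_trace] with columns `t`, `Vm`, `Vm_read`, `I_CC`,
#'   `I_DC`, `I_AMP`, `dt_cycle` (us) and one `g_<label>` column per
#'   conductance (nS).
#' @export
run_closed_loop <- function(cell, conductances = list(), protocol,
                            timing = clamp_timing(), adc = quantizer_spec(),
                            dac = quantizer_spec(),
                            calib = ideal_calibration_map(), seed = 1L,
                            duration = NULL, v_init = NULL,
                            clamp_gates = FALSE,
                            ou_method = c("exact", "euler")) {
  stopifnot(inherits(cell, "membrane_params"),
            inherits(protocol, "stimulus_protocol"),
            inherits(timing, "clamp_timing"),
            inherits(adc, "quantizer_spec"), inherits(dac, "quantizer_spec"),
            inherits(calib, "calibration_map"))
  ou_method <- match.arg(ou_method)
  if (is.null(duration)) duration <- protocol$duration
  if (is.null(v_init)) v_init <- cell$E_rest
  rng <- gaussian_stream(seed)
  # block-buffered normals: jitter and OU noise consume one shared stream
  zbuf <- rng(8192L); zptr <- 0L
  draw <- function() {
    if (zptr == 8192L) { zbuf <<- rng(8192L); zptr <<- 0L }
    zptr <<- zptr + 1L
    zbuf[zptr]
  }

  nC <- length(conductances)
  states <- lapply(conductances, init_conductance_state, V_hold = v_init)
  labels <- vapply(conductances, `[[`, "", "label")
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "_")
  # flatten conductance specs/states for the hot loop
  kindcode <- integer(nC)   # 1 shunt, 2 epsc, 3 ou_pair, 4 gated
  gmax <- numeric(nC); erev <- numeric(nC)
  syn_tx <- syn_ts <- syn_a <- numeric(nC)
  syn_x <- syn_s <- numeric(nC)
  ouE_g0 <- ouE_tau <- ouE_D <- ouE_E <- numeric(nC)
  ouI_g0 <- ouI_tau <- ouI_D <- ouI_E <- numeric(nC)
  ou_rect <- logical(nC); ou_gE <- ou_gI <- numeric(nC)
  gate_sinf <- gate_tau <- gate_exp <- gate_s <- vector("list", nC)
  for (k in seq_len(nC)) {
    spec <- conductances[[k]]
    gmax[k] <- if (is.na(spec$g_max)) 0 else spec$g_max
    erev[k] <- if (is.na(spec$E_rev)) 0 else spec$E_rev
    kindcode[k] <- switch(spec$kind, shunt = 1L, epsc = 2L, ou_pair = 3L, 4L)
    if (kindcode[k] == 2L) {
      syn_tx[k] <- spec$synapse$tau_x; syn_ts[k] <- spec$synapse$tau_s
      syn_a[k] <- spec$synapse$alpha_s
    } else if (kindcode[k] == 3L) {
      pe <- spec$ou$E; pi_ <- spec$ou$I
      ouE_g0[k] <- pe$g0; ouE_tau[k] <- pe$tau; ouE_D[k] <- pe$D
      ouE_E[k] <- pe$E_rev
      ouI_g0[k] <- pi_$g0; ouI_tau[k] <- pi_$tau; ouI_D[k] <- pi_$D
      ouI_E[k] <- pi_$E_rev
      ou_rect[k] <- pe$rectify || pi_$rectify
      ou_gE[k] <- states[[k]]$gE; ou_gI[k] <- states[[k]]$gI
    } else if (kindcode[k] == 4L) {
      gate_sinf[[k]] <- lapply(spec$gates, `[[`, "steady_state")
      gate_tau[[k]] <- lapply(spec$gates, `[[`, "time_constant")
      gate_exp[[k]] <- vapply(spec$gates, `[[`, 0L, "exponent")
      gate_s[[k]] <- as.numeric(states[[k]]$gates)
    }
  }
  ou_exact <- identical(ou_method, "exact")
  current_at <- make_current_fun(protocol)

  # precomputed constants
  E <- cell$E_rest
  RG <- cell$R_m * 1e-3                    # GOhm: pA * RG = mV
  tau <- tau_cell(cell)
  in_s <- calib$input_slope; in_i <- calib$input_intercept
  out_s <- calib$output_slope; out_i <- calib$output_intercept
  ampV <- calib$amp_mV_per_V; ampI <- calib$amp_pA_per_V
  adc_step <- quantizer_step(adc); adc_max <- 2^adc$bits - 1
  adc_lo <- adc$v_min; adc_hi <- adc$v_max
  dac_step <- quantizer_step(dac); dac_max <- 2^dac$bits - 1
  dac_lo <- dac$v_min; dac_hi <- dac$v_max
  mean_us <- timing$mean_cycle; jit <- timing$jitter_sd
  lat <- timing$latency_cycles

  spikes <- protocol$spike_times
  n_spk <- length(spikes); spk_ptr <- 1L

  n_guess <- ceiling(duration * 1e3 / mean_us * 1.05) + 10L
  Tt <- numeric(n_guess); Vm <- numeric(n_guess); Vr <- numeric(n_guess)
  Icc <- numeric(n_guess); Idc <- numeric(n_guess); Iamp <- numeric(n_guess)
  Dtc <- numeric(n_guess)
  Gmat <- if (nC) matrix(0, n_guess, nC) else NULL

  # latency buffer of applied currents (index 1 = oldest)
  I0 <- protocol_current(protocol, 0)
  applied <- rep(I0, lat + 1L)
  v <- v_init
  t <- 0; i <- 0L
  diverged <- FALSE

  ap_ptr <- 1L  # ring-buffer pointer into `applied`

  while (t < duration) {
    # (1) cycle duration
    if (jit > 0) {
      repeat {
        dt_us <- mean_us + draw() * jit
        if (dt_us > mean_us / 2) break
      }
    } else dt_us <- mean_us
    dt <- dt_us * 1e-3

    # (2) plant advance under applied current
    I_app <- applied[ap_ptr]
    v_inf <- E + I_app * RG
    v <- v_inf + (v - v_inf) * exp(-dt / tau)
    t_prev <- t; t <- t + dt

    # (3) read Vm through amplifier scaling -> input map -> ADC -> inverse
    v_adc <- in_s * (v / ampV) + in_i
    if (v_adc < adc_lo) v_adc <- adc_lo else if (v_adc > adc_hi)
      v_adc <- adc_hi
    code <- round((v_adc - adc_lo) / adc_step)
    if (code > adc_max) code <- adc_max
    v_read <- (adc_lo + code * adc_step - in_i) / in_s * ampV

    # spikes falling in this cycle window
    ns <- 0L
    while (spk_ptr <= n_spk && spikes[spk_ptr] <= t) {
      if (spikes[spk_ptr] > t_prev) ns <- ns + 1L
      spk_ptr <- spk_ptr + 1L
    }

    # (4) conductance updates at Vm_read, measured dt; (5) I_DC
    I_dc <- 0
    gvals <- if (nC) numeric(nC) else NULL
    for (k in seq_len(nC)) {
      kc <- kindcode[k]
      if (kc == 1L) {                      # shunt
        g_eff <- gmax[k]
      } else if (kc == 2L) {               # epsc two-stage kinetics
        x <- syn_x[k]
        syn_s[k] <- syn_s[k] + dt * (-syn_s[k] / syn_ts[k] +
                                       syn_a[k] * x * (1 - syn_s[k]))
        syn_x[k] <- x * (1 - dt / syn_tx[k]) + ns
        g_eff <- gmax[k] * syn_s[k]
      } else if (kc == 3L) {               # OU pair
        if (ou_exact) {
          aE <- exp(-dt / ouE_tau[k])
          gE <- ouE_g0[k] + (ou_gE[k] - ouE_g0[k]) * aE +
            sqrt(ouE_D[k] * ouE_tau[k] / 2 * (1 - aE * aE)) * draw()
          aI <- exp(-dt / ouI_tau[k])
          gI <- ouI_g0[k] + (ou_gI[k] - ouI_g0[k]) * aI +
            sqrt(ouI_D[k] * ouI_tau[k] / 2 * (1 - aI * aI)) * draw()
        } else {
          gE <- ou_gE[k] - (ou_gE[k] - ouE_g0[k]) * dt / ouE_tau[k] +
            sqrt(ouE_D[k] * dt) * draw()
          gI <- ou_gI[k] - (ou_gI[k] - ouI_g0[k]) * dt / ouI_tau[k] +
            sqrt(ouI_D[k] * dt) * draw()
        }
        if (ou_rect[k]) { gE <- max(0, gE); gI <- max(0, gI) }
        ou_gE[k] <- gE; ou_gI[k] <- gI
        I_dc <- I_dc - gE * (v_read - ouE_E[k]) - gI * (v_read - ouI_E[k])
        g_eff <- gE + gI
      } else {                             # gated: hcn, na, M-type, ...
        g_eff <- gmax[k]
        sv <- gate_s[[k]]
        sf <- gate_sinf[[k]]; tf <- gate_tau[[k]]; ex <- gate_exp[[k]]
        for (j in seq_along(sv)) {
          s <- sv[j]
          s <- s - dt * (s - sf[[j]](v_read)) / tf[[j]](v_read)
          if (clamp_gates) { if (s < 0) s <- 0 else if (s > 1) s <- 1 }
          sv[j] <- s
          g_eff <- g_eff * s^ex[j]
        }
        gate_s[[k]] <- sv
      }
      if (kc != 3L) I_dc <- I_dc - g_eff * (v_read - erev[k])
      gvals[k] <- g_eff
    }

    # numerical blow-up inside a conductance (e.g. Euler instability at an
    # absurd cycle time) can overflow to NaN before |Vm| reaches the halt
    # threshold; treat it as divergence, preserving the partial trace
    if (!is.finite(I_dc)) { diverged <- TRUE; break }

    # (6) DAC path for I_DC
    v_dac <- (I_dc / ampI - out_i) / out_s
    if (v_dac < dac_lo) v_dac <- dac_lo else if (v_dac > dac_hi)
      v_dac <- dac_hi
    code <- round((v_dac - dac_lo) / dac_step)
    if (code > dac_max) code <- dac_max
    I_dc_app <- (out_s * (dac_lo + code * dac_step) + out_i) * ampI

    # (7) sum with the current-clamp command; applied after the latency
    I_cc <- current_at(t)
    I_amp <- I_cc + I_dc_app
    applied[ap_ptr] <- I_amp            # overwrite oldest slot
    ap_ptr <- if (ap_ptr == lat + 1L) 1L else ap_ptr + 1L

    i <- i + 1L
    if (i > length(Tt)) {  # jitter made cycles shorter than planned
      grow <- function(x) c(x, numeric(n_guess))
      Tt <- grow(Tt); Vm <- grow(Vm); Vr <- grow(Vr); Icc <- grow(Icc)
      Idc <- grow(Idc); Iamp <- grow(Iamp); Dtc <- grow(Dtc)
      if (nC) Gmat <- rbind(Gmat, matrix(0, n_guess, nC))
    }
    Tt[i] <- t; Vm[i] <- v; Vr[i] <- v_read; Icc[i] <- I_cc
    Idc[i] <- I_dc_app; Iamp[i] <- I_amp; Dtc[i] <- dt_us
    if (nC) Gmat[i, ] <- gvals

    if (abs(v) > 500) { diverged <- TRUE; break }
  }

  idx <- seq_len(i)
  tr <- data.frame(t = Tt[idx], Vm = Vm[idx], Vm_read = Vr[idx],
                   I_CC = Icc[idx], I_DC = Idc[idx], I_AMP = Iamp[idx],
                   dt_cycle = Dtc[idx])
  if (nC) {
    G <- Gmat[idx, , drop = FALSE]
    colnames(G) <- paste0("g_", labels)
    tr <- cbind(tr, G)
  }
  new_clamp_trace(tr, meta = list(mode = "closed_loop", seed = seed,
                                  diverged = diverged,
                                  mean_cycle_us = mean_us,
                                  units = trace_units()))
}
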