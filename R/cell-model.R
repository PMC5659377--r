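# Passive model cell ("RC circuit") that every experiment injects current
# into.  Internal unit system, used consistently everywhere in the package:
#   voltage mV, current pA, conductance nS, time ms, capacitance pF,
#   resistance MOhm.
# These are self-consistent up to two fixed powers of ten:
#   I[pA] = g[nS] * V[mV]                  (1 nS * 1 mV = 1 pA)
#   V[mV] = I[pA] * R[MOhm] * 1e-3         (1 pA * 1 GOhm = 1 mV)
#   tau[ms] = R[MOhm] * C[pF] * 1e-3       (1 GOhm * 1 pF = 1 ms)

#' Passive model-cell parameters
#'
#' Describes the resistor-capacitor model cell that stands in for a neuron:
#' a membrane resistance in parallel with a membrane capacitance, returning
#' to a resting potential, optionally behind a series (electrode) resistance
#' with stray capacitance to ground.
#'
#' @param R_m Membrane resistance (MOhm). Must be positive.
#' @param C_m Membrane capacitance (pF). Must be positive.
#' @param E_rest Resting (leak reversal) potential (mV).
#' @param R_series Optional series resistance (MOhm, default 0).
#' @param C_stray Optional stray capacitance (pF, default 0).
#'
#' @return An object of class `membrane_params`. The membrane time constant
#'   `tau_cell = R_m * C_m * 1e-3` ms is always derived, never stored.
#' @examples
#' cell <- membrane_params(R_m = 507.7, C_m = 35.9, E_rest = -70)
#' tau_cell(cell)  # ~18.2 ms
#' @export
membrane_params <- function(R_m, C_m, E_rest = -70, R_series = 0, C_stray = 0) {
  stopifnot(is.numeric(R_m), length(R_m) == 1L, is.finite(R_m), R_m > 0,
            is.numeric(C_m), length(C_m) == 1L, is.finite(C_m), C_m > 0,
            is.numeric(E_rest), length(E_rest) == 1L, is.finite(E_rest),
            is.numeric(R_series), length(R_series) == 1L, R_series >= 0,
            is.numeric(C_stray), length(C_stray) == 1L, C_stray >= 0)
  structure(list(R_m = R_m, C_m = C_m, E_rest = E_rest,
                 R_series = R_series, C_stray = C_stray),
            class = "membrane_params")
}

#' Membrane time constant of a model cell
#'
#' @param params A [membrane_params()] object.
#' @return Time constant in ms (`R_m * C_m * 1e-3`).
#' @export
tau_cell <- function(params) params$R_m * params$C_m * 1e-3

#' Membrane state
#'
#' @param V_m Membrane potential (mV), finite.
#' @param t Time (ms).
#' @return An object of class `membrane_state`.
#' @export
membrane_state <- function(V_m, t = 0) {
  stopifnot(is.finite(V_m), is.finite(t))
  structure(list(V_m = V_m, t = t), class = "membrane_state")
}

#' Advance the passive cell under a constant current (exact update)
#'
#' Integrates `C dV/dt = (E_rest - V)/R + I` exactly over one interval during
#' which the total injected current is held constant:
#' `V' = V_inf + (V - V_inf) exp(-dt/tau)` with `V_inf = E_rest + I R 1e-3`
#' (pA times MOhm gives mV after the 1e-3 factor).  This is the plant of the
#' closed loop and doubles as the integration oracle: between controller
#' updates the physical cell obeys the exact solution, not an Euler step.
#'
#' @param state A [membrane_state()].
#' @param I_total Total injected current (pA), constant over `dt`.
#' @param dt Time step (ms), must be positive.
#' @param params A [membrane_params()].
#' @return The updated `membrane_state` at `t + dt`.
#' @examples
#' cell <- membrane_params(507.7, 35.9, -70)
#' st <- membrane_update(membrane_state(-70), I_total = 50, dt = 1e6, cell)
#' st$V_m - (-70)  # steady deflection I * R = 25.385 mV
#' @export
membrane_update <- function(state, I_total, dt, params) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive finite number")
  if (!is.finite(I_total)) stop("I_total must be finite")
  if (!is.finite(state$V_m)) stop("V_m must be finite")
  v_inf <- params$E_rest + I_total * params$R_m * 1e-3
  v <- v_inf + (state$V_m - v_inf) * exp(-dt / tau_cell(params))
  membrane_state(v, state$t + dt)
}

# Exact update of the two-compartment (series resistance + stray capacitance)
# linear plant over dt with constant injected current I.  State is
# c(V_m, V_p): membrane and pipette node.  Used only when R_series > 0 and
# C_stray > 0; with C_stray = 0 the pipette node is algebraic:
# V_p = V_m + I * R_series * 1e-3.
two_compartment_update <- function(v, I, dt, params) {
  gm <- 1 / (params$R_m * 1e-3)        # nS
  gs <- 1 / (params$R_series * 1e-3)   # nS
  Cm <- params$C_m
  Cp <- params$C_stray
  # d/dt [Vm, Vp] = A [Vm, Vp] + b
  A <- matrix(c(-(gm + gs) / Cm, gs / Cm,
                gs / Cp, -gs / Cp), 2, 2, byrow = TRUE)
  b <- c(gm * params$E_rest / Cm, I / Cp)
  eg <- eigen(A)
  vinf <- -solve(A, b)
  coef <- solve(eg$vectors, v - vinf)
  Re(vinf + eg$vectors %*% (coef * exp(eg$values * dt)))
}

#' Open-loop current-clamp simulation of the model cell
#'
#' Runs the passive cell under a stimulus protocol with no dynamic-clamp
#' conductances, using the exact exponential update on a uniform grid
#' (the injected current is held constant over each step, i.e. treated as a
#' zero-order hold).
#'
#' @param params A [membrane_params()].
#' @param protocol A [build_protocol()] stimulus protocol.
#' @param dt Sample interval (ms), positive.
#' @param duration Total duration (ms); defaults to the protocol's duration.
#' @param v_init Initial membrane potential (mV); defaults to `E_rest`.
#' @return A [clamp_trace] data frame with columns `t`, `Vm`, `I_CC`, `I_AMP`
#'   and `dt_cycle` (constant, in microseconds).
#' @examples
#' cell <- membrane_params(507.7, 35.9, -70)
#' prot <- build_protocol("step", amplitudes = -50, start = 20,
#'                        duration = 100, gap = 50)
#' tr <- simulate_open_loop(cell, prot, dt = 0.1)
#' range(tr$Vm)
#' @export
simulate_open_loop <- function(params, protocol, dt, duration = NULL,
                               v_init = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (length(protocol$segments) == 0L && length(protocol$spike_times) == 0L &&
      protocol$baseline_current == 0)
    stop("empty protocol")
  if (is.null(duration)) duration <- protocol$duration
  if (!is.finite(duration) || duration <= 0) stop("invalid duration")
  if (is.null(v_init)) v_init <- params$E_rest
  n <- ceiling(duration / dt)
  t <- (0:n) * dt
  I <- protocol_current(protocol, t[1:n])
  a <- exp(-dt / tau_cell(params))
  drive <- (1 - a) * (params$E_rest + I * params$R_m * 1e-3)
  v <- stats::filter(drive, a, method = "recursive", init = v_init)
  tr <- data.frame(t = t, Vm = c(v_init, as.numeric(v)),
                   I_CC = c(I, I[n]), dt_cycle = dt * 1e3)
  tr$I_AMP <- tr$I_CC
  new_clamp_trace(tr, meta = list(mode = "open_loop", dt_ms = dt,
                                  units = trace_units()))
}
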