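# Simulated conductances of the dynamic clamp: constant shunt, single-gate
# HCN, transient sodium (m^3 h), the two-stage kinetic EPSC, and the
# Ornstein-Uhlenbeck background pair (the latter's parameters live in
# noise-ou.R).  Gating kinetics follow the relaxation form
#   ds/dt = -(s - s_inf(V)) / tau(V)
# with Euler, RK4 and exact (closed-form) steppers.

#' Voltage-dependent gate specification
#'
#' A gate is defined by its steady-state curve `s_inf(V)` (dimensionless,
#' in [0,1], monotone in V) and its time constant `tau(V)` (ms, strictly
#' positive on the supported range -120..+60 mV), raised to an integer
#' exponent in the conductance product.
#'
#' @param steady_state Function of voltage (mV) returning `s_inf` in [0,1].
#' @param time_constant Function of voltage (mV) returning `tau` in ms (> 0).
#' @param exponent Small positive integer power of the gate.
#' @param name Optional label (e.g. "m", "h", "s").
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(steady_state, time_constant, exponent = 1L,
                      name = "s") {
  stopifnot(is.function(steady_state), is.function(time_constant),
            exponent >= 1, exponent == round(exponent))
  vv <- seq(-120, 60, by = 2)
  si <- steady_state(vv)
  ta <- time_constant(vv)
  if (any(!is.finite(si)) || any(si < -1e-9) || any(si > 1 + 1e-9))
    stop("steady_state must map [-120, 60] mV into [0, 1]")
  d <- diff(si)
  if (!(all(d <= 1e-9) || all(d >= -1e-9)))
    stop("steady_state must be monotone in V")
  if (any(!is.finite(ta)) || any(ta <= 0))
    stop("time_constant must be positive on [-120, 60] mV")
  structure(list(steady_state = steady_state, time_constant = time_constant,
                 exponent = as.integer(exponent), name = name),
            class = "gate_spec")
}

#' Boltzmann gate with a bell-shaped time constant
#'
#' Convenience constructor: `s_inf(V) = 1 / (1 + exp((V - v_half)/slope))`
#' (a negative `slope` gives an activation curve that grows with
#' depolarization; a positive one, as for HCN, grows with hyperpolarization)
#' and `tau(V) = tau_min + tau_amp / (exp((V - v_peak)/sigma) +
#' exp(-(V - v_peak)/sigma))`.
#'
#' @param v_half Half-activation voltage (mV).
#' @param slope Boltzmann slope factor (mV); sign sets the direction.
#' @param tau_min,tau_amp,v_peak,sigma Bell-shaped time-constant parameters
#'   (ms, ms, mV, mV).
#' @param exponent,name Passed to [gate_spec()].
#' @return A `gate_spec`.
#' @export
boltzmann_gate <- function(v_half, slope, tau_min = 5, tau_amp = 50,
                           v_peak = v_half, sigma = 20, exponent = 1L,
                           name = "s") {
  force(v_half); force(slope); force(tau_min); force(tau_amp)
  force(v_peak); force(sigma)
  gate_spec(
    steady_state = function(V) 1 / (1 + exp((V - v_half) / slope)),
    time_constant = function(V)
      tau_min + tau_amp / (exp((V - v_peak) / sigma) +
                           exp(-(V - v_peak) / sigma)),
    exponent = exponent, name = name)
}

#' Tabulated gate kinetics
#'
#' Builds a gate from a table of voltages, steady-state values and time
#' constants (e.g. read from a CSV with columns `V_mV`, `s_inf`, `tau_ms`),
#' using linear interpolation and flat extrapolation beyond the grid.
#'
#' @param table Data frame with columns `V_mV`, `s_inf`, `tau_ms`.
#' @param exponent,name Passed to [gate_spec()].
#' @return A `gate_spec`.
#' @export
tabulated_gate <- function(table, exponent = 1L, name = "s") {
  stopifnot(all(c("V_mV", "s_inf", "tau_ms") %in% names(table)))
  tab <- table[order(table$V_mV), ]
  gate_spec(
    steady_state = function(V)
      stats::approx(tab$V_mV, tab$s_inf, xout = V, rule = 2)$y,
    time_constant = function(V)
      stats::approx(tab$V_mV, tab$tau_ms, xout = V, rule = 2)$y,
    exponent = exponent, name = name)
}

#' Default HCN activation gate
#'
#' Hyperpolarization-activated gate: Boltzmann steady state with
#' half-activation -82 mV and slope 9 mV (open fraction grows as the cell
#' hyperpolarizes) and a bell-shaped time constant peaking at ~30 ms near
#' -70 mV.  These parametric defaults reproduce the physiological signatures
#' of the h-current (sag, subthreshold resonance); they are package choices,
#' overridable via [gate_spec()] or [tabulated_gate()].
#'
#' @return A `gate_spec`.
#' @export
hcn_gate <- function() boltzmann_gate(v_half = -82, slope = 9,
                                      tau_min = 5, tau_amp = 50,
                                      v_peak = -70, sigma = 20, name = "s")

# Hodgkin-Huxley rate helper: x / (1 - exp(-x/y)) * ... with the removable
# singularity handled.
vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / (2 * y)),
                               x / (1 - exp(-x / y)))

#' Default transient-sodium gates (m^3 h)
#'
#' Classic Hodgkin-Huxley activation/inactivation rate functions with a
#' configurable voltage shift and a temperature acceleration factor `phi`
#' (default 3) chosen so that the activation time constant stays below
#' 0.5 ms over the physiological range -- the property that makes the
#' transient sodium conductance the hardest real-time test case.
#'
#' @param v_shift Voltage offset (mV) added to the rate-function argument.
#' @param phi Temperature factor dividing all time constants.
#' @return List of two `gate_spec`s: activation `m` (exponent 3) and
#'   inactivation `h` (exponent 1).
#' @export
na_gates <- function(v_shift = 0, phi = 3) {
  force(v_shift); force(phi)
  am <- function(V) 0.1 * vtrap(V - v_shift + 40, 10)
  bm <- function(V) 4 * exp(-(V - v_shift + 65) / 18)
  ah <- function(V) 0.07 * exp(-(V - v_shift + 65) / 20)
  bh <- function(V) 1 / (1 + exp(-(V - v_shift + 35) / 10))
  list(
    gate_spec(function(V) am(V) / (am(V) + bm(V)),
              function(V) 1 / (phi * (am(V) + bm(V))),
              exponent = 3L, name = "m"),
    gate_spec(function(V) ah(V) / (ah(V) + bh(V)),
              function(V) 1 / (phi * (ah(V) + bh(V))),
              exponent = 1L, name = "h"))
}

#' Conductance specification
#'
#' One simulated conductance of the dynamic clamp.  Use the convenience
#' constructors [shunt_conductance()], [hcn_conductance()],
#' [na_conductance()], [epsc_conductance()], [gated_conductance()] and
#' [ou_background()] rather than calling this directly.
#'
#' @param kind One of `"shunt"`, `"hcn"`, `"na"`, `"gated"`, `"epsc"`,
#'   `"ou_pair"`.
#' @param g_max Maximal conductance (nS, >= 0); `NA` for `ou_pair`.
#' @param E_rev Reversal potential (mV).
#' @param gates List of [gate_spec()]s (gated kinds only).
#' @param synapse List with `tau_x`, `tau_s` (ms) and `alpha_s` (1/ms)
#'   (epsc only); requires `tau_x < tau_s`.
#' @param ou List of two [ou_params()] named `E` and `I` (ou_pair only).
#' @param label Channel label used in trace column names.
#' @return An object of class `conductance_spec`.
#' @export
conductance_spec <- function(kind, g_max = NA_real_, E_rev = NA_real_,
                             gates = list(), synapse = NULL, ou = NULL,
                             label = kind) {
  kind <- match.arg(kind, c("shunt", "hcn", "na", "gated", "epsc", "ou_pair"))
  if (kind != "ou_pair") {
    stopifnot(is.finite(g_max), g_max >= 0, is.finite(E_rev))
  }
  if (kind %in% c("hcn", "na", "gated")) {
    stopifnot(length(gates) >= 1L,
              all(vapply(gates, inherits, TRUE, "gate_spec")))
  }
  if (kind == "epsc") {
    stopifnot(!is.null(synapse), synapse$tau_x > 0, synapse$tau_s > 0,
              synapse$tau_x < synapse$tau_s, synapse$alpha_s >= 0)
  }
  if (kind == "ou_pair") {
    stopifnot(!is.null(ou), inherits(ou$E, "ou_params"),
              inherits(ou$I, "ou_params"))
  }
  structure(list(kind = kind, g_max = g_max, E_rev = E_rev, gates = gates,
                 synapse = synapse, ou = ou, label = label),
            class = "conductance_spec")
}

#' @rdname conductance_spec
#' @export
shunt_conductance <- function(g_max, E_rev = -70, label = "shunt")
  conductance_spec("shunt", g_max, E_rev, label = label)

#' @rdname conductance_spec
#' @export
hcn_conductance <- function(g_max = 2, E_rev = -30, gates = list(hcn_gate()),
                            label = "hcn")
  conductance_spec("hcn", g_max, E_rev, gates = gates, label = label)

#' @rdname conductance_spec
#' @param v_shift,phi Passed to [na_gates()].
#' @export
na_conductance <- function(g_max = 20, E_rev = 50, v_shift = 0, phi = 3,
                           gates = na_gates(v_shift, phi), label = "na")
  conductance_spec("na", g_max, E_rev, gates = gates, label = label)

#' @rdname conductance_spec
#' @export
gated_conductance <- function(g_max, E_rev, gates, label = "gated")
  conductance_spec("gated", g_max, E_rev, gates = gates, label = label)

#' @rdname conductance_spec
#' @param tau_x,tau_s Rise and decay time constants (ms), `tau_x < tau_s`.
#' @param alpha_s Saturation rate constant (1/ms).
#' @export
epsc_conductance <- function(g_max = 2, E_rev = 0, tau_x = 1, tau_s = 10,
                             alpha_s = 1, label = "epsc")
  conductance_spec("epsc", g_max, E_rev,
                   synapse = list(tau_x = tau_x, tau_s = tau_s,
                                  alpha_s = alpha_s),
                   label = label)

#' Initial conductance state
#'
#' Gate variables start at their steady-state value for the holding
#' potential (unless overridden); the synaptic variables start at the
#' absorbing rest state `x = s = 0`; the OU conductances start at their
#' means.
#'
#' @param spec A [conductance_spec()].
#' @param V_hold Holding potential (mV).
#' @return An object of class `conductance_state`.
#' @export
init_conductance_state <- function(spec, V_hold = -70) {
  st <- switch(spec$kind,
    shunt = list(),
    epsc = list(x = 0, s = 0),
    ou_pair = list(gE = spec$ou$E$g0, gI = spec$ou$I$g0),
    list(gates = vapply(spec$gates,
                        function(g) g$steady_state(V_hold), 0)))
  structure(c(st, list(kind = spec$kind)), class = "conductance_state")
}

#' Instantaneous dynamic-clamp current of one conductance
#'
#' Evaluates `I = -g_eff (V_m - E_rev)` with `g_eff` the product of the
#' maximal conductance and the gate variables raised to their exponents
#' (`g_max` for shunt, `g_max s` for HCN, `g_max m^3 h` for sodium,
#' `g_max s` for the synapse, and `gE`/`gI` separately for the OU pair).
#' Positive values depolarize the cell.
#'
#' @param spec A [conductance_spec()].
#' @param state Matching [init_conductance_state()] state.
#' @param V_m Membrane potential (mV).
#' @return Injected current (pA).
#' @examples
#' sh <- shunt_conductance(5, E_rev = -70)
#' conductance_current(sh, init_conductance_state(sh), V_m = -60)  # -50 pA
#' @export
conductance_current <- function(spec, state, V_m) {
  if (!identical(spec$kind, state$kind))
    stop("state kind '", state$kind, "' does not match spec kind '",
         spec$kind, "'")
  switch(spec$kind,
    shunt = -spec$g_max * (V_m - spec$E_rev),
    epsc = -spec$g_max * state$s * (V_m - spec$E_rev),
    ou_pair = -state$gE * (V_m - spec$ou$E$E_rev) -
               state$gI * (V_m - spec$ou$I$E_rev),
    {
      g <- spec$g_max
      for (i in seq_along(spec$gates))
        g <- g * state$gates[[i]]^spec$gates[[i]]$exponent
      -g * (V_m - spec$E_rev)
    })
}

#' Effective conductance of one conductance channel
#'
#' @inheritParams conductance_current
#' @return Effective conductance `g_eff` (nS); for `ou_pair`, the sum
#'   `gE + gI`.
#' @export
effective_conductance <- function(spec, state, V_m = NULL) {
  switch(spec$kind,
    shunt = spec$g_max,
    epsc = spec$g_max * state$s,
    ou_pair = state$gE + state$gI,
    {
      g <- spec$g_max
      for (i in seq_along(spec$gates))
        g <- g * state$gates[[i]]^spec$gates[[i]]$exponent
      g
    })
}

#' One forward-Euler gate update
#'
#' `s' = s - dt (s - s_inf(V)) / tau(V)`.  No clamping to [0,1] unless
#' `clamp = TRUE`: leaving the unit interval is exactly how forward-Euler
#' instability manifests and must remain observable.
#'
#' @param s Current gate value.
#' @param V Membrane potential (mV).
#' @param dt Step (ms), positive.
#' @param gate A [gate_spec()].
#' @param clamp Clamp the result into [0,1]?
#' @return Updated gate value.
#' @export
gate_step_euler <- function(s, V, dt, gate, clamp = FALSE) {
  stopifnot(dt > 0)
  s2 <- s - dt * (s - gate$steady_state(V)) / gate$time_constant(V)
  if (clamp) pmin(1, pmax(0, s2)) else s2
}

#' Exact gate update for piecewise-constant voltage
#'
#' `s' = s_inf(V) + (s - s_inf(V)) exp(-dt / tau(V))`; exact while V is
#' constant, so composing two half steps equals one full step.
#'
#' @inheritParams gate_step_euler
#' @export
gate_step_exact <- function(s, V, dt, gate) {
  stopifnot(dt >= 0)
  si <- gate$steady_state(V)
  si + (s - si) * exp(-dt / gate$time_constant(V))
}

#' Fourth-order Runge-Kutta gate update (V constant over the step)
#'
#' @inheritParams gate_step_euler
#' @export
gate_step_rk4 <- function(s, V, dt, gate) {
  stopifnot(dt > 0)
  si <- gate$steady_state(V)
  tau <- gate$time_constant(V)
  f <- function(s) -(s - si) / tau
  k1 <- f(s)
  k2 <- f(s + dt / 2 * k1)
  k3 <- f(s + dt / 2 * k2)
  k4 <- f(s + dt * k3)
  s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Sodium current under an instantaneous voltage step
#'
#' Voltage-clamp experiment: gates start at steady state for the holding
#' potential, the voltage steps instantaneously to `v_step` at `t_step`, and
#' the sodium current `I = -g_Na m^3 h (V - E_rev)` is integrated with the
#' chosen method.  The per-cycle time step may be jittered (Gaussian SD
#' `jitter_us`, truncated at half the nominal step) to emulate a real-time
#' loop's timing noise.
#'
#' @param spec A sodium [conductance_spec()] (or any gated spec).
#' @param method `"euler"`, `"rk4"` or `"exact"`.
#' @param dt_us Nominal time step (microseconds).
#' @param v_hold,v_step Holding and step potentials (mV).
#' @param t_step Step onset (ms).
#' @param duration Total duration (ms).
#' @param jitter_us Gaussian SD of the per-step jitter (microseconds).
#' @param seed RNG seed for the jitter stream.
#' @param clamp Clamp gate variables to [0,1]? Off by default so Euler
#'   instability is observable.
#' @return Data frame with columns `t` (ms), `V` (mV), `I` (pA) and the gate
#'   variables.
#' @export
na_step_response <- function(spec, method = c("exact", "euler", "rk4"),
                             dt_us = 10, v_hold = -70, v_step = 0,
                             t_step = 20, duration = 50, jitter_us = 0,
                             seed = 1L, clamp = FALSE) {
  method <- match.arg(method)
  stopifnot(dt_us > 0, duration > t_step)
  rng <- gaussian_stream(seed)
  dt_nom <- dt_us * 1e-3
  n_guess <- ceiling(duration / dt_nom) + 10L
  t <- numeric(n_guess); V <- numeric(n_guess); I <- numeric(n_guess)
  ng <- length(spec$gates)
  gates <- matrix(0, n_guess, ng,
                  dimnames = list(NULL, vapply(spec$gates, `[[`, "", "name")))
  s <- vapply(spec$gates, function(g) g$steady_state(v_hold), 0)
  tt <- 0; i <- 0L
  while (tt < duration) {
    dt <- dt_nom
    if (jitter_us > 0) {
      repeat {
        dt <- dt_nom + rng(1L) * jitter_us * 1e-3
        if (dt > dt_nom / 2) break
      }
    }
    v <- if (tt >= t_step) v_step else v_hold
    for (k in seq_len(ng)) {
      s[k] <- switch(method,
        euler = gate_step_euler(s[k], v, dt, spec$gates[[k]], clamp = clamp),
        rk4 = gate_step_rk4(s[k], v, dt, spec$gates[[k]]),
        exact = gate_step_exact(s[k], v, dt, spec$gates[[k]]))
    }
    tt <- tt + dt; i <- i + 1L
    if (i > length(t)) {  # jitter can shorten steps; grow storage
      t <- c(t, numeric(n_guess)); V <- c(V, numeric(n_guess))
      I <- c(I, numeric(n_guess)); gates <- rbind(gates, matrix(0, n_guess, ng))
    }
    t[i] <- tt; V[i] <- v; gates[i, ] <- s
    g <- spec$g_max
    for (k in seq_len(ng)) g <- g * s[k]^spec$gates[[k]]$exponent
    I[i] <- -g * (v - spec$E_rev)
    if (!is.finite(I[i]) || abs(I[i]) > 1e12) break  # divergence: stop early
  }
  idx <- seq_len(i)
  out <- data.frame(t = t[idx], V = V[idx], I = I[idx])
  cbind(out, gates[idx, , drop = FALSE])
}

#' One update of the two-stage kinetic synapse
#'
#' Discretization of `dx/dt = -x/tau_x + sum_i delta(t - t_i)` and
#' `ds/dt = -s/tau_s + alpha_s x (1 - s)`:
#' `x' = x (1 - dt/tau_x) + n_spikes` (each spike falling in the cycle
#' window increments `x` by exactly 1; simultaneous spikes sum) and
#' `s' = s + dt (-s/tau_s + alpha_s x (1 - s))`.
#'
#' @param state A [init_conductance_state()] state of kind `"epsc"`.
#' @param n_spikes Number of presynaptic spikes in this cycle window.
#' @param dt Step (ms), positive.
#' @param spec The epsc [conductance_spec()].
#' @return Updated state.
#' @export
epsc_step <- function(state, n_spikes, dt, spec) {
  stopifnot(dt > 0, n_spikes >= 0, identical(state$kind, "epsc"))
  p <- spec$synapse
  x <- state$x * (1 - dt / p$tau_x) + n_spikes
  s <- state$s + dt * (-state$s / p$tau_s +
                         p$alpha_s * state$x * (1 - state$s))
  state$x <- x; state$s <- s
  state
}
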