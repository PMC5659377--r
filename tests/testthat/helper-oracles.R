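# Shared fixtures and independent numerical oracles for the test suite.

# the reference model cell used throughout (fitted passive parameters)
ref_cell <- function() membrane_params(R_m = 507.7, C_m = 35.9, E_rest = -70)

# Independent RK4 integrator of the bare plant C dV/dt = (E-V)/R + I(t),
# used as an oracle for the exact-update plant integrator.  The command
# current is a zero-order-held sample per step (that is the signal the rig
# physically applies), so both integrators see the identical input.
rk4_plant <- function(cell, I_fun, dt, duration, v0 = cell$E_rest) {
  RG <- cell$R_m * 1e-3
  n <- ceiling(duration / dt)
  v <- numeric(n + 1)
  v[1] <- v0
  t <- 0
  for (i in seq_len(n)) {
    I <- I_fun(t)
    f <- function(vv) ((cell$E_rest - vv) / RG + I) / cell$C_m
    k1 <- f(v[i])
    k2 <- f(v[i] + dt / 2 * k1)
    k3 <- f(v[i] + dt / 2 * k2)
    k4 <- f(v[i] + dt * k3)
    v[i + 1] <- v[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  list(t = (0:n) * dt, V = v)
}

# Independent RK4 integrator of the coupled cell + single-gate conductance
# system (ideal continuous dynamic clamp), used as the closed-loop
# convergence reference.
rk4_cell_gate <- function(cell, g_max, E_rev, gate, I_fun, dt, duration,
                          v0 = cell$E_rest) {
  RG <- cell$R_m * 1e-3
  f <- function(v, s, t)
    c(((cell$E_rest - v) / RG + I_fun(t) - g_max * s * (v - E_rev)) /
        cell$C_m,
      (gate$steady_state(v) - s) / gate$time_constant(v))
  n <- ceiling(duration / dt)
  V <- numeric(n + 1); S <- numeric(n + 1)
  V[1] <- v0; S[1] <- gate$steady_state(v0)
  t <- 0
  for (i in seq_len(n)) {
    k1 <- f(V[i], S[i], t)
    k2 <- f(V[i] + dt / 2 * k1[1], S[i] + dt / 2 * k1[2], t + dt / 2)
    k3 <- f(V[i] + dt / 2 * k2[1], S[i] + dt / 2 * k2[2], t + dt / 2)
    k4 <- f(V[i] + dt * k3[1], S[i] + dt * k3[2], t + dt)
    V[i + 1] <- V[i] + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    S[i + 1] <- S[i] + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    t <- t + dt
  }
  list(t = (0:n) * dt, V = V, S = S)
}

# analytic impedance magnitude (MOhm) of a bare RC cell at frequency f (Hz)
rc_impedance <- function(cell, f) {
  cell$R_m / sqrt(1 + (2 * pi * f * tau_cell(cell) * 1e-3)^2)
}

# steady-state input resistance (MOhm) of the cell with an added constant
# conductance g (nS): parallel combination
parallel_rin <- function(cell, g) 1e3 / (1e3 / cell$R_m + g)

# input resistance from mean steady-state deflection of a -20 pA step
# (baseline window and late step window), as measured on a rig
rin_from_step <- function(tr, onset, duration, amplitude,
                          settle = 0.5 * duration) {
  base <- mean(tr$Vm[tr$t >= onset - 50 & tr$t < onset])
  ss <- mean(tr$Vm[tr$t >= onset + settle & tr$t < onset + duration])
  (ss - base) / amplitude * 1e3
}
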