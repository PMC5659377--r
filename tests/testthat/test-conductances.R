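test_that("conductance currents follow -g_eff (V - E_rev) with the stated sign", {
  # zero driving force for every kind
  sh <- shunt_conductance(5, E_rev = -70)
  ep <- epsc_conductance(2, E_rev = 0)
  na <- na_conductance(20)
  hc <- hcn_conductance(4)
  for (spec in list(sh, ep, na, hc)) {
    st <- init_conductance_state(spec, -70)
    if (spec$kind == "epsc") st$s <- 0.5
    expect_equal(conductance_current(spec, st, spec$E_rev), 0)
  }
  # shunt arithmetic: 5 nS * 10 mV driving force -> -50 pA
  expect_equal(conductance_current(sh, init_conductance_state(sh), -60), -50)
  # sodium with open gates: -20 * 1 * (-70 - 50) = +2400 pA (depolarizing)
  st <- init_conductance_state(na, -70)
  st$gates <- c(1, 1)
  expect_equal(conductance_current(na, st, -70), 2400)
  # local linearity: dI/dV = -g_eff
  st_h <- init_conductance_state(hc, -70)
  g_eff <- effective_conductance(hc, st_h)
  I1 <- conductance_current(hc, st_h, -70)
  I2 <- conductance_current(hc, st_h, -69)
  expect_equal(I2 - I1, -g_eff, tolerance = 1e-12)
})

test_that("mismatched spec/state kinds are rejected", {
  sh <- shunt_conductance(5)
  ep <- epsc_conductance(2)
  expect_error(conductance_current(sh, init_conductance_state(ep), -70),
               "does not match")
})

test_that("gate steppers: fixed point, one-step arithmetic, limits, semigroup", {
  g <- hcn_gate()
  V <- -80
  si <- g$steady_state(V); tau <- g$time_constant(V)
  # Euler fixed point
  expect_equal(gate_step_euler(si, V, 3, g), si)
  # one Euler step of size tau from 0 lands exactly on s_inf
  expect_equal(gate_step_euler(0, V, tau, g), si)
  # exact: identity at dt = 0, steady state as dt -> infinity
  expect_equal(gate_step_exact(0.3, V, 0, g), 0.3)
  expect_equal(gate_step_exact(0.3, V, 1e9, g), si)
  # semigroup: two half steps equal one full step to machine precision
  s1 <- gate_step_exact(gate_step_exact(0.3, V, 7, g), V, 7, g)
  expect_equal(s1, gate_step_exact(0.3, V, 14, g), tolerance = 1e-15)
  # exact stepping keeps s in [0,1] from any s0 in [0,1]
  for (s0 in c(0, 0.5, 1))
    for (dt in c(0.1, 10, 1000)) {
      s <- gate_step_exact(s0, V, dt, g)
      expect_true(s >= 0 && s <= 1)
    }
})

test_that("Euler gate stepping converges to the exact solution at O(dt)", {
  g <- hcn_gate()
  V <- -100; horizon <- 50
  s0 <- g$steady_state(-70)
  s_exact <- gate_step_exact(s0, V, horizon, g)
  errs <- vapply(c(1, 0.5, 0.25, 0.125), function(dt) {
    s <- s0
    for (i in seq_len(horizon / dt)) s <- gate_step_euler(s, V, dt, g)
    abs(s - s_exact)
  }, 0)
  slope <- coef(lm(log(errs) ~ log(c(1, 0.5, 0.25, 0.125))))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  # and at dt = 1 us the Euler trajectory is within 1e-4 everywhere
  si <- g$steady_state(V); tau <- g$time_constant(V)
  dt <- 1e-3
  n <- seq_len(5000)  # first 5 ms, where the error peaks
  eul <- si + (s0 - si) * (1 - dt / tau)^n   # closed form of Euler iterates
  exa <- si + (s0 - si) * exp(-n * dt / tau)
  expect_lt(max(abs(eul - exa)), 1e-4)
})

test_that("sodium voltage step: RK4 at 10 us matches the exact solution to < 0.1 % at the peak", {
  na <- na_conductance(20)
  ex <- na_step_response(na, "exact", dt_us = 10)
  rk <- na_step_response(na, "rk4", dt_us = 10)
  pk <- which.max(abs(ex$I))
  expect_gt(abs(ex$I[pk]), 100)    # a real current transient happened
  expect_lt(abs(rk$I[pk] - ex$I[pk]) / abs(ex$I[pk]), 1e-3)
})

test_that("forward Euler diverges when dt exceeds twice the fastest time constant", {
  na <- na_conductance(20)
  # at 0 mV the activation time constant is ~0.08 ms; dt = 0.2 ms is far
  # beyond the 2*tau stability limit
  tau_m_0 <- na$gates[[1]]$time_constant(0)
  expect_lt(2 * tau_m_0, 0.2)
  eu <- na_step_response(na, "euler", dt_us = 200)
  expect_gt(max(abs(eu$m)), 10)    # gate magnitude left any physical bound
  # while dt below the limit stays stable and close to exact
  eu12 <- na_step_response(na, "euler", dt_us = 12, jitter_us = 2, seed = 3)
  expect_true(all(abs(eu12$m) <= 1.01))
  ex <- na_step_response(na, "exact", dt_us = 12, jitter_us = 2, seed = 3)
  pk <- which.max(abs(ex$I))
  expect_lt(abs(eu12$I[pk] - ex$I[pk]) / abs(ex$I[pk]), 0.05)
})

test_that("sodium activation is fast (tau_m < 0.5 ms over the spike range)", {
  na <- na_conductance()
  taus <- na$gates[[1]]$time_constant(seq(-60, 60, by = 5))
  expect_true(all(taus < 0.5))
})

test_that("unknown integration methods are rejected", {
  expect_error(na_step_response(na_conductance(), "simpson"))
})

test_that("kinetic synapse: rest state, delta convention and saturation", {
  ep <- epsc_conductance(2, tau_x = 1, tau_s = 10, alpha_s = 1)
  st <- init_conductance_state(ep, -70)
  # absorbing rest state without spikes
  for (i in 1:50) st <- epsc_step(st, 0, 0.1, ep)
  expect_equal(st$x, 0); expect_equal(st$s, 0)
  # one spike increments x by exactly 1
  st <- epsc_step(st, 1, 0.1, ep)
  expect_equal(st$x, 1)
  # s never exceeds 1 even under a barrage
  st <- init_conductance_state(ep, -70)
  for (i in 1:2000) st <- epsc_step(st, if (i %% 10 == 0) 2 else 0, 0.05, ep)
  expect_lte(st$s, 1)
  # x decays between spikes with time constant tau_x
  st <- init_conductance_state(ep, -70)
  st <- epsc_step(st, 1, 1e-9, ep)
  x0 <- st$x
  for (i in 1:100) st <- epsc_step(st, 0, 0.01, ep)  # 1 ms = tau_x
  expect_equal(st$x / x0, exp(-1), tolerance = 0.01)
})

test_that("50 Hz trains summate: pre-spike troughs of s grow over the first spikes", {
  ep <- epsc_conductance(2, tau_x = 1, tau_s = 10, alpha_s = 1)
  dt <- 0.02
  spike_every <- 20 / dt            # 50 Hz
  st <- init_conductance_state(ep, -70)
  troughs <- numeric(0)
  for (i in seq_len(10 * spike_every)) {
    spike <- (i %% spike_every) == 1
    if (spike && i > 1) troughs <- c(troughs, st$s)
    st <- epsc_step(st, as.integer(spike), dt, ep)
  }
  expect_true(all(diff(troughs[1:3]) > 0))
  # at 10 Hz the interval is 10 decay constants: no appreciable summation
  st <- init_conductance_state(ep, -70)
  spike_every10 <- 100 / dt
  troughs10 <- numeric(0)
  for (i in seq_len(5 * spike_every10)) {
    spike <- (i %% spike_every10) == 1
    if (spike && i > 1) troughs10 <- c(troughs10, st$s)
    st <- epsc_step(st, as.integer(spike), dt, ep)
  }
  expect_true(all(troughs10 < 1e-3))
})

test_that("an M-type conductance is just a configuration of the gated machinery", {
  m_gate <- boltzmann_gate(v_half = -35, slope = -10, tau_min = 20,
                           tau_amp = 80, v_peak = -35, sigma = 20,
                           name = "m")
  km <- gated_conductance(g_max = 3, E_rev = -90, gates = list(m_gate),
                          label = "im")
  st <- init_conductance_state(km, -70)
  expect_equal(st$gates[[1]], m_gate$steady_state(-70))
  I <- conductance_current(km, st, -70)
  expect_lt(I, 0)   # outward (hyperpolarizing) at rest, E_rev below V
  # and it runs through the closed loop unchanged
  tr <- run_closed_loop(ref_cell(), list(km),
                        build_protocol("step", amplitudes = 40, start = 10,
                                       duration = 60, tail = 10),
                        seed = 1)
  expect_true("g_im" %in% names(tr))
  expect_false(trace_meta(tr)$diverged)
  # depolarizing step activates the conductance
  expect_gt(tr$g_im[which.max(tr$t)], tr$g_im[1])
})

test_that("gate specs validate monotonicity and positivity", {
  expect_error(gate_spec(function(V) V, function(V) rep(1, length(V))))
  expect_error(gate_spec(function(V) rep(0.5, length(V)),
                         function(V) rep(-1, length(V))))
  expect_silent(gate_spec(function(V) 1 / (1 + exp(-(V + 50) / 5)),
                          function(V) rep(2, length(V))))
})

test_that("tabulated kinetics interpolate linearly with flat extrapolation", {
  vv <- seq(-120, 60, by = 10)
  tab <- data.frame(V_mV = vv, s_inf = 1 / (1 + exp((vv + 82) / 9)),
                    tau_ms = rep(30, length(vv)))
  g <- tabulated_gate(tab)
  expect_equal(g$steady_state(-82), 0.5, tolerance = 0.01)
  expect_equal(g$steady_state(-200), g$steady_state(-120))
  expect_equal(g$time_constant(0), 30)
})
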