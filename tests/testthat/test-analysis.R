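test_that("exponential step fits recover generating R and tau", {
  cell <- ref_cell()
  prot <- build_protocol("step", amplitudes = -50, start = 20,
                         duration = 120)
  tr <- simulate_open_loop(cell, prot, dt = 0.05)
  f <- fit_rin_tau(tr, list(onset = 20, duration = 120, amplitude = -50))
  expect_lt(abs(f$R_in / 507.7 - 1), 0.01)
  expect_lt(abs(f$tau / tau_cell(cell) - 1), 0.01)
  # with 0.5 mV additive noise the fit stays within 5 % across 10 seeds
  for (seed in 1:10) {
    rng <- gaussian_stream(seed)
    trn <- tr
    trn$Vm <- tr$Vm + 0.5 * rng(nrow(tr))
    fn <- fit_rin_tau(trn, list(onset = 20, duration = 120,
                                amplitude = -50))
    expect_lt(abs(fn$R_in / 507.7 - 1), 0.05)
    expect_lt(abs(fn$tau / tau_cell(cell) - 1), 0.05)
  }
})

test_that("depolarizing and hyperpolarizing steps give the same R_in on a linear cell", {
  cell <- ref_cell()
  ests <- vapply(c(-50, 50), function(a) {
    prot <- build_protocol("step", amplitudes = a, start = 20,
                           duration = 120)
    tr <- simulate_open_loop(cell, prot, dt = 0.05)
    fit_rin_tau(tr, list(onset = 20, duration = 120, amplitude = a))$R_in
  }, 0)
  expect_equal(ests[1], ests[2], tolerance = 1e-6)
})

test_that("step fitting rejects zero amplitude", {
  cell <- ref_cell()
  prot <- build_protocol("step", amplitudes = -50, start = 20,
                         duration = 120)
  tr <- simulate_open_loop(cell, prot, dt = 0.1)
  expect_error(fit_rin_tau(tr, list(onset = 20, duration = 120,
                                    amplitude = 0)))
})

test_that("RC impedance matches the analytic curve and has no interior maximum", {
  cell <- ref_cell()
  prot <- build_protocol("chirp", f0 = 0, f1 = 15, amplitude = 20,
                         duration = 10000, start = 100, tail = 0)
  tr <- simulate_open_loop(cell, prot, dt = 0.5)
  z <- impedance_profile(tr, band = c(0.5, 15), i_col = "I_CC")
  # DC limit: lowest-band magnitude near the membrane resistance
  expect_lt(abs(z$magnitude[1] / rc_impedance(cell, z$f[1]) - 1), 0.03)
  # 10 Hz: analytic R / sqrt(1 + (2 pi f R C)^2) = 333.9 MOhm
  i10 <- which.min(abs(z$f - 10))
  expect_lt(abs(z$magnitude[i10] / 333.9 - 1), 0.02)
  # whole band within 3 % of the analytic low-pass curve
  expect_lt(max(abs(z$magnitude / rc_impedance(cell, z$f) - 1)), 0.03)
  expect_null(z$resonance_f)
})

test_that("closed loop with zero conductances has the analytic RC impedance", {
  cell <- ref_cell()
  prot <- build_protocol("chirp", f0 = 0, f1 = 15, amplitude = 20,
                         duration = 6000, start = 200, tail = 0)
  tm <- clamp_timing(mean_cycle = 50, jitter_sd = 1.5)
  tr <- run_closed_loop(cell, list(), prot, timing = tm, seed = 4)
  z <- impedance_profile(tr, band = c(0.5, 15))
  expect_lt(max(abs(z$magnitude / rc_impedance(cell, z$f) - 1)), 0.03)
  expect_null(z$resonance_f)
})

test_that("impedance analysis rejects band-empty or powerless input", {
  cell <- ref_cell()
  prot <- build_protocol("step", amplitudes = 0, start = 0, duration = 100,
                         tail = 0)
  tr <- simulate_open_loop(cell, prot, dt = 1)
  expect_error(impedance_profile(tr, band = c(0.5, 15)))
})

test_that("error statistics: identity, constant offset, mismatched lengths", {
  x <- sin(seq(0, 10, by = 0.01)) * 50
  es0 <- error_stats(x, x)
  expect_equal(es0$mean_abs, 0)
  expect_equal(es0$max_abs, 0)
  es <- error_stats(x + 0.7, x)
  expect_equal(es$mean_abs, 0.7, tolerance = 1e-12)
  expect_equal(es$sd_abs, 0)
  expect_equal(sum(es$histogram$counts), length(x))
  expect_error(error_stats(x, x[-1]))
})

test_that("dynamic-clamp HCN current tracks a precise integration along the recorded voltage", {
  cell <- ref_cell()
  hcn <- hcn_conductance(4)
  prot <- build_protocol("step", amplitudes = -50, start = 20,
                         duration = 100, tail = 30)
  tr <- run_closed_loop(cell, list(hcn), prot, seed = 2,
                        timing = clamp_timing(mean_cycle = 12, jitter_sd = 2))
  gate <- hcn$gates[[1]]
  s <- gate$steady_state(-70)
  Iref <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    s <- gate_step_exact(s, tr$Vm_read[i], tr$dt_cycle[i] * 1e-3, gate)
    Iref[i] <- -4 * s * (tr$Vm_read[i] - (-30))
  }
  es <- error_stats(tr$I_DC, Iref)
  expect_lt(es$mean_abs, 0.01 * max(abs(Iref)))   # < 1 % of peak current
})

test_that("Vm statistics clip spikes and degrade gracefully", {
  tr <- new_clamp_trace(data.frame(t = seq(0, 100, by = 0.1), Vm = -65))
  s <- vm_stats(tr)
  expect_equal(s$sd, 0)
  expect_equal(s$mean, -65)
  # threshold with no crossings leaves the statistics unchanged
  s2 <- vm_stats(tr, spike_threshold = 0)
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$n_spikes, 0)
  # synthetic spikes are clipped out of the statistics
  t <- seq(0, 100, by = 0.1)
  v <- -65 + 60 * exp(-((t - 50)^2) / 0.5)
  tr3 <- new_clamp_trace(data.frame(t = t, Vm = v))
  s3 <- vm_stats(tr3, spike_threshold = -20)
  expect_equal(s3$n_spikes, 1)
  expect_lt(s3$mean, -60)
  expect_lt(max(abs(s3$mean + 65)), 1)
  # everything clipped -> error
  tr4 <- new_clamp_trace(data.frame(t = c(0, 1), Vm = c(-70, 10)))
  expect_error(vm_stats(tr4, spike_threshold = 0, clip_window = 10))
})

test_that("Vm fluctuations grow with the OU conductance noise level", {
  cell <- ref_cell()
  prot <- build_protocol("step", amplitudes = 0, start = 0, duration = 300,
                         tail = 0)
  tm <- clamp_timing(mean_cycle = 20, jitter_sd = 1.5)
  sds <- vapply(c(0.25, 0.75, 1.5), function(s) {
    ou <- ou_background(sE = s, sI = s)   # gE0 = gI0 = 4 nS held fixed
    tr <- run_closed_loop(cell, list(ou), prot, timing = tm, seed = 12)
    vm_stats(tr[tr$t > 50, ])$sd
  }, 0)
  expect_true(all(diff(sds) > 0))
})
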