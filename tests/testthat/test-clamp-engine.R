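test_that("quantizer arithmetic: step size, clipping and rounding bound", {
  q <- quantizer_spec()                    # 12 bit over 0-3.3 V
  expect_equal(quantizer_step(q) * 1e3, 0.8057, tolerance = 1e-4)  # mV
  expect_equal(quantizer_step(q), 3.3 / 4096)
  expect_equal(quantize(-1, q), 0)
  expect_equal(quantize(5, q), 3.3 - quantizer_step(q))
  v <- seq(q$v_min, q$v_max - quantizer_step(q) / 2, length.out = 20001)
  expect_lte(max(abs(quantize(v, q) - v)), quantizer_step(q) / 2 + 1e-15)
  # high-resolution converter shrinks the step by 2^12
  expect_equal(quantizer_step(quantizer_spec(bits = 24)) * 2^12,
               quantizer_step(q))
})

test_that("cycle-time sampling: constant without jitter, correct SD, truncated", {
  tm0 <- clamp_timing(mean_cycle = 10, jitter_sd = 0)
  expect_equal(sample_cycle_dt(100, tm0), rep(10, 100))
  tm <- clamp_timing(mean_cycle = 11.1, jitter_sd = 2)
  dts <- sample_cycle_dt(51200, tm, gaussian_stream(10))
  expect_gt(sd(dts), 1.8)
  expect_lt(sd(dts), 2.2)
  expect_true(all(dts > 11.1 / 2))
  expect_equal(mean(dts), 11.1, tolerance = 0.01)
})

test_that("closed loop with no conductances reproduces open-loop current clamp within one quantum", {
  cell <- ref_cell()
  prot <- build_protocol("step", amplitudes = -50, start = 20,
                         duration = 120, tail = 30)
  tm <- clamp_timing(mean_cycle = 10, jitter_sd = 0, latency_cycles = 0)
  trc <- run_closed_loop(cell, list(), prot, timing = tm, seed = 1)
  tro <- simulate_open_loop(cell, prot, dt = 0.01)
  keep <- trc$t <= max(tro$t)    # last cycle overshoots the open-loop grid
  vo <- approx(tro$t, tro$Vm, xout = trc$t[keep])$y
  # worst-case steady offset: one DAC current quantum across the membrane
  dac_q_pA <- quantizer_step(quantizer_spec()) * 1.64794 * 400
  bound <- dac_q_pA * cell$R_m * 1e-3 + 0.06   # + ADC read quantum
  expect_lt(max(abs(trc$Vm[keep] - vo)), bound)
  # with deep quantizers the identity is essentially exact
  q24 <- quantizer_spec(bits = 24)
  trq <- run_closed_loop(cell, list(), prot, timing = tm, adc = q24,
                         dac = q24, seed = 1)
  keep <- trq$t <= max(tro$t)
  vq <- approx(tro$t, tro$Vm, xout = trq$t[keep])$y
  expect_lt(max(abs(trq$Vm[keep] - vq)), 1e-3)
})

test_that("5 nS shunt on the reference cell gives the parallel-conductance input resistance", {
  cell <- ref_cell()
  sh <- shunt_conductance(5, E_rev = -70)
  prot <- build_protocol("step", amplitudes = -50, start = 20,
                         duration = 120, tail = 30)
  tr <- run_closed_loop(cell, list(sh), prot, seed = 2)
  f <- fit_rin_tau(tr, list(onset = 20, duration = 120, amplitude = -50))
  expect_equal(f$R_in, parallel_rin(cell, 5), tolerance = 0.01)   # 143.5 MOhm
  expect_equal(f$R_in, 143.5, tolerance = 0.01)
  expect_equal(f$tau, 5.15, tolerance = 0.02)
})

test_that("I_AMP = I_CC + I_DC holds exactly at every recorded cycle", {
  cell <- ref_cell()
  tr <- run_closed_loop(cell, list(shunt_conductance(5), ou_background()),
                        build_protocol("step", amplitudes = 25, start = 10,
                                       duration = 50, tail = 10),
                        seed = 3)
  expect_equal(max(abs(tr$I_AMP - tr$I_CC - tr$I_DC)), 0)
})

test_that("Vm_read differs from Vm by at most one ADC quantum through the input gain", {
  cell <- ref_cell()
  tr <- run_closed_loop(cell, list(),
                        build_protocol("step", amplitudes = c(-50, 50),
                                       start = 10, duration = 40, gap = 20),
                        seed = 4)
  res <- vm_resolution()    # ADC step / combined gain, in mV
  expect_lt(max(abs(tr$Vm_read - tr$Vm)), res / 2 + 1e-9)
})

test_that("seeded closed-loop runs are bitwise reproducible", {
  cell <- ref_cell()
  args <- list(cell, list(ou_background()),
               build_protocol("step", amplitudes = -20, start = 10,
                              duration = 50, tail = 10))
  t1 <- do.call(run_closed_loop, c(args, seed = 42))
  t2 <- do.call(run_closed_loop, c(args, seed = 42))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- do.call(run_closed_loop, c(args, seed = 43))
  expect_false(identical(t3$Vm, t1$Vm))
})

test_that("with ideal converters and no jitter the loop converges to the coupled-ODE reference", {
  cell <- ref_cell()
  hcn <- hcn_conductance(4)
  I_fun <- function(t) if (t >= 20 && t < 120) -50 else 0
  ref <- rk4_cell_gate(cell, 4, -30, hcn$gates[[1]], I_fun, dt = 0.001,
                       duration = 151)
  prot <- build_protocol("step", amplitudes = -50, start = 20,
                         duration = 100, tail = 30)
  q26 <- quantizer_spec(bits = 26)
  errs <- vapply(c(40, 20, 10), function(mc) {
    tm <- clamp_timing(mean_cycle = mc, jitter_sd = 0, latency_cycles = 0)
    tr <- run_closed_loop(cell, list(hcn), prot, timing = tm, adc = q26,
                          dac = q26, seed = 1, duration = 150)
    vr <- approx(ref$t, ref$V, xout = tr$t, rule = 2)$y
    max(abs(tr$Vm - vr))
  }, 0)
  expect_true(all(diff(errs) < 0))     # error shrinks with the cycle time
  expect_lt(errs[3], 0.02)             # and is small at 10 us
})

test_that("a divergent run halts with a diagnostic flag and a partial trace", {
  cell <- ref_cell()
  # a huge sodium conductance updated at a cycle time far beyond the gate
  # stability limit explodes; the engine must flag, not throw
  na <- na_conductance(g_max = 500)
  tm <- clamp_timing(mean_cycle = 500, jitter_sd = 0)
  prot <- build_protocol("step", amplitudes = 100, start = 5, duration = 200,
                         tail = 0)
  tr <- run_closed_loop(cell, list(na), prot, timing = tm, seed = 5)
  expect_true(trace_meta(tr)$diverged)
  expect_lt(max(tr$t), 205)
  expect_gt(nrow(tr), 0)
})

test_that("invalid timing and quantizer parameters are rejected", {
  expect_error(clamp_timing(mean_cycle = 0))
  expect_error(clamp_timing(mean_cycle = 10, jitter_sd = -1))
  expect_error(clamp_timing(latency_cycles = -1))
  expect_error(quantizer_spec(bits = 0))
  expect_error(quantizer_spec(v_min = 3.3, v_max = 0))
})
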