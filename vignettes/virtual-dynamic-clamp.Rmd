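---
title: "A virtual dynamic-clamp rig: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual dynamic-clamp rig: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualclamp)
```

## The system being modeled

A dynamic-clamp controller sits between an intracellular amplifier and the
cell: every cycle it reads the amplifier's representation of the membrane
potential, computes the current that a set of simulated conductances would
pass at that potential, and writes the command back so the amplifier
injects `I_AMP = I_CC + I_DC` — the current-clamp protocol's current plus
the dynamic-clamp current. `virtualclamp` replaces both sides of that loop
with software. The cell ("plant") is a passive RC circuit; the controller
is a faithful model of a small real-time device: it sees the world only
through a 12-bit ADC behind an imperfect analog map, acts only through a
12-bit DAC behind another imperfect map, runs at a jittered cycle time, is
one cycle late, and integrates channel kinetics with forward Euler.

Everything here is deliberately the *simple* version of each component:
the point is not a better simulator of neurons but a controllable,
fully-instrumented replica of what a budget real-time loop does to
signals, with exact and high-order integrators available as ground truth.

## Units

One internal unit system is used everywhere: mV, pA, nS, ms, pF, with
resistances in MΩ. These are self-consistent up to fixed powers of ten:

* `I[pA] = g[nS] · V[mV]` exactly;
* `V[mV] = I[pA] · R[MΩ] · 1e-3` (a pA across a GΩ is a mV);
* `τ[ms] = R[MΩ] · C[pF] · 1e-3`.

CSV trace headers carry the unit in each column name (`t_ms`, `Vm_mV`,
`I_DC_pA`, `dt_cycle_us`, `g_<label>_nS`), so files are self-describing.

## The plant and its integrator

The model cell is `C dV/dt = (E_rest − V)/R + I(t)`. Between controller
writes the injected current is constant, so the plant is advanced with the
exact exponential update
`V' = V∞ + (V − V∞)·exp(−dt/τ)`, `V∞ = E_rest + I·R·1e-3` — not Euler.
The distinction matters: the forward-Euler approximation belongs to the
*controller* being studied, while the physical cell obeys the true
solution. Using the exact update for the plant keeps controller error and
plant error from being conflated. The default cell (`R = 507.7 MΩ`,
`C = 35.9 pF`, rest −70 mV, τ ≈ 18.2 ms) is the fitted equivalent circuit
of a commercial patch-clamp model cell, which is also why the resistance is
not a round number. Optional series resistance and stray capacitance are
available as a two-compartment linear plant, but default to zero: a rig
compensates them with bridge balance, and the experiments here assume that
has been done.

## The closed loop, cycle by cycle

1. Draw the cycle duration: Gaussian with configurable mean (default
   10 µs) and SD (default 1.5 µs), truncated below at half the mean —
   a cycle cannot take negative time, and sub-half-mean cycles do not
   occur on real hardware either.
2. Advance the plant exactly under the currently applied `I_AMP`.
3. Read the voltage: `Vm → amplifier output (0.1 V per mV) → input
   circuit map → ADC quantization → inverse map → Vm_read`. With the
   default 12-bit converter over 0–3.3 V and the default circuit, one ADC
   count corresponds to 0.055 mV of membrane potential
   (`vm_resolution()`).
4. Update every conductance state with `Vm_read` and the *measured*
   (jittered) cycle time. Gate variables use forward Euler — that is the
   controller's contract, and its instability for `dt > 2τ` must remain
   observable, so clamping gates to [0,1] is off by default. The OU
   conductances use the exact stationary-preserving stochastic update (see
   below).
5. Sum the conductance currents into `I_DC`.
6. Pass `I_DC` through the output map and DAC quantizer (one DAC count ≈
   0.53 pA with the defaults).
7. `I_AMP = I_CC + I_DC` takes effect `latency_cycles` later (default 1).
   Latency is a ring buffer of whole cycles: the command computed from the
   read at cycle *k* starts acting `latency_cycles` cycles after that
   read.

If `|Vm|` ever exceeds 500 mV — or a conductance state overflows to a
non-finite current, which Euler instability can do faster than the voltage
bound trips — the run halts, keeps the partial trace, and sets a
`diverged` flag in the metadata rather than throwing: a blown-up run is a
legitimate experimental observation here.

Reproducibility: one integer seed drives a private Gaussian stream from
which jitter and OU noise draw in a fixed order; runs are bitwise
reproducible and independent of R's global RNG state.

## Conductance kinetics and their defaults

All gated conductances share one relaxation form,
`ds/dt = −(s − s_inf(V))/τ(V)`, with the effective conductance
`g_max · Π s_i^{p_i}`. Kinetics are supplied as R functions, parametric
Boltzmann/bell-shaped forms, or tabulated CSV (linear interpolation, flat
extrapolation). Defaults:

* **HCN**: Boltzmann steady state with half-activation −82 mV and slope
  9 mV (activated by hyperpolarization), bell-shaped τ peaking near 30 ms
  around −70 mV, reversal −30 mV. These are textbook-shaped parameters
  chosen to reproduce the h-current's signatures — sag on hyperpolarizing
  steps and subthreshold resonance — not a fit to any particular cell
  type. The test suite verifies the signatures, not waveform identity.
* **Sodium**: classic Hodgkin–Huxley `m³h` rate functions with a
  configurable voltage shift and a temperature factor (default 3×) that
  brings the activation time constant under 0.5 ms throughout the spike
  voltage range. That speed is the entire point: it makes sodium the
  worst case for a first-order real-time integrator, with a hard Euler
  stability boundary at `dt = 2·min τ_m` (≈ 0.16 ms here).
* **Synapse**: two-stage scheme, `x` incremented by exactly 1 per
  presynaptic spike falling in the cycle window (simultaneous spikes sum),
  `τ_x = 1 ms`, `τ_s = 10 ms`, `α_s = 1 ms⁻¹`, reversal 0 mV — an
  AMPA-like profile whose `s ≤ 1` saturation is built into the equations.
* **M-type potassium** (and any other single-gate conductance) needs no
  code: `gated_conductance()` with one activation gate and `E_rev ≈ −90 mV`
  runs through the same path.

## The synaptic background (point-conductance) model

Two independent OU conductances, excitatory and inhibitory:
`dg/dt = −(g − g0)/τ + √D·χ(t)` with white unit-variance `χ`, stationary
variance `σ² = Dτ/2`. Some presentations write the noise term with
amplitude `D`; only `√D` (units nS·ms^−1/2^) is dimensionally consistent
with a diffusion constant in nS²/ms and with `σ² = Dτ/2`, so `√D` is the
convention implemented, and parameters may be given either as `D` or as
the stationary SD. The single-step update is the exact conditional
law `g' = g0 + (g − g0)e^{−dt/τ} + σ√(1 − e^{−2dt/τ})·N(0,1)`, which keeps
the stationary distribution at any step size; Euler–Maruyama is provided
for cross-checks and as an engine option (`ou_method = "euler"`), but the
exact update is the engine default because it makes the background
statistics independent of the cycle time — the quantity under study is the
loop, not the SDE discretization. Negative conductance excursions are
allowed by default (the SDE is faithful to them); a rectify flag clips at
zero. Defaults `τ_E = 2.7 ms`, `τ_I = 10.5 ms`, `E_E = 0 mV`,
`E_I = −75 mV`, means 4 nS and SDs 0.25 nS follow standard cortical
point-conductance settings.

## Electronics: maps, quantizers, calibration

The amplifier-to-controller map and controller-to-amplifier map are the
ideal closed forms of the two differential-amplifier stages, computed from
the circuit's resistor values (defaults: the reference design,
R1 = 2200 Ω … R17 = 4700 Ω, ±9 V rails). Both are affine; the summing
stage has unit weights by default. Quantizers use the standard mid-tread
convention: codes `0 … 2^bits − 1` at spacing `span/2^bits` (0.8057 mV per
count for 12 bits over 3.3 V), clipping at the rails.

Real components are a few percent off their nominal values, so the package
also models *calibration*: `fit_calibration()` is an ordinary
least-squares line through measured input/output pairs, and
`model_cell_calibration()` recovers both maps from a sweep of commands
against a model cell of known resistance, using the fact that the DAQ
records the true membrane potential independently of the controller. The
fixture generator represents component tolerance abstractly — each
resistor off by exactly ±`perturbation_fraction` with seeded signs, plus
additive Gaussian measurement noise — rather than simulating op-amp
physics; bandwidth, slew-rate and rail behavior of real op-amps are
documented limitations, not simulated effects.

## Analysis choices

* `fit_rin_tau()`: single-exponential Levenberg–Marquardt fit initialized
  from a log-linear regression; `R_in` is the fitted steady deflection
  over the step amplitude.
* `impedance_profile()`: `|Z(f)| = |FFT(V − mean)/FFT(I_CC − mean)|`,
  interpolated to a uniform grid first (closed-loop samples are jittered),
  smoothed with a 0.5 Hz moving average. The current channel is the
  *command* current: dividing by the total injected current would always
  return the passive plant, because that is literally what the total
  current drives. A resonance is reported only when an interior maximum
  exceeds the low-frequency magnitude by ≥ 5 % (`min_gain`); FFT-ratio
  ripple on a flat low-pass profile is ~2 % and would otherwise register
  as spurious structure.
* `vm_stats()`: optional spike clipping removes ±2 ms around upward
  threshold crossings before computing subthreshold statistics.
* `error_stats()`: sample-wise measured-minus-reference statistics, the
  reference being a precise (exact or RK4) integration of the same
  kinetics along the recorded voltage.

## Verification strategy and problem sizes

Every approximation in the controller has an oracle: the exact gate
stepper (closed-form relaxation, semigroup property at machine precision),
RK4 at 10 µs (agreeing with exact to <0.1 % at the sodium-current peak),
and an independent RK4 integration of the coupled cell+conductance ODEs to
which the full closed loop converges as quantization, jitter, latency and
cycle time are removed. Euler's global error measurably scales as O(dt)
and measurably diverges past `dt = 2τ`.

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in about a minute: closed-loop runs of 0.5–8 s of
simulated time at 10–50 µs cycles (10⁴–10⁶ cycles), OU statistics on 10⁶
steps, spectra on 2¹⁸ samples. The input-resistance measurement under
synaptic background repeats a −20 pA, 500 ms step over a family of sweeps
and averages the per-sweep deflections, exactly as one would on a rig:
the deflection is ~2 mV against ~1 mV of synaptic fluctuation, so a
single sweep estimates the conductance ratio with double-digit percent
error, while sweep-averaging brings the estimate to a few percent.

## What the synthetic data do and do not show

The generator reproduces the *conditions* of the reference experiments —
the fitted RC cell, the printed conductance settings, component tolerance
of a few percent, measurement noise — deterministically from a seed, with
the generating truth recorded in a manifest so recovery tests have an
answer key. It does not emulate electrode artifacts (pipette capacitance
transients, bridge imbalance), amplifier dynamics, op-amp nonideality
beyond an affine offset, or spiking plants: passing tests demonstrate that
the controller logic and numerics are correct and that the analysis
pipeline recovers known parameters under realistic noise, not that any
particular biological neuron would behave identically.

## Known limitations

* The plant is passive and linear; active (spiking) cells are exercised
  only through voltage-clamp protocols of the sodium model.
* Hardware timing figures (throughput, absolute latency in µs) are
  emulated parameters, not measurements; nothing here benchmarks a CPU.
* HCN/Na kinetic parameters are representative defaults, overridable but
  not fitted to a specific preparation.
* The calibration model treats all circuit error as affine plus noise;
  genuinely nonlinear component behavior is out of scope.
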