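# virtualclamp

A fully software "virtual rig" for dynamic-clamp electrophysiology.

Dynamic clamp closes a loop between a neuron and a computer: the amplifier
reports the membrane potential `Vm` in real time, the computer calculates
the current a simulated ion channel would pass,

```
I = -g(t) * (Vm - E_rev),
```

and that current is injected back into the cell on top of whatever the
current-clamp protocol commands (`I_AMP = I_CC + I_DC`). Microcontroller
implementations of this loop are attractive because they are cheap and
fast, but they impose real constraints — 12-bit ADC/DAC quantization,
imperfect analog voltage maps that need empirical calibration, cycle-time
jitter, a one-cycle latency, and first-order (forward Euler) integration of
the channel kinetics. `virtualclamp` re-creates that entire loop in
software: a passive RC model cell (the plant) is simulated exactly, while a
clamp engine reads a quantized, calibrated estimate of `Vm` each cycle and
injects conductance currents through the same imperfections a physical
controller would have. Because everything is simulated, every approximation
can be checked against an analytic or high-order oracle.

The package is for electrophysiologists and methods developers who want to
understand — or teach — what a dynamic-clamp controller actually does to
their signals before trusting one on a rig.

## What is simulated

* **Model cell** — RC circuit with the reference fitted values
  R = 507.7 MΩ, C = 35.9 pF (τ = 18.2 ms), advanced with the exact
  exponential update between controller cycles.
* **Conductances** — constant shunt; HCN (single activation gate,
  hyperpolarization-activated, producing sag and subthreshold resonance);
  transient sodium `g_Na m³h` with Hodgkin–Huxley kinetics (τ_m < 0.5 ms);
  a two-stage kinetic AMPA-type synapse driven by TTL-style spike times
  (`dx/dt = -x/τ_x + Σδ(t-t_i)`, `ds/dt = -s/τ_s + α_s x (1-s)`); and the
  Ornstein–Uhlenbeck point-conductance background
  (`dg/dt = -(g-g0)/τ + √D χ(t)`, stationary variance `Dτ/2`) as an
  excitatory/inhibitory pair. An M-type potassium conductance is just a
  configuration of the same gate machinery.
* **Electronics** — the ±9 V ↔ 0–3.3 V differential-amplifier maps (ideal
  closed forms from the circuit's resistor values, or empirically fitted
  lines), the summing stage, 12-bit ADC/DAC quantization, Gaussian
  cycle-time jitter and whole-cycle latency.
* **Integrators** — forward Euler (the controller's method), RK4 and exact
  closed-form steppers for every gate, so Euler's O(dt) error and its
  instability beyond `dt > 2τ` are measurable, reproducible facts.

## Worked example: a 5 nS shunt cuts the input resistance

```r
library(virtualclamp)

cell  <- membrane_params(R_m = 507.7, C_m = 35.9, E_rest = -70)
shunt <- shunt_conductance(5, E_rev = -70)               # 5 nS leak
prot  <- build_protocol("step", amplitudes = -50, start = 20,
                        duration = 120, tail = 30)

tr  <- run_closed_loop(cell, list(shunt), prot, seed = 1)
fit <- fit_rin_tau(tr, list(onset = 20, duration = 120, amplitude = -50))
```

Output of the fit, against the parallel-conductance prediction
`1/(1/507.7 MΩ + 5 nS)`:

```
R_in = 143.9 MOhm (bare cell: 507.7; predicted with 5 nS shunt: 143.5)
tau  = 5.16 ms  (bare cell: 18.23)
cycles: 17015, mean cycle 10.0 us, Vm resolution 0.0550 mV
```

The simulated controller recovers the predicted input resistance to 0.3 %
through its quantized, jittered, one-cycle-latent loop. Swapping the shunt
for `hcn_conductance(4)` and the step for a chirp
(`build_protocol("chirp", ...)`) turns the low-pass cell into a bandpass
resonator (`impedance_profile()` reports the resonance frequency);
`ou_background()` reproduces the in-vivo-like high-conductance state.

There is also a thin command line (installed under `exec/`):

```sh
dynaclamp fixtures --kind figure_experiment --experiment fig4_shunt --dir fx
dynaclamp simulate --config fx/config.json --seed 1 --out trace.csv
dynaclamp analyze rin --trace trace.csv --amplitude -50 --out rin.json
dynaclamp voltage-step --method euler --dt-us 12 --jitter-us 2 --out na.csv
```

## Layout

| Path | Contents |
| --- | --- |
| `R/cell-model.R` | RC plant, exact membrane update, open-loop simulation |
| `R/conductances.R` | gate kinetics, shunt/HCN/Na/EPSC models, Euler/RK4/exact steppers |
| `R/noise-ou.R` | OU background pair, seed-reproducible Gaussian streams |
| `R/clamp-engine.R` | quantizers, timing model, the closed loop |
| `R/calibration.R` | circuit maps, OLS and model-cell calibration |
| `R/stimuli.R` | step/ramp/chirp/train protocols |
| `R/analysis.R` | R_in/τ fits, impedance and resonance, error and Vm statistics |
| `R/fixtures.R` | deterministic synthetic inputs + experiment configs |
| `R/trace-io.R`, `R/cli.R` | CSV/JSON formats, configuration schema, CLI |
| `vignettes/` | methods notes: model, numerics, design choices, limits |
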