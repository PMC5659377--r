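Package: virtualclamp
Title: Virtual Dynamic-Clamp Rig for a Passive Model Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully software re-creation of a microcontroller dynamic-clamp
    electrophysiology rig. A passive RC model cell is simulated in closed loop
    with a dynamic-clamp engine that reads a quantized, calibrated estimate of
    the membrane potential every cycle and injects the current that simulated
    conductances (shunt, HCN, transient sodium, two-stage kinetic EPSC, and
    Ornstein-Uhlenbeck synaptic background) would have passed. The package
    models the rig's 12-bit ADC/DAC quantization, linear amplifier/controller
    voltage maps with empirical calibration, cycle-time jitter and one-cycle
    latency, and provides forward-Euler, Runge-Kutta and exact integrators so
    the real-time numerics can be verified against analytic oracles. Analysis
    tools recover input resistance and membrane time constant from step
    responses, impedance and resonance from chirp (ZAP) responses, and
    subthreshold membrane-potential statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
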