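# Stimulus protocols: families of current steps, slow ramps, chirp (ZAP)
# sweeps and fixed-rate spike trains (TTL emulation for the kinetic synapse).

#' Build a stimulus protocol
#'
#' Constructs the current-clamp command waveform `I_CC(t)` and, for synaptic
#' experiments, the list of presynaptic spike times.  Protocols are stored as
#' an ordered list of non-overlapping segments plus a baseline current that
#' applies outside all segments.
#'
#' Supported kinds:
#' \describe{
#'   \item{step}{`amplitudes` (pA, one segment per amplitude), `duration`
#'     (ms), `start` (ms, onset of the first step) and `gap` (ms between
#'     consecutive steps).  A family of steps becomes consecutive segments
#'     separated by `gap`, as on a rig running one sweep after another.}
#'   \item{ramp}{`rate` (pA/s) and `duration` (ms), starting at `start`.}
#'   \item{chirp}{sinusoid whose instantaneous frequency sweeps linearly from
#'     `f0` to `f1` (Hz) over `duration` ms, with amplitude `amplitude` (pA).}
#'   \item{train}{TTL-style spike train: `rate` (Hz) and `count` spikes at
#'     times `start + k/rate`, `k = 0..count-1`.  Contributes no current.}
#'   \item{custom}{arbitrary waveform: data frame `waveform` with columns
#'     `t_ms` and `I_pA`, linearly interpolated, flat extrapation.}
#' }
#'
#' @param kind One of `"step"`, `"ramp"`, `"chirp"`, `"train"`, `"custom"`.
#' @param amplitudes,duration,start,gap,rate,count,f0,f1,amplitude,waveform
#'   Kind-specific parameters, see Details.
#' @param baseline_current Holding current (pA) outside all segments.
#' @param tail Extra recording time (ms) appended after the last segment.
#' @return An object of class `stimulus_protocol` with fields `segments`,
#'   `spike_times`, `baseline_current` and `duration`.
#' @examples
#' build_protocol("step", amplitudes = seq(-50, 50, 25), duration = 100)
#' build_protocol("train", rate = 50, count = 10)
#' @export
build_protocol <- function(kind, amplitudes = NULL, duration = NULL,
                           start = 20, gap = 50, rate = NULL, count = NULL,
                           f0 = 0, f1 = 15, amplitude = 20, waveform = NULL,
                           baseline_current = 0, tail = 50) {
  kind <- match.arg(kind, c("step", "ramp", "chirp", "train", "custom"))
  if (start < 0 || gap < 0 || tail < 0) stop("negative times are not allowed")
  segments <- list()
  spike_times <- numeric(0)
  end <- start
  switch(kind,
    step = {
      if (is.null(amplitudes) || is.null(duration) || duration <= 0)
        stop("step protocol needs amplitudes and a positive duration")
      t0 <- start
      for (a in amplitudes) {
        segments[[length(segments) + 1L]] <-
          list(kind = "step", start = t0, duration = duration,
               params = list(amplitude = a))
        t0 <- t0 + duration + gap
      }
      end <- t0 - gap
    },
    ramp = {
      if (is.null(rate) || is.null(duration) || duration <= 0)
        stop("ramp protocol needs rate (pA/s) and a positive duration")
      segments[[1L]] <- list(kind = "ramp", start = start, duration = duration,
                             params = list(rate = rate))
      end <- start + duration
    },
    chirp = {
      if (is.null(duration) || duration <= 0 || amplitude < 0 ||
          f0 < 0 || f1 < 0)
        stop("chirp protocol needs a positive duration and non-negative f0, f1, amplitude")
      segments[[1L]] <- list(kind = "chirp", start = start, duration = duration,
                             params = list(f0 = f0, f1 = f1,
                                           amplitude = amplitude))
      end <- start + duration
    },
    train = {
      if (is.null(rate) || is.null(count) || rate <= 0 || count < 1)
        stop("train protocol needs a positive rate (Hz) and count")
      spike_times <- start + (seq_len(count) - 1L) * 1000 / rate
      end <- max(spike_times)
    },
    custom = {
      if (is.null(waveform) || !all(c("t_ms", "I_pA") %in% names(waveform)))
        stop("custom protocol needs a waveform with columns t_ms and I_pA")
      segments[[1L]] <- list(kind = "custom", start = min(waveform$t_ms),
                             duration = diff(range(waveform$t_ms)),
                             params = list(waveform = waveform[order(waveform$t_ms), ]))
      end <- max(waveform$t_ms)
    })
  structure(list(segments = segments, spike_times = spike_times,
                 baseline_current = baseline_current,
                 duration = end + tail),
            class = "stimulus_protocol")
}

#' Evaluate the command current of a protocol
#'
#' Piecewise evaluation of `I_CC(t)`: inside a segment the segment's waveform
#' applies (added to the baseline); outside all segments the baseline current
#' is returned.  The chirp phase is the exact integral of the linearly swept
#' instantaneous frequency, so the waveform is phase-continuous.
#'
#' @param protocol A [build_protocol()] object.
#' @param t Time or vector of times (ms), non-negative.
#' @return Current (pA), same length as `t`.
#' @export
protocol_current <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"), all(t >= 0))
  I <- rep(protocol$baseline_current, length(t))
  for (seg in protocol$segments) {
    idx <- t >= seg$start & t < seg$start + seg$duration
    if (!any(idx)) next
    tt <- t[idx] - seg$start
    I[idx] <- I[idx] + switch(seg$kind,
      step = seg$params$amplitude,
      ramp = seg$params$rate * tt / 1000,  # pA/s * ms -> pA
      chirp = {
        p <- seg$params
        ts <- tt / 1000                      # seconds
        Tt <- seg$duration / 1000
        phase <- 2 * pi * (p$f0 * ts + (p$f1 - p$f0) * ts^2 / (2 * Tt))
        p$amplitude * sin(phase)
      },
      custom = {
        w <- seg$params$waveform
        stats::approx(w$t_ms, w$I_pA, xout = tt + seg$start, rule = 2)$y
      })
  }
  I
}

#' Analytic chirp phase (cycles) at time t within a chirp segment
#'
#' The accumulated phase divided by 2*pi equals the time integral of the
#' instantaneous frequency; exposed for phase-continuity checks.
#'
#' @param f0,f1 Sweep endpoints (Hz).
#' @param duration Sweep duration (ms).
#' @param t Time from sweep onset (ms).
#' @return Accumulated cycles at `t`.
#' @export
chirp_cycles <- function(f0, f1, duration, t) {
  ts <- t / 1000; Tt <- duration / 1000
  f0 * ts + (f1 - f0) * ts^2 / (2 * Tt)
}

#' Serialize / restore a protocol
#'
#' `protocol_to_list()` turns a protocol into plain lists suitable for JSON;
#' `protocol_from_list()` inverts it.  Round-tripping preserves the protocol.
#'
#' @param protocol A `stimulus_protocol`.
#' @return A plain list (`protocol_to_list`) or a `stimulus_protocol`
#'   (`protocol_from_list`).
#' @export
protocol_to_list <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  out <- unclass(protocol)
  out$segments <- lapply(out$segments, function(s) {
    if (s$kind == "custom") s$params$waveform <- as.list(s$params$waveform)
    s
  })
  out
}

#' @rdname protocol_to_list
#' @param x A plain list as produced by `protocol_to_list()`.
#' @export
protocol_from_list <- function(x) {
  x$segments <- lapply(x$segments, function(s) {
    if (s$kind == "custom") s$params$waveform <- as.data.frame(s$params$waveform)
    s
  })
  x$spike_times <- as.numeric(x$spike_times)
  structure(x[c("segments", "spike_times", "baseline_current", "duration")],
            class = "stimulus_protocol")
}
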