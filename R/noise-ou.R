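# Ornstein-Uhlenbeck synaptic background ("point conductance" model): two
# independent mean-reverting Gaussian conductance trains, one excitatory and
# one inhibitory,
#   dg/dt = -(g - g0)/tau + sqrt(D) * chi(t),
# with chi white Gaussian noise of unit spectral density, so the stationary
# variance is D*tau/2.  Note on conventions: the noise term is sometimes
# written with amplitude D rather than sqrt(D); only sqrt(D) (units
# nS/sqrt(ms)) is dimensionally consistent with a diffusion constant D in
# nS^2/ms and the stationary variance D*tau/2, so that is the convention
# implemented here.

#' Ornstein-Uhlenbeck conductance parameters
#'
#' @param g0 Mean conductance (nS).
#' @param tau Correlation time (ms), positive.
#' @param D Diffusion constant (nS^2/ms), non-negative.  Exactly one of `D`
#'   and `sd` must be given; they are related by `sd^2 = D * tau / 2`.
#' @param sd Stationary standard deviation (nS), alternative to `D`.
#' @param E_rev Reversal potential (mV).
#' @param rectify Clip negative conductance excursions at zero?  Off by
#'   default: the SDE itself allows transiently negative conductances.
#' @return An object of class `ou_params`.  The stationary SD is always
#'   derived via [ou_stationary_sd()], never stored.
#' @examples
#' pe <- ou_params(g0 = 4, tau = 2.7, sd = 0.25, E_rev = 0)
#' ou_stationary_sd(pe)
#' @export
ou_params <- function(g0, tau, D = NULL, sd = NULL, E_rev = 0,
                      rectify = FALSE) {
  stopifnot(is.finite(g0), is.finite(tau), tau > 0, is.finite(E_rev))
  if (is.null(D) && is.null(sd)) stop("give either D or sd")
  if (!is.null(D) && !is.null(sd)) stop("give only one of D and sd")
  if (is.null(D)) D <- 2 * sd^2 / tau
  stopifnot(D >= 0)
  structure(list(g0 = g0, tau = tau, D = D, E_rev = E_rev,
                 rectify = isTRUE(rectify)),
            class = "ou_params")
}

#' Stationary standard deviation of an OU conductance
#'
#' @param params An [ou_params()] object.
#' @return `sqrt(D * tau / 2)` in nS.
#' @export
ou_stationary_sd <- function(params) sqrt(params$D * params$tau / 2)

#' Seed-reproducible stream of unit Gaussian deviates
#'
#' Returns a generator function `f(n)` producing standard-normal draws from a
#' private RNG state seeded once with `seed`.  Streams are independent of the
#' global RNG and of each other: the same seed always yields the bitwise
#' identical sequence, regardless of what other code draws in between.
#'
#' @param seed Integer seed.
#' @return A function of `n` returning `n` N(0,1) deviates.
#' @examples
#' g <- gaussian_stream(42)
#' identical(g(5), gaussian_stream(42)(5))
#' @export
gaussian_stream <- function(seed) {
  state <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  function(n = 1L) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    assign(".Random.seed", state, globalenv())
    x <- stats::rnorm(n)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
}

#' One Ornstein-Uhlenbeck step
#'
#' Default is the exact stationary-preserving update
#' `g' = g0 + (g - g0) exp(-dt/tau) + sqrt(D tau/2 (1 - exp(-2 dt/tau))) z`
#' with `z ~ N(0,1)`, which has the correct conditional mean and variance at
#' any step size.  The Euler-Maruyama variant
#' `g' = g - (g - g0) dt/tau + sqrt(D dt) z` is provided for cross-checks
#' against the real-time controller's first-order scheme.
#'
#' @param g Current conductance (nS).
#' @param dt Step (ms), positive.
#' @param params An [ou_params()] object.
#' @param rng A [gaussian_stream()] generator.
#' @param method `"exact"` or `"euler"`.
#' @return Updated conductance (nS); clipped at zero if `params$rectify`.
#' @export
ou_step <- function(g, dt, params, rng, method = c("exact", "euler")) {
  stopifnot(dt > 0)
  method <- match.arg(method)
  g2 <- if (method == "exact") {
    a <- exp(-dt / params$tau)
    sd_step <- sqrt(params$D * params$tau / 2 * (1 - a * a))
    params$g0 + (g - params$g0) * a +
      (if (sd_step > 0) sd_step * rng(1L) else 0)
  } else {
    g - (g - params$g0) * dt / params$tau +
      (if (params$D > 0) sqrt(params$D * dt) * rng(1L) else 0)
  }
  if (params$rectify) max(0, g2) else g2
}

#' Simulate a long OU conductance trace
#'
#' Vectorized recursion (exact update at fixed `dt`) for statistical checks:
#' stationary variance, autocorrelation, power spectrum.
#'
#' @param params An [ou_params()] object.
#' @param n Number of steps.
#' @param dt Step (ms).
#' @param seed Integer seed (a fresh [gaussian_stream()] is created), or a
#'   generator function.
#' @param g_init Initial value; defaults to `g0`.
#' @param method `"exact"` or `"euler"`.
#' @return Numeric vector of length `n + 1` (including the initial value).
#' @export
ou_simulate <- function(params, n, dt, seed = 1L, g_init = params$g0,
                        method = c("exact", "euler")) {
  method <- match.arg(method)
  rng <- if (is.function(seed)) seed else gaussian_stream(seed)
  z <- rng(n)
  if (method == "exact") {
    a <- exp(-dt / params$tau)
    sd_step <- sqrt(params$D * params$tau / 2 * (1 - a * a))
    drive <- (1 - a) * params$g0 + sd_step * z
  } else {
    a <- 1 - dt / params$tau
    drive <- params$g0 * dt / params$tau + sqrt(params$D * dt) * z
  }
  g <- stats::filter(drive, a, method = "recursive", init = g_init)
  out <- c(g_init, as.numeric(g))
  if (params$rectify) pmax(0, out) else out
}

#' OU background conductance pair
#'
#' The point-conductance model of synaptic bombardment: one excitatory and
#' one inhibitory OU conductance, stepped independently.  Defaults follow
#' common cortical point-conductance settings: correlation times 2.7 ms (E)
#' and 10.5 ms (I), reversals 0 mV (E) and -75 mV (I).
#'
#' @param gE0,gI0 Mean conductances (nS).
#' @param sE,sI Stationary SDs (nS); alternatively give `DE`, `DI`.
#' @param DE,DI Diffusion constants (nS^2/ms).
#' @param tauE,tauI Correlation times (ms).
#' @param EE,EI Reversal potentials (mV).
#' @param rectify Clip negative conductances at zero?
#' @param label Trace column label.
#' @return A [conductance_spec()] of kind `"ou_pair"`.
#' @export
ou_background <- function(gE0 = 4, gI0 = 4, sE = NULL, sI = NULL,
                          DE = NULL, DI = NULL, tauE = 2.7, tauI = 10.5,
                          EE = 0, EI = -75, rectify = FALSE, label = "ou") {
  if (is.null(sE) && is.null(DE)) sE <- 0.25
  if (is.null(sI) && is.null(DI)) sI <- 0.25
  conductance_spec("ou_pair",
                   ou = list(E = ou_params(gE0, tauE, D = DE, sd = sE,
                                           E_rev = EE, rectify = rectify),
                             I = ou_params(gI0, tauI, D = DI, sd = sI,
                                           E_rev = EI, rectify = rectify)),
                   label = label)
}
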