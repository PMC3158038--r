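#' AdEx neuron parameters
#'
#' Parameter set for the adaptive exponential integrate-and-fire (AdEx)
#' neuron. The membrane follows
#' \deqn{C\,dV/dt = -g_L (V - E_L) + g_L \Delta_T e^{(V-V_T)/\Delta_T} - w + I,}
#' \deqn{\tau_w\,dw/dt = a (V - E_L) - w,}
#' and when `V` crosses the numerical detection cutoff a spike is emitted,
#' `V` is reset and `w` is incremented by `b`.
#'
#' Defaults are the regular-spiking cortical parameter set stored in the
#' package defaults file (see [ssanetDefaults()]).
#'
#' @param capacitance Membrane capacitance C (pF).
#' @param leakConductance Leak conductance g_L (nS).
#' @param leakReversal Leak reversal E_L (mV).
#' @param slopeFactor Spike-initiation slope factor Delta_T (mV).
#' @param threshold Effective threshold V_T (mV).
#' @param tauAdaptation Adaptation time constant tau_w (ms).
#' @param adaptationCoupling Subthreshold adaptation coupling a (nS).
#' @param adaptationIncrement Spike-triggered adaptation increment b (pA).
#' @param reset Post-spike reset potential (mV).
#' @param cutoff Numerical spike-detection cutoff (mV); must exceed the
#'   effective threshold.
#' @return A list of class `AdExParams`.
#' @export
#' @examples
#' p <- adexParams()
#' s <- adexState(p$leakReversal, 0)
#' adexStep(s, p, inputCurrent = 0)   # resting fixed point
adexParams <- function(capacitance = NULL, leakConductance = NULL,
                       leakReversal = NULL, slopeFactor = NULL,
                       threshold = NULL, tauAdaptation = NULL,
                       adaptationCoupling = NULL, adaptationIncrement = NULL,
                       reset = NULL, cutoff = NULL) {
  d <- ssanetDefaults()$adex
  p <- list(
    capacitance = capacitance %||% d$capacitance,
    leakConductance = leakConductance %||% d$leak_conductance,
    leakReversal = leakReversal %||% d$leak_reversal,
    slopeFactor = slopeFactor %||% d$slope_factor,
    threshold = threshold %||% d$threshold,
    tauAdaptation = tauAdaptation %||% d$tau_adaptation,
    adaptationCoupling = adaptationCoupling %||% d$adaptation_coupling,
    adaptationIncrement = adaptationIncrement %||% d$adaptation_increment,
    reset = reset %||% d$reset,
    cutoff = cutoff %||% d$cutoff)
  .check(p$capacitance > 0 && p$leakConductance > 0 &&
           p$tauAdaptation > 0 && p$slopeFactor > 0,
         "capacitance, conductances, time constants and slope factor must be > 0")
  .check(p$cutoff > p$threshold, "cutoff must exceed the effective threshold")
  structure(p, class = "AdExParams")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' AdEx neuron state
#'
#' @param v Membrane potential (mV).
#' @param w Adaptation current (pA).
#' @return A named numeric vector of class `AdExState`.
#' @export
adexState <- function(v, w = 0) {
  structure(c(v = as.numeric(v), w = as.numeric(w)), class = "AdExState")
}

#' Advance an AdEx neuron by one time step
#'
#' Forward-Euler update of the AdEx membrane and adaptation equations. If
#' the membrane potential reaches the detection cutoff the neuron spikes
#' within the same step: the potential is set to the reset value and the
#' adaptation current is incremented.
#'
#' @param state An [adexState()].
#' @param params An [adexParams()].
#' @param inputCurrent Input current (pA).
#' @param dt Time step (ms); must lie in (0, 1].
#' @return A list with elements `state` (the new [adexState()]) and `spike`
#'   (logical).
#' @export
adexStep <- function(state, params, inputCurrent = 0, dt = 0.1) {
  .check(dt > 0 && dt <= 1, "dt must lie in (0, 1] ms")
  v <- state[["v"]]; w <- state[["w"]]
  # cap the exponential argument: beyond the cutoff the trajectory is
  # replaced by the reset rule anyway, so the cap never changes spike times
  ex <- params$leakConductance * params$slopeFactor *
    exp(min((v - params$threshold) / params$slopeFactor, 30))
  dv <- (-params$leakConductance * (v - params$leakReversal) + ex - w +
           inputCurrent) / params$capacitance
  dw <- (params$adaptationCoupling * (v - params$leakReversal) - w) /
    params$tauAdaptation
  v2 <- v + dt * dv
  w2 <- w + dt * dw
  if (!is.finite(v2) || !is.finite(w2))
    stop("AdEx state became non-finite: dt too large for the input regime",
         call. = FALSE)
  spike <- v2 >= params$cutoff
  if (spike) {
    v2 <- params$reset
    w2 <- w2 + params$adaptationIncrement
  }
  list(state = adexState(v2, w2), spike = spike)
}

#' Poisson spike emission
#'
#' Draws whether a Poisson unit with the given rate fires within one step.
#' The per-step spike probability is `1 - exp(-rate * dt / 1000)`; `dt`
#' should be chosen so this stays well below 0.1.
#'
#' @param rate Firing rate (Hz), scalar or vector; must be non-negative.
#' @param dt Time step (ms).
#' @return Logical, `TRUE` where a spike occurred (vectorised over `rate`).
#' @export
poissonSpike <- function(rate, dt = 0.1) {
  .check(all(rate >= 0), "rate must be non-negative")
  .check(dt > 0, "dt must be positive")
  runif(length(rate)) < 1 - exp(-rate * dt / 1000)
}

#' Background-noise (point-conductance) parameters
#'
#' Two-channel Ornstein-Uhlenbeck conductance noise emulating in-vivo-like
#' synaptic background activity: an excitatory and an inhibitory conductance
#' each relax towards a mean with their own correlation time constant while
#' being driven by white noise with a configured stationary standard
#' deviation. The resulting current is scaled by a surface-area factor.
#'
#' Presets shipped in the defaults file: `"high_spontaneous"` (AB/ABC
#' models; excitatory sigma calibrated for ~5 Hz spontaneous firing),
#' `"low_spontaneous"` (ABD model; membrane fluctuations but few spontaneous
#' spikes) and `"none"`.
#'
#' @param preset Preset name, or `NULL` to use only the explicit arguments.
#' @param ge0,gi0 Mean excitatory/inhibitory conductances (nS).
#' @param sige,sigi Stationary conductance standard deviations (nS).
#' @param taue,taui Correlation time constants (ms).
#' @param Ee,Ei Reversal potentials (mV).
#' @param scale Surface-area scaling factor applied to the summed current.
#' @return A list of class `OUNoiseParams`.
#' @export
ouNoiseParams <- function(preset = "high_spontaneous", ge0 = NULL, gi0 = NULL,
                          sige = NULL, sigi = NULL, taue = NULL, taui = NULL,
                          Ee = NULL, Ei = NULL, scale = NULL) {
  d <- if (is.null(preset)) list() else {
    all <- ssanetDefaults()$noise
    .check(preset %in% names(all),
           sprintf("unknown noise preset '%s' (have: %s)", preset,
                   paste(names(all), collapse = ", ")))
    all[[preset]]
  }
  p <- list(ge0 = ge0 %||% d$ge0 %||% 0, gi0 = gi0 %||% d$gi0 %||% 0,
            sige = sige %||% d$sige %||% 0, sigi = sigi %||% d$sigi %||% 0,
            taue = taue %||% d$taue %||% 2.728,
            taui = taui %||% d$taui %||% 10.49,
            Ee = Ee %||% d$Ee %||% 0, Ei = Ei %||% d$Ei %||% -75,
            scale = scale %||% d$scale %||% 1)
  .check(p$sige >= 0 && p$sigi >= 0, "noise sigmas must be >= 0")
  .check(p$taue > 0 && p$taui > 0, "noise time constants must be > 0")
  .check(p$scale > 0, "scale factor must be > 0")
  structure(p, class = "OUNoiseParams")
}

#' Background-noise state
#' @param ge,gi Current excitatory/inhibitory conductances (nS).
#' @return Named numeric vector of class `OUNoiseState`.
#' @export
ouNoiseState <- function(ge, gi) {
  structure(c(ge = as.numeric(ge), gi = as.numeric(gi)), class = "OUNoiseState")
}

#' Advance the background-noise conductances one step
#'
#' Exact discretisation of the Ornstein-Uhlenbeck process: each conductance
#' relaxes to its mean with its correlation time constant and has stationary
#' standard deviation equal to the configured sigma. Conductances are not
#' clipped at zero (the point-conductance model admits negative excursions)
#' unless `clip = TRUE`.
#'
#' @param state An [ouNoiseState()].
#' @param params An [ouNoiseParams()].
#' @param dt Time step (ms).
#' @param clip Clip conductances at zero after the update (default `FALSE`).
#' @return The new [ouNoiseState()].
#' @export
ouNoiseStep <- function(state, params, dt = 0.1, clip = FALSE) {
  .check(dt > 0, "dt must be positive")
  ae <- exp(-dt / params$taue)
  ai <- exp(-dt / params$taui)
  z <- rnorm(2)
  ge <- params$ge0 + (state[["ge"]] - params$ge0) * ae +
    params$sige * sqrt(1 - ae^2) * z[1]
  gi <- params$gi0 + (state[["gi"]] - params$gi0) * ai +
    params$sigi * sqrt(1 - ai^2) * z[2]
  if (clip) { ge <- max(ge, 0); gi <- max(gi, 0) }
  ouNoiseState(ge, gi)
}

#' Noise current from the background conductances
#'
#' Converts the two conductances into a membrane current,
#' `scale * (ge * (Ee - V) + gi * (Ei - V))` (pA).
#'
#' @param state An [ouNoiseState()].
#' @param params An [ouNoiseParams()].
#' @param membranePotential Postsynaptic membrane potential (mV).
#' @return Current (pA).
#' @export
noiseCurrent <- function(state, params, membranePotential) {
  params$scale * (state[["ge"]] * (params$Ee - membranePotential) +
                    state[["gi"]] * (params$Ei - membranePotential))
}

#' Calibrate the excitatory noise sigma to a target spontaneous rate
#'
#' Simulates an unconnected AdEx unit under the background noise for a grid
#' of excitatory sigma values and returns the sigma whose spontaneous firing
#' rate is closest to the target (with the full sigma/rate table attached).
#' Used to construct the `"high_spontaneous"` preset.
#'
#' @param targetRate Desired spontaneous rate (Hz).
#' @param sige Grid of excitatory sigma values to try (nS).
#' @param duration Simulated time per grid point (ms).
#' @param preset Noise preset supplying the remaining parameters.
#' @param seed RNG seed.
#' @return The selected sigma (numeric) with attribute `table`, a
#'   `data.frame` of sigma and measured rate.
#' @export
calibrateNoiseSigma <- function(targetRate, sige = seq(3, 15, by = 2),
                                duration = 20000, preset = "low_spontaneous",
                                seed = 1L) {
  rates <- vapply(seq_along(sige), function(i) {
    np <- ouNoiseParams(preset, sige = sige[i])
    spontaneousRate(np, duration = duration, seed = seed + i)
  }, numeric(1))
  tab <- data.frame(sige = sige, rate = rates)
  best <- sige[which.min(abs(rates - targetRate))]
  structure(best, table = tab)
}

#' Spontaneous firing rate of a noise-driven AdEx unit
#'
#' @param noiseParams An [ouNoiseParams()].
#' @param adex An [adexParams()].
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param seed RNG seed.
#' @return Firing rate (Hz).
#' @export
spontaneousRate <- function(noiseParams, adex = adexParams(),
                            duration = 20000, dt = 0.1, seed = 1L) {
  net <- buildNetwork(architectureSpec(
    "AB", nB = 1L, nSub = 1L, octaveSpan = 2,
    weights = c(AtoB = 0), noisePreset = NULL, seed = seed))
  net@noise <- unclass(noiseParams)
  net@adex <- unclass(adex)
  seq1 <- toneSequence(0, duration, 0, "standard", ioi = duration,
                       protocol = "silence")
  rec <- simulateNetwork(net, seq1, dt = dt, seed = seed)
  nrow(spikeEvents(rec, "B")) / duration * 1000
}
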