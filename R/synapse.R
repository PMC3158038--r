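#' Kinetic synapse parameters
#'
#' Parameter set for the three synapse classes: fast excitatory, fast
#' inhibitory, and fast excitatory with rapid depression and slow recovery.
#' All three share one kinetic scheme in which a unit supply of transmitter
#' resource is divided among three pools: recovered (R), effective (E) and
#' inactive (I). A presynaptic spike opens a square transmitter pulse of
#' fixed duration; while the pulse is open, resource transfers R -> E at
#' rate `R / tauRise`; at all times E -> I at rate `E / tauDecay` and
#' I -> R at rate `I / tauRec`. The non-depressing classes are the same
#' scheme with instantaneous I -> R return, so depression is governed
#' entirely by `tauRec`.
#'
#' Pathway presets (`"AtoB"`, `"AtoC"`, `"CtoB"`, `"BtoD"`) come from the
#' defaults file; explicit arguments override preset values.
#'
#' @param class Synapse class: `"depressing"`, `"excitatory"` or
#'   `"inhibitory"`.
#' @param pathway Optional pathway preset name.
#' @param tauRise Rise (R -> E transfer) time constant (ms).
#' @param tauDecay Decay (E -> I) time constant (ms).
#' @param tauRec Recovery (I -> R) time constant (ms); ignored (instantaneous
#'   return) for the non-depressing classes.
#' @param pulse Transmitter pulse duration (ms).
#' @param reversal Synaptic reversal potential (mV).
#' @param weight Maximal efficacy (nS).
#' @return A list of class `KineticSynapseParams`.
#' @export
#' @examples
#' p <- synapseParams("depressing", pathway = "AtoB")
#' st <- synapseState()
#' st <- synapseStep(st, p, presynSpike = TRUE)
synapseParams <- function(class = c("depressing", "excitatory", "inhibitory"),
                          pathway = NULL, tauRise = NULL, tauDecay = NULL,
                          tauRec = NULL, pulse = NULL, reversal = NULL,
                          weight = NULL) {
  d <- list()
  if (!is.null(pathway)) {
    all <- ssanetDefaults()$synapses
    .check(pathway %in% names(all),
           sprintf("unknown synapse pathway preset '%s'", pathway))
    d <- all[[pathway]]
    if (missing(class)) class <- d$class
  }
  class <- match.arg(class)
  p <- list(class = class,
            tauRise = tauRise %||% d$tau_rise %||% 0.91,
            tauDecay = tauDecay %||% d$tau_decay %||% 5.26,
            tauRec = tauRec %||% d$tau_rec %||% 800,
            pulse = pulse %||% d$pulse %||% 1,
            reversal = reversal %||% d$reversal %||%
              if (class == "inhibitory") -80 else 0,
            weight = weight %||% d$weight %||% 1)
  .check(p$tauRise > 0 && p$tauDecay > 0 && p$tauRec > 0,
         "synaptic time constants must be > 0")
  .check(p$pulse > 0, "pulse duration must be > 0")
  .check(p$weight >= 0, "weight must be >= 0")
  structure(p, class = "KineticSynapseParams")
}

#' Synapse resource state
#'
#' @param recovered,effective,inactive Resource fractions; must sum to 1.
#' @param timer Remaining transmitter-pulse time (ms).
#' @return Named numeric vector of class `DepressingSynapseState`. Fresh
#'   synapses start with all resource recovered.
#' @export
synapseState <- function(recovered = 1, effective = 0, inactive = 0,
                         timer = 0) {
  .check(abs(recovered + effective + inactive - 1) < 1e-6,
         "resource fractions must sum to 1")
  .check(timer >= 0, "pulse timer must be >= 0")
  structure(c(R = recovered, E = effective, I = inactive, timer = timer),
            class = "DepressingSynapseState")
}

#' Advance a synapse by one time step
#'
#' If a presynaptic spike arrives, the transmitter pulse timer is set (or
#' reset -- pulses do not stack) to the full pulse duration. The three-pool
#' flow is integrated with a second-order (Heun) step whose stage fluxes
#' are antisymmetric, so R + E + I is conserved to machine precision. For
#' the non-depressing classes the inactive pool is returned to the
#' recovered pool in full each step.
#'
#' @param state A [synapseState()].
#' @param params A [synapseParams()].
#' @param presynSpike Logical: did the presynaptic unit spike this step?
#' @param dt Time step (ms).
#' @return The new [synapseState()].
#' @export
synapseStep <- function(state, params, presynSpike = FALSE, dt = 0.1) {
  .check(dt > 0, "dt must be positive")
  R <- state[["R"]]; E <- state[["E"]]; I <- state[["I"]]
  timer <- state[["timer"]]
  if (isTRUE(presynSpike)) timer <- params$pulse
  gate <- timer > 0
  depressing <- params$class == "depressing"
  a <- if (gate) 1 / params$tauRise else 0
  b <- 1 / params$tauDecay
  cc <- if (depressing) 1 / params$tauRec else 0
  deriv <- function(x) c(cc * x[3] - a * x[1],
                         a * x[1] - b * x[2],
                         b * x[2] - cc * x[3])
  x <- c(R, E, I)
  k1 <- deriv(x)
  k2 <- deriv(x + dt * k1)
  x <- x + dt * (k1 + k2) / 2
  if (!depressing) {   # instantaneous inactive -> recovered return
    x[1] <- x[1] + x[3]
    x[3] <- 0
  }
  R2 <- x[1]; E2 <- x[2]; I2 <- x[3]
  if (min(R2, E2, I2) < -1e-9 || max(R2, E2, I2) > 1 + 1e-9)
    stop("synapse resource fractions left [0, 1]: dt too large", call. = FALSE)
  timer <- max(timer - dt, 0)
  if (timer < 1e-9) timer <- 0   # guard against fp residue extending the pulse
  structure(c(R = R2, E = E2, I = I2, timer = timer),
            class = "DepressingSynapseState")
}

#' Synaptic current
#'
#' The postsynaptic current is proportional to the effective resource
#' fraction: `weight * E * (reversal - V)` (pA), depolarising while the
#' membrane sits below an excitatory reversal.
#'
#' @param state A [synapseState()].
#' @param params A [synapseParams()].
#' @param postsynPotential Postsynaptic membrane potential (mV).
#' @return Current (pA).
#' @export
synapticCurrent <- function(state, params, postsynPotential) {
  params$weight * state[["E"]] * (params$reversal - postsynPotential)
}

# internal: peak effective fraction over a simulated spike train
.peakEffective <- function(params, spikeTimes, tEnd, dt = 0.1,
                           after = -Inf) {
  st <- synapseState()
  n <- ceiling(tEnd / dt)
  spikeStep <- unique(floor(spikeTimes / dt))
  peak <- 0
  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    st <- synapseStep(st, params, presynSpike = (k - 1) %in% spikeStep, dt = dt)
    if (t >= after && st[["E"]] > peak) peak <- st[["E"]]
  }
  peak
}

#' Paired-pulse recovery curve
#'
#' Protocol wrapper exposing the depression recovery time constant: a
#' conditioning spike train is followed, at each probe delay, by a single
#' probe spike, and the probe-evoked peak effective fraction is expressed as
#' a ratio of the unconditioned single-spike peak. Ratios approach 1 as the
#' delay grows; fitting `1 - ratio` against delay recovers `tauRec`.
#'
#' @param params A [synapseParams()].
#' @param conditioningTrain Spike times (ms) of the conditioning train.
#' @param probeDelays Delays (ms) from the last conditioning spike to the
#'   probe spike; must be positive and non-empty.
#' @param dt Integration step (ms).
#' @return `data.frame` with columns `delay` and `ratio`.
#' @export
recoveryCurve <- function(params, conditioningTrain, probeDelays, dt = 0.1) {
  .check(length(probeDelays) > 0, "probeDelays must not be empty")
  .check(all(probeDelays > 0), "probe delays must be > 0")
  lastSpike <- max(conditioningTrain)
  settle <- 4 * params$tauDecay
  unconditioned <- .peakEffective(params, 0, tEnd = settle, dt = dt)
  ratio <- vapply(probeDelays, function(delay) {
    probe <- lastSpike + delay
    pk <- .peakEffective(params, c(conditioningTrain, probe),
                         tEnd = probe + settle, dt = dt, after = probe)
    pk / unconditioned
  }, numeric(1))
  data.frame(delay = probeDelays, ratio = ratio)
}

#' Fit the recovery time constant from a recovery curve
#'
#' Log-linear least squares on `log(1 - ratio)` versus delay.
#'
#' @param curve A `data.frame` from [recoveryCurve()].
#' @return Estimated recovery time constant (ms).
#' @export
fitRecoveryTau <- function(curve) {
  keep <- curve$ratio < 1 - 1e-9
  .check(sum(keep) >= 2, "need at least two unrecovered points to fit")
  fit <- lm(log(1 - ratio) ~ delay, data = curve[keep, ])
  -1 / coef(fit)[["delay"]]
}

#' Log-normal jitter specification
#'
#' Synaptic parameter heterogeneity: at network build time each listed
#' parameter of every synapse is multiplied by an independent log-normal
#' variate with log-mean 0 and log-sd `sdlog`. Neuron parameters are never
#' jittered.
#'
#' @param sdlog Log-scale standard deviation (>= 0). The default comes from
#'   the defaults file.
#' @param parameters Character vector of parameter names subject to jitter.
#' @return A list of class `JitterSpec`.
#' @export
jitterSpec <- function(sdlog = NULL, parameters = NULL) {
  d <- ssanetDefaults()$jitter
  sdlog <- sdlog %||% d$sdlog
  parameters <- parameters %||% d$parameters
  .check(sdlog >= 0, "jitter sdlog must be >= 0")
  structure(list(sdlog = sdlog, parameters = parameters),
            class = "JitterSpec")
}

#' Apply log-normal jitter to synapse parameters
#'
#' @param params A [synapseParams()].
#' @param spec A [jitterSpec()].
#' @return A jittered copy of `params`; positivity of time constants is
#'   preserved by the multiplicative log-normal form.
#' @export
jitterParams <- function(params, spec = jitterSpec()) {
  map <- c(weight = "weight", tau_rise = "tauRise", tau_decay = "tauDecay",
           tau_rec = "tauRec", reversal = "reversal", pulse = "pulse")
  for (nm in spec$parameters) {
    fld <- if (nm %in% names(map)) map[[nm]] else nm
    .check(fld %in% names(params), sprintf("unknown jitter parameter '%s'", nm))
    params[[fld]] <- params[[fld]] * rlnorm(1, 0, spec$sdlog)
  }
  params
}
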