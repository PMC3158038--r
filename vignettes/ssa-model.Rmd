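---
title: "Modelling stimulus-specific adaptation with convergent depressing synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stimulus-specific adaptation with convergent depressing synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The phenomenon and the model

Stimulus-specific adaptation (SSA) is the decline of a neuron's spiking
response to a frequently repeated stimulus that does not generalise to rare
stimuli: in a two-tone *oddball* sequence a neuron adapts to the common
*standard* tone yet keeps responding to the rare *deviant*, even though both
tones are physically interchangeable. `ssanet` implements a spiking-network
account of this phenomenon in which the whole effect arises from
**short-term depression of the synapses that convey frequency-specific
input**, without any topographic map or dedicated novelty circuitry.

The model is a small feed-forward network of homogeneous populations:

* **Population A** — frequency-tuned sub-populations of independent Poisson
  units. Unit rates follow a raised Gaussian tuning curve of the tone
  frequency $f$ (octaves):
  $r(f) = r_0 + (r_{\max} - r_0)\,
  e^{-(f - f_{best})^2 / 2\sigma^2}$, with
  $\sigma = \mathrm{BW} / (2\sqrt{2\ln 2})$ so that the *bandwidth*
  $\mathrm{BW}$ is the separation in octaves between the two half-rise
  frequencies. Best frequencies are spaced uniformly on the octave axis
  (96 sub-populations over 2 octaves for two-tone tasks, 144 over 3 octaves
  for multi-tone tasks, at full scale).
* **Population B** — adaptive exponential integrate-and-fire (AdEx) units,
  each receiving one *depressing* excitatory synapse from a distinct
  Poisson unit of every sub-population. This convergent layer of depressing
  synapses is where SSA is generated.
* **Population C** (ABC model) — an inhibitory AdEx population driven from
  A exactly like B but through *non-depressing* synapses; each B unit
  receives 16 fast inhibitory afferents from randomly chosen C units.
  C does not participate in generating SSA: its delayed shunting inhibition
  suppresses spontaneous and late stimulus-driven spiking so that B
  responds to a tone with either zero or one spike (binary spiking), which
  raises the contrast of the phasic response against the noise floor.
* **Population D** (ABD model) — a second AdEx population driven from B
  through depressing synapses, all-to-all. Two depressing layers in series
  make D respond to the *novelty* of a tone rather than its mere rarity.

## Unit dynamics

AdEx membrane and adaptation equations, forward-Euler integrated at
$\Delta t = 0.1$ ms:

$$C\frac{dV}{dt} = -g_L(V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - w + I(t), \qquad
\tau_w\frac{dw}{dt} = a(V - E_L) - w.$$

When $V$ crosses a numerical detection cutoff (0 mV, well above
$V_T + \Delta_T$; the dynamics diverge there so the exact value is
immaterial) the unit spikes, $V$ is reset to $V_r$ and $w$ jumps by $b$.
The parameter set is the standard regular-spiking cortical AdEx set
($C = 281$ pF, $g_L = 30$ nS, $E_L = V_r = -70.6$ mV, $\Delta_T = 2$ mV,
$V_T = -50.4$ mV, $\tau_w = 144$ ms, $a = 4$ nS, $b = 80.5$ pA), shipped in
`inst/extdata/defaults.yaml` and never jittered.

Every AdEx unit receives in-vivo-like background conductance noise: two
Ornstein–Uhlenbeck processes (excitatory and inhibitory) with means
$g_{e0}, g_{i0}$, stationary standard deviations $\sigma_e, \sigma_i$ and
correlation times $\tau_e, \tau_i$, advanced by the exact discretisation
and converted to a current
$I = s\,[g_e(E_e - V) + g_i(E_i - V)]$ where $s$ is a surface-area scaling
factor (default 1). Conductances are not clipped at zero; clipping is an
opt-in flag. Two presets are shipped: `low_spontaneous`
($\sigma_e = 3$ nS — membrane fluctuations but few spontaneous spikes, used
by the ABD model) and `high_spontaneous` ($\sigma_e = 23$ nS, calibrated
with `calibrateNoiseSigma()` so an unconnected unit fires at roughly 5 Hz,
typical of high spontaneous activity in auditory cortex, used by AB/ABC).

## Synapse dynamics

All synapses share one kinetic scheme. A unit supply of transmitter
resource is split across three pools — recovered $R$, effective $E$,
inactive $I$ — with $R + E + I = 1$. A presynaptic spike opens (or re-opens;
pulses never stack) a square transmitter pulse of duration 1 ms. While the
pulse is open, resource flows $R \to E$ at rate $R/\tau_{rise}$; at all
times $E \to I$ at rate $E/\tau_{decay}$ and $I \to R$ at rate
$I/\tau_{rec}$. The postsynaptic current is
$I_{syn} = g\,E\,(E_{rev} - V)$.

The three classes differ only in parameters: fast excitatory
(AMPA-like, $\tau_{rise} = 0.91$ ms, $\tau_{decay} = 5.26$ ms,
$E_{rev} = 0$ mV) with instantaneous $I \to R$ return (non-depressing);
fast inhibitory (GABA$_A$-like, $\tau_{decay} = 5.56$ ms,
$E_{rev} = -80$ mV), also non-depressing; and the depressing excitatory
class, identical to the fast excitatory one except that the inactive pool
returns with $\tau_{rec} = 800$ ms. Implementing the non-depressing classes
as the depressing model with instantaneous return keeps a single code path
and makes the depression-disabled control (`setDepressionEnabled()`) an
exact limit of the same dynamics.

Heterogeneity: at build time every synapse's weight, time constants and
reversal potential are multiplied by independent log-normal variates with
log-sd 0.1 (about 10 % coefficient of variation). Neuron parameters are
never jittered.

# Numerical choices

* **Clock-driven engine, one global step.** The pulse-gated synapse ODEs
  and the OU noise require per-step updates for every synapse and unit
  anyway, so an event-driven scheme buys nothing. The engine (C++) and the
  exported R single-step functions (`adexStep()`, `synapseStep()`,
  `ouNoiseStep()`) implement the identical update so that the compiled
  path can be validated step-by-step against an R-level integration (see
  `test-network.R`).
* **Membrane: forward Euler,** $\Delta t = 0.1$ ms, exponential argument
  capped at 30 (beyond the detection cutoff the trajectory is replaced by
  the reset rule, so the cap never affects spike times). Spike times agree
  with a 10×-refined integration to within 1 ms on frozen input traces.
* **Synapse pools: Heun's method** (second order). Forward Euler at
  $\Delta t = 0.1$ ms mis-states the single-pulse peak of the effective
  pool by several percent because $\Delta t/\tau_{rise} \approx 0.11$; the
  Heun step brings the refined-step disagreement below 0.2 %. The stage
  fluxes are antisymmetric between pools, so $R + E + I = 1$ holds to
  machine precision for arbitrary spike trains.
* **Pulse timer epsilon.** The pulse timer is decremented by $\Delta t$
  each step and snapped to zero below $10^{-9}$ ms; without the snap,
  floating-point residue (~$10^{-16}$) keeps the transmitter gate open for
  one extra step and inflates every response by the corresponding
  fraction.
* **OU noise: exact discretisation,** so the stationary moments are
  correct at any step size.
* **Reproducibility.** Every stimulus generator, the network build and the
  simulation are pure functions of their seed. The engine seeds an
  internal xoshiro256++ generator from R's RNG, so `set.seed`-style
  determinism is preserved while keeping the inner loop fast. Experiment
  runners derive per-condition child seeds deterministically from the root
  seed.

# Choices made where the design was open

* **Markov switching metric.** Two-state chains over (deviant, standard)
  decouple the deviant probability $p$ from the switching rate. We
  parameterise the deviant-to-standard probability as
  $q_{DS} = s\,q_{\max}$ with $q_{\max} = \min(1, (1-p)/p)$ and obtain the
  standard-to-deviant probability from the stationarity balance
  $p\,q_{DS} = (1-p)\,q_{SD}$. The *scaled switching metric* $s$ then runs
  from 0 (the chain never switches) to 1 (switches at the highest rate
  compatible with stationary probability $p$), and the i.i.d. oddball
  sequence is the special case $s = (1-p)/q_{\max}$, where both rows of
  the transition matrix equal $(p, 1-p)$.
* **Input spontaneous rate 0.2 Hz.** With a per-spike utilisation of
  $1 - e^{-1/0.91} \approx 0.67$ and $\tau_{rec} = 800$ ms, an input floor
  of even 1 Hz drives every depressing synapse to a baseline recovery of
  ~0.65 and erases the contrast between 1 s and 10 s of recovery — the
  very contrast SSA is made of. Spontaneous activity in the AdEx
  populations is instead supplied by the background conductance noise,
  which is also where the model places it conceptually; the input floor is
  therefore kept near-silent.
* **Tuning bandwidth 0.25 octaves** (half-rise separation). At a bandwidth
  equal to the common 0.5-octave tone separation, standards drive the
  deviant channel at half-maximal rate, and cross-frequency depression
  swamps the history effects that the Markov experiments measure.
  0.25 octaves is within the range of peripheral and midbrain auditory
  tuning and keeps the two channels of a 0.5-octave pair effectively
  independent while leaving strong overlap for 0.1-octave pairs.
* **Pathway weights.** Synaptic weights have no first-principles values;
  they were chosen with `runCalibration()` sweeps and frozen in the
  defaults file:
  A→B 20 nS and C→B 40 nS place the ABC model at the binary-spiking point
  of the excitation/inhibition balance (≥ 90 % of tone responses hold 0 or
  1 spike) while keeping the SSA index clearly positive; A→C 8 nS gives
  population C moderate tonic spiking during tones. The ABD model runs in
  the low-noise regime where feed-forward drive must reach threshold
  without help from background fluctuations, so it carries its own weight
  set (A→B 60 nS, B→D 40 nS), mirroring the fact that the two-layer model
  is specified with its own weights.
* **Spike-count window.** `countSpikes()` defaults to the full
  onset-to-onset epoch (the least-committal reading, capturing tonic as
  well as phasic responses). The experiment runners default to the
  onset-limited window $[0, \text{tone duration})$: with the
  high-spontaneous noise preset the inter-tone interval contributes ~5
  noise spikes per epoch against a phasic response of well under one
  spike, and at the scaled-down population size the epoch-wide count
  cannot resolve the effect. Both conventions are available everywhere via
  the `window` argument.
* **Presentation rates in the scaled suite.** The oddball/Markov/grid
  runners default to a 250 ms inter-onset interval with 50 ms tones. SSA
  in this model grows steeply as the interval shrinks (the
  `runIsiSweep()` read-out), and at 1 s intervals a single interval of
  recovery already restores the thresholded response, clipping history and
  ordering effects to zero at desk scale. The fast regime corresponds to
  the rapid presentation rates used for the two-layer experiments.
* **Undefined indices.** An SSA index with a zero denominator is reported
  as `NA`, excluded from medians and tests, never imputed.
* **No multiplicity correction** across conditions: each condition is
  reported with its own per-condition test.

# What the synthetic stimuli do and do not emulate

The generators reproduce the *structure* of the standard SSA protocols —
role patterns, frequency placement on the octave axis, swapped twin
presentations, balanced many-standards controls, isochronous timing — and
their statistical laws are tested exactly (transition matrices, stationary
distributions, predecessor combinatorics). They do not emulate acoustics:
there is no cochlear front-end, no intensity or duration tuning, no
off-octave frequency axis, and trial-to-trial variability enters only
through Poisson spiking, synaptic parameter jitter and conductance noise.
Passing tests therefore show that the network mechanism produces the
documented response patterns under the stated input model — not that the
input model is a complete account of the auditory periphery.

# Problem sizes

The shipped test and acceptance suites run the scaled-down study
conditions: 8 AdEx units per population, 24 two-tone (36 multi-tone)
sub-populations, 200-tone sequences, two presentations per condition.
Full-scale runs (48 units, 96/144 sub-populations, 800–1000 tones) use the
same code through the `nB`/`nSub`/`nTones` arguments or the CLI `--scale`
flag; `architectureSpec()` carries the full-scale defaults. At desk scale a
population median over 8 units is noisy, which is why the suite asserts
orderings and signed-rank significance rather than absolute index values.

# Known limitations

* Population medians at desk scale have high seed-to-seed variance; the
  8-unit signed-rank test detects only effects with median indices of
  roughly 0.1 and above.
* The AB model's SSA at 1 s presentation is real but small relative to the
  high noise floor, and at 8 units it is usually not significant — the
  calibrated ABC model is the surface on which quantitative claims are
  made.
* Synaptic delays are zero; the C→B inhibition is delayed only by C's
  integration time.
* Facilitation, NMDA/GABA$_B$ components, stochastic vesicle release,
  three-state Markov stimuli and the four-population cascade are out of
  scope.
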