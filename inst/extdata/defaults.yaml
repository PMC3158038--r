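# Default model parameter sets, keyed by component and pathway.
#
# Units: capacitance pF, conductances/weights nS, potentials mV, times ms,
# rates Hz, currents pA, frequencies octaves. All values are overridable
# through the builder functions; this file is the single source of shipped
# defaults.
#
# Provenance notes:
#   adex              — standard AdEx parameter set for a regular-spiking
#                       cortical neuron (tonic adaptation regime).
#   noise             — point-conductance background model; the
#                       "low_spontaneous" sigmas are the canonical values for
#                       the fluctuating-conductance cortical background; in
#                       "high_spontaneous" the excitatory sigma was
#                       calibrated with calibrateNoiseSigma() to give a
#                       spontaneous rate of ~5 Hz in an unconnected AdEx
#                       unit, typical of high spontaneous activity in
#                       auditory cortex.
#   synapses          — fast AMPA-like and GABA_A-like first-order kinetics;
#                       depressing classes add a slow resource-recovery pool
#                       (tau_rec 800 ms, cortical paired-pulse recovery
#                       scale). Weights were set with the calibration
#                       workflow (see the methods vignette): the A->B weight
#                       is the plateau point of an SI-vs-weight sweep, the
#                       C->B weight is the point where population B shows
#                       binary (0/1 spike) tone responses with the A->C
#                       weight fixed at a value giving moderate tonic firing
#                       in C.
adex:
  capacitance: 281.0
  leak_conductance: 30.0
  leak_reversal: -70.6
  slope_factor: 2.0
  threshold: -50.4
  tau_adaptation: 144.0
  adaptation_coupling: 4.0
  adaptation_increment: 80.5
  reset: -70.6
  cutoff: 0.0
noise:
  none:
    ge0: 0.0
    gi0: 0.0
    sige: 0.0
    sigi: 0.0
    taue: 2.728
    taui: 10.49
    Ee: 0.0
    Ei: -75.0
    scale: 1.0
  low_spontaneous:
    ge0: 12.1
    gi0: 57.3
    sige: 3.0
    sigi: 6.6
    taue: 2.728
    taui: 10.49
    Ee: 0.0
    Ei: -75.0
    scale: 1.0
  high_spontaneous:
    ge0: 12.1
    gi0: 57.3
    sige: 23.0
    sigi: 6.6
    taue: 2.728
    taui: 10.49
    Ee: 0.0
    Ei: -75.0
    scale: 1.0
synapses:
  AtoB:
    class: depressing
    tau_rise: 0.91
    tau_decay: 5.26
    tau_rec: 800.0
    pulse: 1.0
    reversal: 0.0
    weight: 20.0
  AtoC:
    class: excitatory
    tau_rise: 0.91
    tau_decay: 5.26
    tau_rec: 800.0
    pulse: 1.0
    reversal: 0.0
    weight: 8.0
  CtoB:
    class: inhibitory
    tau_rise: 0.2
    tau_decay: 5.56
    tau_rec: 800.0
    pulse: 1.0
    reversal: -80.0
    weight: 40.0
  BtoD:
    class: depressing
    tau_rise: 0.91
    tau_decay: 5.26
    tau_rec: 800.0
    pulse: 1.0
    reversal: 0.0
    weight: 15.0
tuning:
  spontaneous_rate: 0.2
  max_rate: 100.0
  bandwidth: 0.25
jitter:
  sdlog: 0.1
  parameters: [weight, tau_rise, tau_decay, tau_rec, reversal]
# Per-architecture weight overrides: the two-layer model runs in the
# low-noise regime, where the feed-forward drive must cross threshold
# without help from background fluctuations.
architecture_weights:
  ABD:
    AtoB: 60.0
    BtoD: 40.0
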