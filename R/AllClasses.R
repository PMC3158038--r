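#' ToneSequence: an isochronous tone protocol
#'
#' Ordered tone events defining a stimulus protocol. Each event has an onset
#' (ms), a duration (ms), a frequency (octaves relative to the centre of the
#' input range) and a role label (`"standard"`, `"deviant"`, or a position
#' index for multi-tone protocols). All protocols are isochronous: the
#' inter-onset interval is constant.
#'
#' @slot events A `data.frame` with columns `onset`, `duration`, `freq`,
#'   `role`, one row per tone, sorted by onset.
#' @slot ioi Inter-onset interval (ms).
#' @slot protocol Protocol tag (e.g. `"oddball"`, `"markov"`, `"block"`).
#' @slot seed Generator seed used to realise the sequence (`NA` for
#'   deterministic protocols).
#' @name ToneSequence-class
#' @aliases ToneSequence
#' @export
setClass("ToneSequence",
  representation(events = "data.frame", ioi = "numeric",
                 protocol = "character", seed = "integer"),
  validity = function(object) {
    ev <- object@events
    need <- c("onset", "duration", "freq", "role")
    if (!all(need %in% names(ev)))
      return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
    if (nrow(ev) == 0) return("sequence has no events")
    if (any(ev$onset < 0)) return("onsets must be >= 0")
    if (any(ev$duration <= 0)) return("durations must be > 0")
    if (is.unsorted(ev$onset, strictly = TRUE)) return("events must be sorted by onset")
    n <- nrow(ev)
    if (n > 1) {
      gap <- ev$onset[-1] - (ev$onset[-n] + ev$duration[-n])
      if (any(gap < -1e-9)) return("events must not overlap")
      ioi <- diff(ev$onset)
      if (any(abs(ioi - object@ioi) > 1e-6))
        return("inter-onset interval must be constant and equal to @ioi")
    }
    TRUE
  }
)

#' Construct a ToneSequence
#'
#' @param onset,duration,freq,role Per-tone vectors (ms, ms, octaves, label).
#' @param ioi Inter-onset interval (ms); inferred from onsets when `NULL`.
#' @param protocol Protocol tag.
#' @param seed Integer seed used by the generator, or `NA`.
#' @return A [ToneSequence-class] object.
#' @export
toneSequence <- function(onset, duration, freq, role, ioi = NULL,
                         protocol = "custom", seed = NA_integer_) {
  if (is.null(ioi)) {
    ioi <- if (length(onset) > 1) onset[2] - onset[1] else duration[1]
  }
  new("ToneSequence",
      events = data.frame(onset = as.numeric(onset),
                          duration = as.numeric(duration),
                          freq = as.numeric(freq),
                          role = as.character(role),
                          stringsAsFactors = FALSE),
      ioi = as.numeric(ioi), protocol = protocol,
      seed = as.integer(seed))
}

#' @describeIn ToneSequence-class number of tones
#' @param x,object A `ToneSequence`.
#' @export
setMethod("length", "ToneSequence", function(x) nrow(x@events))

#' Tone events of a ToneSequence
#' @param x A [ToneSequence-class].
#' @return The events `data.frame`.
#' @export
toneEvents <- function(x) x@events

#' Inter-onset interval of a ToneSequence
#' @param x A [ToneSequence-class].
#' @return The inter-onset interval (ms).
#' @export
toneIOI <- function(x) x@ioi

#' @export
setMethod("show", "ToneSequence", function(object) {
  ev <- object@events
  cat(sprintf("ToneSequence '%s': %d tones, ioi %g ms, duration %g ms\n",
              object@protocol, nrow(ev), object@ioi, ev$duration[1]))
  tab <- table(ev$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  freqs:", paste(sprintf("%+.3f", sort(unique(ev$freq))), collapse = " "),
      "octaves\n")
})

#' SpikeRecord: raw simulation output
#'
#' Spike events per population produced by [simulateNetwork()].
#'
#' @slot events `data.frame` with columns `population` (character), `unit`
#'   (integer, 1-based within its population) and `time` (ms).
#' @slot dt Simulation step (ms).
#' @slot duration Total simulated time (ms).
#' @name SpikeRecord-class
#' @aliases SpikeRecord
#' @export
setClass("SpikeRecord",
  representation(events = "data.frame", dt = "numeric", duration = "numeric"),
  validity = function(object) {
    ev <- object@events
    need <- c("population", "unit", "time")
    if (!all(need %in% names(ev)))
      return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
    if (nrow(ev) > 0) {
      if (any(ev$time <= 0 | ev$time > object@duration + 1e-9))
        return("spike times must lie in (0, duration]")
      o <- order(ev$population, ev$unit, ev$time)
      tt <- ev$time[o]
      grp <- paste(ev$population[o], ev$unit[o])
      same <- grp[-1] == grp[-length(grp)]
      if (any(same & diff(tt) < 0))
        return("spike times must be non-decreasing per unit")
    }
    TRUE
  }
)

#' Spike events of a SpikeRecord
#' @param x A [SpikeRecord-class].
#' @param population Optional population filter (e.g. `"B"`).
#' @return A `data.frame` of spike events.
#' @export
spikeEvents <- function(x, population = NULL) {
  ev <- x@events
  if (!is.null(population)) ev <- ev[ev$population %in% population, , drop = FALSE]
  ev
}

#' @export
setMethod("show", "SpikeRecord", function(object) {
  ev <- object@events
  cat(sprintf("SpikeRecord: %g ms at dt %g ms, %d spikes\n",
              object@duration, object@dt, nrow(ev)))
  if (nrow(ev) > 0) {
    tab <- table(ev$population)
    cat("  per population:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' Network: a built AB / ABC / ABD model instance
#'
#' Concrete network produced by [buildNetwork()]: population sizes, the
#' per-synapse (jittered) parameter tables for each pathway, and the noise
#' and neuron parameter sets. Population A units are indexed so that unit
#' `(s-1)*nB + b` belongs to sub-population `s` and projects to unit `b` of
#' populations B (depressing) and, in the ABC model, C (non-depressing).
#'
#' @slot architecture `"AB"`, `"ABC"` or `"ABD"`.
#' @slot nB Units per AdEx population (B, and C or D where present).
#' @slot nSub Number of frequency-tuned sub-populations in A.
#' @slot octaveSpan Octave span of the input range.
#' @slot inhibitoryInDegree Inhibitory afferents per B unit (ABC only).
#' @slot pathways Named list of per-synapse parameter `data.frame`s
#'   (`pre`, `post`, `weight`, `tau_rise`, `tau_decay`, `tau_rec`, `pulse`,
#'   `reversal`, `depressing`).
#' @slot adex Named list of AdEx parameters (shared by all AdEx units).
#' @slot noise Named list of background-noise parameters.
#' @slot noisePreset Name of the noise preset used.
#' @slot jitter The [jitterSpec()] applied at build time.
#' @slot seed Build seed.
#' @name Network-class
#' @aliases Network
#' @export
setClass("Network",
  representation(architecture = "character", nB = "integer", nSub = "integer",
                 octaveSpan = "numeric", inhibitoryInDegree = "integer",
                 pathways = "list", adex = "list", noise = "list",
                 noisePreset = "character", jitter = "list", seed = "integer"),
  validity = function(object) {
    arch <- object@architecture
    if (!arch %in% c("AB", "ABC", "ABD")) return("architecture must be AB, ABC or ABD")
    want <- switch(arch, AB = "AtoB", ABC = c("AtoB", "AtoC", "CtoB"),
                   ABD = c("AtoB", "BtoD"))
    if (!setequal(names(object@pathways), want))
      return(sprintf("%s model must have pathways %s", arch,
                     paste(want, collapse = ", ")))
    nA <- object@nSub * object@nB
    ab <- object@pathways$AtoB
    if (nrow(ab) != nA) return("A->B must have one synapse per A unit")
    if (!all(tabulate(ab$post, object@nB) == object@nSub))
      return("each B unit must receive one A->B synapse per sub-population")
    if (arch == "ABC") {
      cb <- object@pathways$CtoB
      deg <- tabulate(cb$post, object@nB)
      if (!all(deg == object@inhibitoryInDegree))
        return("each B unit must receive exactly the configured inhibitory in-degree")
      if (anyDuplicated(cb[, c("pre", "post")]))
        return("C->B afferents must be sampled without replacement")
    }
    if (arch == "ABD") {
      bd <- object@pathways$BtoD
      if (nrow(bd) != object@nB^2) return("B->D must be all-to-all")
    }
    TRUE
  }
)

#' Pathway parameter table of a Network
#' @param x A [Network-class].
#' @param pathway Pathway name, e.g. `"AtoB"`.
#' @return The per-synapse parameter `data.frame`.
#' @export
networkPathway <- function(x, pathway) {
  .check(pathway %in% names(x@pathways),
         sprintf("unknown pathway '%s' (have: %s)", pathway,
                 paste(names(x@pathways), collapse = ", ")))
  x@pathways[[pathway]]
}

#' Population sizes of a Network
#' @param x A [Network-class].
#' @return Named integer vector of unit counts per population.
#' @export
populationSizes <- function(x) {
  out <- c(A = x@nSub * x@nB, B = x@nB)
  if (x@architecture == "ABC") out <- c(out, C = x@nB)
  if (x@architecture == "ABD") out <- c(out, D = x@nB)
  out
}

#' @export
setMethod("show", "Network", function(object) {
  sz <- populationSizes(object)
  cat(sprintf("Network (%s): %s; %d sub-populations over %g octaves\n",
              object@architecture,
              paste(sprintf("|%s|=%d", names(sz), sz), collapse = ", "),
              object@nSub, object@octaveSpan))
  for (p in names(object@pathways)) {
    tab <- object@pathways[[p]]
    cat(sprintf("  %s: %d synapses, %s, mean weight %.2f nS\n", p, nrow(tab),
                if (all(tab$depressing)) "depressing" else
                  if (any(tab$reversal < -40)) "inhibitory" else "non-depressing",
                mean(tab$weight)))
  }
  cat(sprintf("  noise preset '%s', jitter sdlog %g, seed %d\n",
              object@noisePreset, object@jitter$sdlog, object@seed))
})

#' SIResult: SSA indices for a population of units
#'
#' Per-unit mean deviant/standard responses and the derived SSA indices,
#' plus the population-level summary (median neuron-specific SI and the
#' two-sided Wilcoxon signed-rank p-value against a zero median).
#'
#' Indices with a zero denominator are undefined and stored as `NA`; they
#' are excluded from the median and the test, never imputed.
#'
#' @slot perUnit `data.frame` with one row per unit: `unit`, `d1`, `d2`,
#'   `s1`, `s2` (mean spike counts for the two frequencies as deviant and
#'   standard), `si1`, `si2` (frequency-specific indices) and `si`
#'   (neuron-specific index).
#' @slot frequencies The two tone frequencies (octaves).
#' @slot medianSI Median neuron-specific SI over defined units.
#' @slot pValue Signed-rank p-value for median SI = 0.
#' @slot condition Free-form condition label.
#' @name SIResult-class
#' @aliases SIResult
#' @export
setClass("SIResult",
  representation(perUnit = "data.frame", frequencies = "numeric",
                 medianSI = "numeric", pValue = "numeric",
                 condition = "character"),
  validity = function(object) {
    pu <- object@perUnit
    need <- c("unit", "d1", "d2", "s1", "s2", "si1", "si2", "si")
    if (!all(need %in% names(pu)))
      return(sprintf("perUnit must have columns %s", paste(need, collapse = ", ")))
    idx <- unlist(pu[, c("si1", "si2", "si")])
    if (any(abs(idx) > 1 + 1e-12, na.rm = TRUE))
      return("SSA indices must lie in [-1, 1]")
    TRUE
  }
)

#' Per-unit SSA index table
#' @param x An [SIResult-class].
#' @return The per-unit `data.frame`.
#' @export
siPerUnit <- function(x) x@perUnit

#' Median neuron-specific SI
#' @param x An [SIResult-class].
#' @return Named numeric: median SI and its signed-rank p-value.
#' @export
siMedian <- function(x) c(median = x@medianSI, p.value = x@pValue)

#' @export
setMethod("show", "SIResult", function(object) {
  cat(sprintf("SIResult [%s]: %d units, median SI %.3f (signed-rank p = %.3g)\n",
              object@condition, nrow(object@perUnit), object@medianSI,
              object@pValue))
  und <- sum(is.na(object@perUnit$si))
  if (und > 0) cat(sprintf("  %d unit(s) with undefined SI excluded\n", und))
})
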