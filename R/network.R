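#' Architecture specification for the SSA networks
#'
#' Declarative description of an AB, ABC or ABD network:
#'
#' * **AB**: population A (`nSub * nB` frequency-tuned Poisson units)
#'   projects to population B (`nB` AdEx units); each B unit receives one
#'   depressing, excitatory synapse from a distinct Poisson unit of every
#'   sub-population.
#' * **ABC** adds an inhibitory population C (`nB` AdEx units): A projects
#'   to C exactly as to B but via non-depressing synapses, and each B unit
#'   receives `inhibitoryInDegree` fast inhibitory synapses from randomly
#'   chosen C units (sampled without replacement).
#' * **ABD** adds population D (`nB` AdEx units) receiving input from B
#'   only, via depressing synapses connected all-to-all.
#'
#' @param architecture `"AB"`, `"ABC"` or `"ABD"`.
#' @param nB Units per AdEx population (full-scale default 48).
#' @param nSub Sub-populations in A (96 two-tone, 144 multi-tone).
#' @param octaveSpan Octave span of the input range (2 two-tone, 3
#'   multi-tone).
#' @param inhibitoryInDegree Inhibitory afferents per B unit (ABC; default
#'   16, capped at `nB` for scaled-down networks).
#' @param noisePreset Background-noise preset name; defaults to
#'   `"high_spontaneous"` for AB/ABC and `"low_spontaneous"` for ABD.
#'   `NULL` disables noise.
#' @param jitter A [jitterSpec()].
#' @param weights Optional named numeric vector overriding pathway weights,
#'   e.g. `c(AtoB = 4)`.
#' @param synapses Optional named list of [synapseParams()] overriding whole
#'   pathway parameter sets.
#' @param seed Build seed (jitter and C->B wiring).
#' @return A list of class `ArchitectureSpec` for [buildNetwork()].
#' @export
architectureSpec <- function(architecture = c("AB", "ABC", "ABD"),
                             nB = 48L, nSub = 96L, octaveSpan = 2,
                             inhibitoryInDegree = NULL, noisePreset = "auto",
                             jitter = jitterSpec(), weights = NULL,
                             synapses = NULL, seed = 1L) {
  architecture <- match.arg(architecture)
  .check(nB >= 1 && nSub >= 1, "nB and nSub must be >= 1")
  if (identical(noisePreset, "auto")) {
    noisePreset <- if (architecture == "ABD") "low_spontaneous"
                   else "high_spontaneous"
  }
  inhibitoryInDegree <- inhibitoryInDegree %||% min(16L, nB)
  if (architecture == "ABC") {
    .check(inhibitoryInDegree >= 1 && inhibitoryInDegree <= nB,
           "inhibitory in-degree must lie in [1, |C|]")
  }
  structure(list(architecture = architecture, nB = as.integer(nB),
                 nSub = as.integer(nSub), octaveSpan = octaveSpan,
                 inhibitoryInDegree = as.integer(inhibitoryInDegree),
                 noisePreset = noisePreset, jitter = jitter,
                 weights = weights, synapses = synapses,
                 seed = as.integer(seed)),
            class = "ArchitectureSpec")
}

# internal: expand a synapseParams set into an n-row per-synapse table with
# independent log-normal jitter on the listed parameters
.synapseTable <- function(pre, post, params, jitter) {
  n <- length(pre)
  tab <- data.frame(pre = pre, post = post,
                    weight = rep(params$weight, n),
                    tau_rise = rep(params$tauRise, n),
                    tau_decay = rep(params$tauDecay, n),
                    tau_rec = rep(params$tauRec, n),
                    pulse = rep(params$pulse, n),
                    reversal = rep(params$reversal, n),
                    depressing = rep(params$class == "depressing", n))
  if (jitter$sdlog > 0) {
    map <- c(weight = "weight", tau_rise = "tau_rise",
             tau_decay = "tau_decay", tau_rec = "tau_rec",
             reversal = "reversal", pulse = "pulse")
    for (nm in jitter$parameters) {
      col <- map[[nm]]
      tab[[col]] <- tab[[col]] * rlnorm(n, 0, jitter$sdlog)
    }
  }
  tab
}

#' Build a network instance
#'
#' Materialises an [architectureSpec()]: constructs the connectivity and
#' draws the per-synapse log-normal parameter jitter. The build is a pure
#' function of the spec (including its seed).
#'
#' @param spec An [architectureSpec()].
#' @return A [Network-class].
#' @export
#' @examples
#' net <- buildNetwork(architectureSpec("ABC", nB = 4L, nSub = 12L, seed = 7L))
#' populationSizes(net)
buildNetwork <- function(spec) {
  .check(is(spec, "ArchitectureSpec"), "spec must be an architectureSpec()")
  set.seed(spec$seed)
  nB <- spec$nB; nSub <- spec$nSub
  arch <- spec$architecture
  archW <- ssanetDefaults()$architecture_weights[[arch]]
  paramsFor <- function(pathway) {
    if (!is.null(spec$synapses[[pathway]])) return(spec$synapses[[pathway]])
    p <- synapseParams(pathway = pathway)
    if (!is.null(archW[[pathway]])) p$weight <- archW[[pathway]]
    if (!is.null(spec$weights) && pathway %in% names(spec$weights))
      p$weight <- unname(spec$weights[[pathway]])
    p
  }
  # A unit (s-1)*nB + b projects to B unit b (and C unit b in ABC)
  preA <- as.integer(outer(seq_len(nB), (seq_len(nSub) - 1L) * nB, `+`))
  postB <- rep(seq_len(nB), times = nSub)
  pathways <- list(AtoB = .synapseTable(preA, postB, paramsFor("AtoB"),
                                        spec$jitter))
  if (arch == "ABC") {
    pathways$AtoC <- .synapseTable(preA, postB, paramsFor("AtoC"),
                                   spec$jitter)
    preC <- unlist(lapply(seq_len(nB), function(b)
      sample(nB, spec$inhibitoryInDegree)))
    postCB <- rep(seq_len(nB), each = spec$inhibitoryInDegree)
    pathways$CtoB <- .synapseTable(as.integer(preC), postCB,
                                   paramsFor("CtoB"), spec$jitter)
  }
  if (arch == "ABD") {
    preB <- rep(seq_len(nB), times = nB)
    postD <- rep(seq_len(nB), each = nB)
    pathways$BtoD <- .synapseTable(preB, postD, paramsFor("BtoD"),
                                   spec$jitter)
  }
  noise <- if (is.null(spec$noisePreset)) unclass(ouNoiseParams("none"))
           else unclass(ouNoiseParams(spec$noisePreset))
  new("Network", architecture = arch, nB = nB, nSub = nSub,
      octaveSpan = spec$octaveSpan,
      inhibitoryInDegree = spec$inhibitoryInDegree,
      pathways = pathways, adex = unclass(adexParams()), noise = noise,
      noisePreset = spec$noisePreset %||% "none", jitter = unclass(spec$jitter),
      seed = spec$seed)
}

#' Enable or disable short-term depression on a pathway
#'
#' Switches a pathway's synapses between the depressing dynamics and the
#' non-depressing limit (instantaneous inactive -> recovered return),
#' leaving weights, kinetics and jitter untouched, so the depressing
#' responses are restored exactly by re-enabling.
#'
#' @param network A [Network-class].
#' @param pathway Pathway name (e.g. `"AtoB"`).
#' @param enabled Logical.
#' @return The modified [Network-class].
#' @export
setDepressionEnabled <- function(network, pathway, enabled) {
  .check(pathway %in% names(network@pathways),
         sprintf("unknown pathway '%s'", pathway))
  network@pathways[[pathway]]$depressing <- rep(isTRUE(enabled),
                                                nrow(network@pathways[[pathway]]))
  network
}

#' Run the clock-driven simulation
#'
#' Advances the full network state on a single global step: the tone
#' schedule sets per-sub-population Poisson rates through the tuning curve,
#' population A spikes are drawn, all synapses are stepped (transmitter
#' pulses, three-pool resource flow, postsynaptic currents), the
#' Ornstein-Uhlenbeck background conductances are advanced, and every AdEx
#' unit is integrated with spike detection and reset. The result is a pure
#' function of (network, sequence, tuning, dt, seed).
#'
#' @param network A [Network-class] from [buildNetwork()].
#' @param sequence A [ToneSequence-class].
#' @param tuning A [tuningSpec()]; by default built from the network's
#'   sub-population count and octave span with shipped tuning defaults.
#' @param dt Time step (ms).
#' @param tEnd Simulated time (ms); default: one inter-onset interval past
#'   the last onset. Must cover the last tone.
#' @param seed RNG seed.
#' @param recordA Also record population A spikes (voluminous; default off).
#' @param aSpikes Optional 0/1 integer matrix (`tEnd/dt` rows, `|A|`
#'   columns) of imposed population A spike trains, used for deterministic
#'   testing; when supplied no Poisson draws are made.
#' @return A [SpikeRecord-class].
#' @export
simulateNetwork <- function(network, sequence, tuning = NULL, dt = 0.1,
                            tEnd = NULL, seed = 1L, recordA = FALSE,
                            aSpikes = NULL) {
  .check(is(network, "Network"), "network must be a Network")
  .check(is(sequence, "ToneSequence"), "sequence must be a ToneSequence")
  .check(dt > 0 && dt <= 1, "dt must lie in (0, 1] ms")
  if (is.null(tuning)) {
    tuning <- tuningSpec(nSub = network@nSub, octaveSpan = network@octaveSpan)
  }
  .check(tuning$nSub == network@nSub,
         "tuning sub-population count must match the network")
  ev <- sequence@events
  lastOff <- max(ev$onset + ev$duration)
  if (is.null(tEnd)) tEnd <- max(ev$onset) + sequence@ioi
  .check(tEnd >= lastOff, "tEnd must cover the last tone")
  pw <- lapply(names(network@pathways), function(nm) {
    tab <- network@pathways[[nm]]
    prePop <- substr(nm, 1, 1)
    postPop <- substr(nm, nchar(nm), nchar(nm))
    c(as.list(tab[setdiff(names(tab), "depressing")]),
      list(depressing = all(tab$depressing), prePop = prePop,
           postPop = postPop))
  })
  names(pw) <- names(network@pathways)
  engineNet <- list(arch = network@architecture, nB = network@nB,
                    nSub = network@nSub, adex = network@adex,
                    noise = network@noise, pathways = pw)
  set.seed(seed)
  raw <- .sim_engine(engineNet, as.matrix(ev[, c("onset", "duration", "freq")]),
                     unclass(tuning), dt, tEnd, aSpikes, recordA)
  events <- do.call(rbind, lapply(names(raw), function(p) {
    data.frame(population = rep(p, length(raw[[p]]$unit)),
               unit = raw[[p]]$unit, time = raw[[p]]$time)
  }))
  if (is.null(events))
    events <- data.frame(population = character(), unit = integer(),
                         time = numeric())
  new("SpikeRecord", events = events, dt = dt, duration = tEnd)
}

#' Connectivity audit of a built network
#'
#' Exhaustively checks the degree constraints of the architecture and
#' returns the per-pathway in/out degree summary used in the build manifest.
#'
#' @param network A [Network-class].
#' @return A `data.frame` with one row per pathway: synapse count, post
#'   in-degree (min/max) and pre out-degree (min/max).
#' @export
connectivitySummary <- function(network) {
  do.call(rbind, lapply(names(network@pathways), function(nm) {
    tab <- network@pathways[[nm]]
    indeg <- table(tab$post)
    outdeg <- table(tab$pre)
    data.frame(pathway = nm, nSynapses = nrow(tab),
               inDegreeMin = min(indeg), inDegreeMax = max(indeg),
               outDegreeMin = min(outdeg), outDegreeMax = max(outdeg))
  }))
}

#' Write a SpikeRecord as a tab-separated event table
#'
#' Columns `population`, `unit_id`, `time_ms`, preceded by `#`-prefixed
#' header lines recording dt and duration; [readSpikeRecord()] restores the
#' object.
#'
#' @param x A [SpikeRecord-class].
#' @param file Path.
#' @return `file`, invisibly.
#' @export
writeSpikeRecord <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_ms\t%.9g", x@dt),
               sprintf("# duration_ms\t%.9g", x@duration),
               "population\tunit_id\ttime_ms"), con)
  ev <- x@events
  write.table(data.frame(ev$population, ev$unit, ev$time), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeSpikeRecord
#' @export
readSpikeRecord <- function(file) {
  hdr <- readLines(file, n = 2)
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  vals <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  ev <- read.table(file, sep = "\t", header = TRUE, skip = 2,
                   stringsAsFactors = FALSE)
  new("SpikeRecord",
      events = data.frame(population = ev$population, unit = ev$unit_id,
                          time = ev$time_ms),
      dt = as.numeric(vals[["dt_ms"]]),
      duration = as.numeric(vals[["duration_ms"]]))
}
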