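# Reference integrators and fixture builders used as independent oracles.
# These deliberately reuse only the exported single-step operations (or
# plain R arithmetic), never the compiled engine, so that engine results can
# be cross-checked against them.

# integrate an AdEx unit over a frozen input-current trace; returns spike
# times (ms)
integrateAdEx <- function(params, current, dt, tEnd) {
  n <- round(tEnd / dt)
  st <- adexState(params$leakReversal, 0)
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    out <- adexStep(st, params, inputCurrent = current((k - 1) * dt), dt = dt)
    st <- out$state
    if (out$spike) spikes <- c(spikes, k * dt)
  }
  spikes
}

# integrate a synapse over a spike train; returns the full state trace
integrateSynapse <- function(params, spikeTimes, dt, tEnd) {
  n <- round(tEnd / dt)
  st <- synapseState()
  spikeStep <- unique(floor(spikeTimes / dt))
  trace <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("R", "E", "I", "timer")))
  for (k in seq_len(n)) {
    st <- synapseStep(st, params, presynSpike = (k - 1) %in% spikeStep, dt = dt)
    trace[k, ] <- st
  }
  trace
}

# synthetic SpikeRecord with the given number of spikes per (tone, unit),
# placed at fixed offsets inside each tone's window
syntheticRecord <- function(sequence, counts, population = "B",
                            offset = 10, spacing = 5) {
  ev <- toneEvents(sequence)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (u in seq_len(ncol(counts))) {
      k <- counts[i, u]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = population, unit = u,
          time = ev$onset[i] + offset + spacing * (seq_len(k) - 1))
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), unit = integer(), time = numeric())
  events <- events[order(events$population, events$unit, events$time), ]
  new("SpikeRecord", events = events, dt = 0.1,
      duration = max(ev$onset) + sequence@ioi)
}

# power-iteration stationary distribution of a stochastic matrix (oracle
# for the analytic left eigenvector)
stationaryByPowerIteration <- function(m, iter = 10000) {
  v <- c(0.5, 0.5)
  for (i in seq_len(iter)) v <- as.numeric(v %*% m)
  v / sum(v)
}
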