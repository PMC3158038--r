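#' Input tuning specification
#'
#' Population A consists of `nSub` sub-populations of Poisson units with
#' best frequencies spaced uniformly on an octave scale over the input span
#' (two-tone tasks: 96 sub-populations over 2 octaves; multi-tone tasks: 144
#' over 3 octaves). Each sub-population's firing rate follows a raised
#' Gaussian profile of the tone frequency (see [tuningRate()]). Bandwidth is
#' defined as the separation, in octaves, between the two frequencies that
#' evoke a rate half-way between the maximal and spontaneous rates.
#'
#' @param nSub Number of sub-populations.
#' @param octaveSpan Octave span of the input range.
#' @param spontaneousRate Spontaneous rate (Hz) in the absence of a tone.
#' @param maxRate Maximal rate (Hz) at the best frequency.
#' @param bandwidth Tuning bandwidth (octaves, half-rise separation).
#' @return A list of class `TuningSpec` with the derived `bestFreq` vector
#'   (octaves, centred on zero) and Gaussian `sigma`.
#' @export
#' @examples
#' tun <- tuningSpec()
#' tuningRate(0, 0, tun)                    # maximal rate
#' tuningRate(tun$bandwidth / 2, 0, tun)    # half-rise point
tuningSpec <- function(nSub = 96L, octaveSpan = 2, spontaneousRate = NULL,
                       maxRate = NULL, bandwidth = NULL) {
  d <- ssanetDefaults()$tuning
  spontaneousRate <- spontaneousRate %||% d$spontaneous_rate
  maxRate <- maxRate %||% d$max_rate
  bandwidth <- bandwidth %||% d$bandwidth
  .check(nSub >= 1, "nSub must be >= 1")
  .check(spontaneousRate >= 0 && maxRate > spontaneousRate,
         "need 0 <= spontaneous rate < maximal rate")
  .check(bandwidth > 0, "bandwidth must be > 0")
  bestFreq <- if (nSub == 1) 0 else
    seq(-octaveSpan / 2, octaveSpan / 2, length.out = nSub)
  structure(list(nSub = as.integer(nSub), octaveSpan = octaveSpan,
                 spontaneousRate = spontaneousRate, maxRate = maxRate,
                 bandwidth = bandwidth, bestFreq = bestFreq,
                 sigma = bandwidth / (2 * sqrt(2 * log(2)))),
            class = "TuningSpec")
}

#' Raised-Gaussian tuning curve
#'
#' Firing rate of a sub-population with the given best frequency in response
#' to a tone:
#' \deqn{r(f) = r_0 + (r_{max} - r_0)\,e^{-(f - f_{best})^2 / 2\sigma^2},}
#' with `sigma = bandwidth / (2 sqrt(2 ln 2))` so that the rate at
#' `bandwidth/2` octaves from the best frequency is exactly half-way between
#' the maximal and spontaneous rates.
#'
#' @param toneFreq Tone frequency (octaves); vectorised.
#' @param bestFreq Best frequency (octaves); vectorised.
#' @param spec A [tuningSpec()].
#' @return Firing rate(s) (Hz).
#' @export
tuningRate <- function(toneFreq, bestFreq, spec) {
  spec$spontaneousRate + (spec$maxRate - spec$spontaneousRate) *
    exp(-(toneFreq - bestFreq)^2 / (2 * spec$sigma^2))
}

#' Per-sub-population drive rates at a time point
#'
#' During a tone each sub-population fires at its [tuningRate()] for the
#' tone frequency; between tones all sub-populations fire at the spontaneous
#' rate.
#'
#' @param sequence A [ToneSequence-class].
#' @param tuning A [tuningSpec()].
#' @param t Time (ms), scalar, >= 0.
#' @return Numeric vector of rates (Hz), one per sub-population.
#' @export
driveRates <- function(sequence, tuning, t) {
  .check(t >= 0, "t must be >= 0")
  ev <- sequence@events
  k <- findInterval(t, ev$onset)
  if (k >= 1 && t < ev$onset[k] + ev$duration[k]) {
    tuningRate(ev$freq[k], tuning$bestFreq, tuning)
  } else {
    rep(tuning$spontaneousRate, tuning$nSub)
  }
}

# internal: regular onset grid
.onsets <- function(n, ioi) (seq_len(n) - 1) * ioi

#' Generate an oddball sequence pair
#'
#' Two-tone oddball protocol: tone roles are drawn i.i.d. with deviant
#' probability `p`; the two frequencies sit equally spaced on the octave
#' axis around the centre of the input range (at -deltaF/2 and +deltaF/2).
#' The sequence is returned together with its frequency-swapped twin, which
#' preserves the exact pattern of standards and deviants so that each
#' frequency is observed in both roles.
#'
#' @param deltaF Frequency separation between the two tones (octaves).
#' @param p Deviant probability; must lie in (0, 0.5] (at 0.5 the protocol
#'   is the equiprobable control condition).
#' @param nTones Number of tones per presentation.
#' @param ioi Inter-onset interval (ms).
#' @param duration Tone duration (ms).
#' @param seed RNG seed.
#' @return List with elements `first` and `second` ([ToneSequence-class]):
#'   in `first` the deviant is the high tone, in `second` the frequencies
#'   are exchanged under the same role pattern.
#' @export
makeOddball <- function(deltaF, p, nTones = 800L, ioi = 1000, duration = 100,
                        seed = 1L) {
  .check(p > 0 && p <= 0.5,
         "deviant probability must lie in (0, 0.5]: the deviant is the minority (or equiprobable control)")
  .check(nTones > 0, "nTones must be > 0")
  set.seed(seed)
  dev <- runif(nTones) < p
  role <- ifelse(dev, "deviant", "standard")
  fLow <- -deltaF / 2
  fHigh <- deltaF / 2
  onset <- .onsets(nTones, ioi)
  first <- toneSequence(onset, rep(duration, nTones),
                        ifelse(dev, fHigh, fLow), role, ioi = ioi,
                        protocol = "oddball", seed = seed)
  second <- toneSequence(onset, rep(duration, nTones),
                         ifelse(dev, fLow, fHigh), role, ioi = ioi,
                         protocol = "oddball-swapped", seed = seed)
  list(first = first, second = second)
}

#' Two-state Markov chain specification
#'
#' @param p Deviant probability (stationary), in (0, 0.5].
#' @param s Scaled switching metric in \[0, 1\]: 0 never switches, 1
#'   switches at the highest rate compatible with stationary probability
#'   `p`. The i.i.d. oddball sequence is the special case
#'   `s = (1 - p) / qmax`.
#' @param nTones Number of tones per presentation.
#' @param deltaF Frequency separation (octaves).
#' @param ioi Inter-onset interval (ms).
#' @param duration Tone duration (ms).
#' @return A list of class `MarkovSpec`.
#' @export
markovSpec <- function(p, s, nTones = 1000L, deltaF = 0.5, ioi = 1000,
                       duration = 100) {
  .check(p > 0 && p <= 0.5, "p must lie in (0, 0.5]")
  .check(s >= 0 && s <= 1, "s must lie in [0, 1]")
  .check(nTones > 0, "nTones must be > 0")
  structure(list(p = p, s = s, nTones = as.integer(nTones), deltaF = deltaF,
                 ioi = ioi, duration = duration),
            class = "MarkovSpec")
}

#' Transition matrix of the two-state (deviant/standard) Markov chain
#'
#' States are ordered (deviant, standard). The deviant-to-standard
#' transition probability is `qDS = s * qmax` with
#' `qmax = min(1, (1 - p) / p)` -- the largest switching rate compatible
#' with a stationary deviant probability `p`; the standard-to-deviant
#' probability follows from the stationarity balance
#' `p * qDS = (1 - p) * qSD`. The stationary distribution is therefore
#' `(p, 1 - p)` for any `s > 0`, and the i.i.d. oddball sequence is
#' recovered at `s = (1 - p) / qmax`, where both rows equal `(p, 1 - p)`.
#'
#' @param p Deviant probability, in (0, 0.5].
#' @param s Scaled switching metric in \[0, 1\]. At `s = 0` the chain is
#'   frozen (identity matrix); the matrix is returned with attribute
#'   `frozen = TRUE`.
#' @return A 2x2 row-stochastic matrix with dimnames
#'   `c("deviant", "standard")` and attributes `oddballS` (the s-value of
#'   the i.i.d. special case) and `frozen`.
#' @export
#' @examples
#' m <- markovTransitionMatrix(0.3, 1)
#' m                      # switches as often as stationarity allows
#' attr(markovTransitionMatrix(0.3, 0.7), "oddballS")
markovTransitionMatrix <- function(p, s) {
  .check(p > 0 && p <= 0.5, "p must lie in (0, 0.5]")
  .check(s >= 0 && s <= 1, "s must lie in [0, 1]")
  qmax <- min(1, (1 - p) / p)
  qDS <- s * qmax
  qSD <- p * qDS / (1 - p)
  m <- matrix(c(1 - qDS, qDS, qSD, 1 - qSD), nrow = 2, byrow = TRUE,
              dimnames = list(c("deviant", "standard"),
                              c("deviant", "standard")))
  structure(m, oddballS = (1 - p) / qmax, frozen = (s == 0))
}

#' Generate a Markov tone sequence pair
#'
#' Realises the two-state chain from its stationary initial distribution and
#' returns the sequence together with its frequency-swapped twin sharing the
#' same role pattern. Deviants sit at `+deltaF/2` in the first presentation.
#'
#' @param spec A [markovSpec()], or the deviant probability `p` if `s` is
#'   given.
#' @param s,nTones,deltaF,ioi,duration Used only when `spec` is numeric.
#' @param seed RNG seed.
#' @param initialState Required when `s = 0` (frozen chain: the stationary
#'   start is undefined); `"deviant"` or `"standard"`.
#' @return List with elements `first` and `second` ([ToneSequence-class]).
#' @export
makeMarkov <- function(spec, s = NULL, nTones = 1000L, deltaF = 0.5,
                       ioi = 1000, duration = 100, seed = 1L,
                       initialState = NULL) {
  if (!is(spec, "MarkovSpec")) {
    spec <- markovSpec(spec, s, nTones = nTones, deltaF = deltaF, ioi = ioi,
                       duration = duration)
  }
  m <- markovTransitionMatrix(spec$p, spec$s)
  set.seed(seed)
  n <- spec$nTones
  state <- integer(n)   # 1 = deviant, 2 = standard
  if (spec$s == 0) {
    .check(!is.null(initialState),
           "s = 0 freezes the chain: supply initialState explicitly")
    state[1] <- match(match.arg(initialState, c("deviant", "standard")),
                      c("deviant", "standard"))
  } else {
    state[1] <- if (runif(1) < spec$p) 1L else 2L
  }
  u <- runif(n)
  for (k in seq_len(n - 1)) {
    state[k + 1] <- if (u[k] < m[state[k], 1]) 1L else 2L
  }
  dev <- state == 1L
  role <- ifelse(dev, "deviant", "standard")
  onset <- .onsets(n, spec$ioi)
  fLow <- -spec$deltaF / 2; fHigh <- spec$deltaF / 2
  list(first = toneSequence(onset, rep(spec$duration, n),
                            ifelse(dev, fHigh, fLow), role, ioi = spec$ioi,
                            protocol = "markov", seed = seed),
       second = toneSequence(onset, rep(spec$duration, n),
                             ifelse(dev, fLow, fHigh), role, ioi = spec$ioi,
                             protocol = "markov-swapped", seed = seed))
}

#' Generate block / sequential / random multi-tone grids
#'
#' `nFreq` frequencies, each presented exactly `nRep` times, spaced
#' uniformly on the octave axis and centred on the input range. In block
#' mode, identical frequencies are presented in blocks ascending from the
#' lowest to the highest; in sequential mode an ascending stepwise series is
#' repeated `nRep` times; in random mode the same multiset of tones is
#' ordered randomly. Roles carry the 1-based frequency position index.
#'
#' @param mode `"block"`, `"sequential"` or `"random"`.
#' @param nFreq,nRep Number of frequencies and repetitions (>= 1).
#' @param octaveSpacing Spacing between adjacent frequencies (octaves).
#' @param ioi Inter-onset interval (ms).
#' @param duration Tone duration (ms).
#' @param seed RNG seed (used by random mode only).
#' @return A [ToneSequence-class].
#' @export
makeGridSequence <- function(mode = c("block", "sequential", "random"),
                             nFreq = 10L, nRep = 10L, octaveSpacing = 0.2,
                             ioi = 1000, duration = 100, seed = 1L) {
  mode <- match.arg(mode)
  .check(nFreq >= 1 && nRep >= 1, "nFreq and nRep must be >= 1")
  idx <- switch(mode,
    block = rep(seq_len(nFreq), each = nRep),
    sequential = rep(seq_len(nFreq), times = nRep),
    random = { set.seed(seed); sample(rep(seq_len(nFreq), each = nRep)) })
  freqs <- (seq_len(nFreq) - (nFreq + 1) / 2) * octaveSpacing
  n <- nFreq * nRep
  toneSequence(.onsets(n, ioi), rep(duration, n), freqs[idx],
               as.character(idx), ioi = ioi, protocol = mode,
               seed = if (mode == "random") seed else NA_integer_)
}

#' Generate a many-standards control pair
#'
#' Builds a single-standard oddball sequence and its matched many-standards
#' control. In the oddball sequence, exactly `p * nTones` deviant slots are
#' drawn at random; the deviant frequency occupies those slots and a single
#' standard frequency fills the rest. In the control, the deviant frequency
#' appears in exactly the same slots, while the remaining slots are filled
#' by the non-deviant positions in balanced counts (each used equally often,
#' in random order), making all tones equiprobable up to rounding.
#'
#' @param positions Distinct tone frequencies (octaves).
#' @param deviantIndex Index into `positions` of the deviant tone.
#' @param standardIndex Index into `positions` of the single standard used
#'   in the oddball sequence.
#' @param nTones Total tones; `p * nTones` must be a whole number and the
#'   remaining standard count must divide evenly among the non-deviant
#'   positions for the control.
#' @param p Deviant probability.
#' @param ioi,duration Timing (ms).
#' @param seed RNG seed.
#' @return List with elements `oddball` and `control`
#'   ([ToneSequence-class]); role is `"deviant"` in the deviant slots and
#'   `"standard"` elsewhere in both sequences.
#' @export
makeManyStandards <- function(positions, deviantIndex, standardIndex,
                              nTones = 1000L, p = 0.1, ioi = 1000,
                              duration = 100, seed = 1L) {
  .check(!anyDuplicated(positions), "positions must be distinct")
  .check(deviantIndex %in% seq_along(positions) &&
           standardIndex %in% seq_along(positions) &&
           deviantIndex != standardIndex,
         "deviantIndex and standardIndex must be distinct position indices")
  nDev <- p * nTones
  .check(abs(nDev - round(nDev)) < 1e-9, "p * nTones must be an integer")
  nDev <- as.integer(round(nDev))
  nStd <- nTones - nDev
  nOther <- length(positions) - 1L
  if (nStd %% nOther != 0) {
    feasible <- nOther * ceiling(nStd / nOther) / (1 - p)
    stop(sprintf(paste0("control standards (%d) do not divide evenly among ",
                        "%d non-deviant positions; nearest feasible nTones ",
                        "is %d"), nStd, nOther, as.integer(round(feasible))),
         call. = FALSE)
  }
  set.seed(seed)
  devSlots <- sort(sample(nTones, nDev))
  isDev <- seq_len(nTones) %in% devSlots
  role <- ifelse(isDev, "deviant", "standard")
  onset <- .onsets(nTones, ioi)
  fOdd <- ifelse(isDev, positions[deviantIndex], positions[standardIndex])
  others <- positions[-deviantIndex]
  fill <- sample(rep(others, each = nStd %/% nOther))
  fCtl <- numeric(nTones)
  fCtl[isDev] <- positions[deviantIndex]
  fCtl[!isDev] <- fill
  list(oddball = toneSequence(onset, rep(duration, nTones), fOdd, role,
                              ioi = ioi, protocol = "many-standards-oddball",
                              seed = seed),
       control = toneSequence(onset, rep(duration, nTones), fCtl, role,
                              ioi = ioi, protocol = "many-standards-control",
                              seed = seed))
}

#' Write / read a ToneSequence as a tab-separated annotation file
#'
#' One row per tone with columns `onset_ms`, `duration_ms`, `freq_octaves`,
#' `role`; the inter-onset interval, protocol tag and seed are stored in
#' `#`-prefixed header lines so the round trip is lossless.
#'
#' @param x A [ToneSequence-class].
#' @param file Path.
#' @return `writeToneSequence` returns `file` invisibly; `readToneSequence`
#'   returns a [ToneSequence-class].
#' @export
writeToneSequence <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ioi_ms\t%.9g", x@ioi),
               sprintf("# protocol\t%s", x@protocol),
               sprintf("# seed\t%d", x@seed),
               "onset_ms\tduration_ms\tfreq_octaves\trole"), con)
  ev <- x@events
  write.table(data.frame(ev$onset, ev$duration, ev$freq, ev$role),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @rdname writeToneSequence
#' @export
readToneSequence <- function(file) {
  hdr <- readLines(file, n = 3)
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  vals <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  ev <- read.table(file, sep = "\t", header = TRUE, skip = 3,
                   stringsAsFactors = FALSE)
  toneSequence(ev$onset_ms, ev$duration_ms, ev$freq_octaves, ev$role,
               ioi = as.numeric(vals[["ioi_ms"]]),
               protocol = vals[["protocol"]],
               seed = as.integer(vals[["seed"]]))
}
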