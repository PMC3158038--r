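# Reproducible experiment runners. Each runner mirrors one of the standard
# SSA protocols: it generates the stimulus pair, simulates both
# presentations on a shared network instance, and reduces the spike records
# to the protocol's read-out. Default problem sizes are the scaled-down
# suite (8 AdEx units per population, 24 two-tone sub-populations, 200-tone
# sequences); full-scale values are 48 / 96 (144 multi-tone) / 800-1000.

# deterministic child seed for condition i under a root seed
.childSeed <- function(root, i) {
  as.integer((as.numeric(root) * 10007 + i * 101) %% 2147483647L)
}

# simulate a first/second presentation pair and return the SIResult plus
# pooled per-role counts
.runPair <- function(network, pair, population = "B", window = NULL,
                     seed = 1L, dt = 0.1) {
  rec1 <- simulateNetwork(network, pair$first, dt = dt, seed = seed)
  rec2 <- simulateNetwork(network, pair$second, dt = dt, seed = seed + 1L)
  t1 <- countSpikes(rec1, pair$first, window = window, population = population)
  t2 <- countSpikes(rec2, pair$second, window = window, population = population)
  si <- computeSI(t1, t2)
  both <- rbind(t1, t2)
  list(si = si, tables = list(t1, t2),
       records = list(rec1, rec2),
       meanDeviant = mean(both$count[both$role == "deviant"]),
       meanStandard = mean(both$count[both$role == "standard"]))
}

#' Oddball grid experiment
#'
#' Runs the oddball protocol over a (deltaF, p) condition grid plus the
#' equiprobable control (p = 0.5), on one shared network instance. Each
#' condition is an oddball pair (sequence plus frequency-swapped twin); the
#' read-out is the per-unit SSA index table with its population summary.
#'
#' @param architecture Network architecture (default `"ABC"`).
#' @param deltaF Frequency separations (octaves) to cross.
#' @param p Deviant probabilities to cross.
#' @param control Include the p = 0.5 control condition (at `max(deltaF)`).
#' @param nB,nSub Network scale.
#' @param nTones Tones per presentation.
#' @param ioi,duration Tone timing (ms). The scaled suite presents tones
#'   at a fast rate: SSA grows as the inter-onset interval shrinks, and at
#'   desk scale the fast regime is the one with enough statistical power
#'   for an 8-unit population (see the methods vignette).
#' @param weights Optional pathway weight overrides (see
#'   [architectureSpec()]).
#' @param window Spike-count window relative to tone onset; the runners
#'   default to the onset-limited window `c(0, duration)`.
#' @param seed Root seed; condition seeds are derived deterministically.
#' @return A list of class `OddballGrid`: `summary` (a `data.frame` with
#'   `deltaF`, `p`, `medianSI`, `pValue`, `meanDeviant`, `meanStandard`)
#'   and `results` (named list of [SIResult-class]).
#' @export
runOddballGrid <- function(architecture = "ABC", deltaF = c(0.1, 0.5),
                           p = c(0.1, 0.3), control = TRUE, nB = 8L,
                           nSub = 24L, nTones = 200L, ioi = 250,
                           duration = 50, weights = NULL, window = NULL,
                           seed = 1L) {
  if (is.null(window)) window <- c(0, duration)
  net <- buildNetwork(architectureSpec(architecture, nB = nB, nSub = nSub,
                                       weights = weights, seed = seed))
  grid <- expand.grid(deltaF = deltaF, p = p)
  if (control) grid <- rbind(grid, data.frame(deltaF = max(deltaF), p = 0.5))
  results <- list()
  summary <- grid
  summary$medianSI <- NA_real_; summary$pValue <- NA_real_
  summary$meanDeviant <- NA_real_; summary$meanStandard <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cs <- .childSeed(seed, i)
    pair <- makeOddball(grid$deltaF[i], grid$p[i], nTones = nTones,
                        ioi = ioi, duration = duration, seed = cs)
    run <- .runPair(net, pair, window = window, seed = cs + 1L)
    run$si@condition <- sprintf("deltaF=%g, p=%g", grid$deltaF[i], grid$p[i])
    results[[run$si@condition]] <- run$si
    summary$medianSI[i] <- run$si@medianSI
    summary$pValue[i] <- run$si@pValue
    summary$meanDeviant[i] <- run$meanDeviant
    summary$meanStandard[i] <- run$meanStandard
  }
  structure(list(summary = summary, results = results, seed = seed),
            class = "OddballGrid")
}

#' SSA index versus inter-onset interval
#'
#' Oddball runs at fixed (deltaF, p) over a set of inter-onset intervals,
#' with a decaying exponential fit attached; `predict(isi)` on the fit
#' reads off the expected SI at an arbitrary interval.
#'
#' @param isi Inter-onset intervals (ms), at least 3.
#' @param deltaF,p Fixed oddball condition.
#' @inheritParams runOddballGrid
#' @return A list of class `IsiSweep`: `summary` (`data.frame` with `isi`,
#'   `medianSI`, `pValue`), `fit` (an `ExpFit`), `results`.
#' @export
runIsiSweep <- function(isi = c(250, 500, 1000, 2000), deltaF = 0.5, p = 0.1,
                        architecture = "ABC", nB = 8L, nSub = 24L,
                        nTones = 200L, duration = 100, weights = NULL,
                        window = NULL, seed = 1L) {
  .check(length(isi) >= 3, "need at least 3 inter-onset intervals")
  .check(all(isi > duration), "isi must exceed the tone duration")
  if (is.null(window)) window <- c(0, duration)
  net <- buildNetwork(architectureSpec(architecture, nB = nB, nSub = nSub,
                                       weights = weights, seed = seed))
  results <- list()
  out <- data.frame(isi = isi, medianSI = NA_real_, pValue = NA_real_)
  for (i in seq_along(isi)) {
    cs <- .childSeed(seed, i)
    pair <- makeOddball(deltaF, p, nTones = nTones, ioi = isi[i],
                        duration = duration, seed = cs)
    win <- window
    run <- .runPair(net, pair, window = win, seed = cs + 1L)
    run$si@condition <- sprintf("isi=%g", isi[i])
    results[[run$si@condition]] <- run$si
    out$medianSI[i] <- run$si@medianSI
    out$pValue[i] <- run$si@pValue
  }
  fit <- fitExponential(out$isi, out$medianSI, form = "decay")
  structure(list(summary = out, fit = fit, results = results, seed = seed),
            class = "IsiSweep")
}

#' SSA index over an (inter-onset interval, tone duration) grid
#'
#' Oddball runs over a grid of inter-onset intervals and tone durations.
#' Cells with equal offset-to-onset recovery time (isi - duration) lie on
#' unit-slope diagonals; the attached diagnostic groups cells by recovery
#' time for the iso-recovery comparison.
#'
#' @param isi,duration Grid axes (ms); all `isi` must exceed all
#'   `duration`.
#' @inheritParams runIsiSweep
#' @return A list of class `DurationSweep`: `summary` (`data.frame` with
#'   `isi`, `duration`, `recovery`, `medianSI`) and `byRecovery`
#'   (`data.frame` of mean/sd SI per recovery time; single-cell grids get
#'   no comparison).
#' @export
runDurationSweep <- function(isi = c(350, 600, 850), duration = c(50, 300),
                             deltaF = 0.5, p = 0.1, architecture = "ABC",
                             nB = 8L, nSub = 24L, nTones = 200L,
                             weights = NULL, seed = 1L) {
  .check(all(outer(isi, duration, `-`) > 0),
         "every isi must exceed every duration")
  net <- buildNetwork(architectureSpec(architecture, nB = nB, nSub = nSub,
                                       weights = weights, seed = seed))
  grid <- expand.grid(isi = isi, duration = duration)
  grid$recovery <- grid$isi - grid$duration
  grid$medianSI <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cs <- .childSeed(seed, i)
    pair <- makeOddball(deltaF, p, nTones = nTones, ioi = grid$isi[i],
                        duration = grid$duration[i], seed = cs)
    # one common onset window across cells so that the iso-recovery
    # comparison is not confounded by window length
    run <- .runPair(net, pair, window = c(0, min(duration)),
                    seed = cs + 1L)
    grid$medianSI[i] <- run$si@medianSI
  }
  byRec <- NULL
  if (nrow(grid) > 1) {
    recs <- sort(unique(grid$recovery))
    byRec <- data.frame(recovery = recs,
                        meanSI = vapply(recs, function(r)
                          mean(grid$medianSI[grid$recovery == r]), 0),
                        sdSI = vapply(recs, function(r)
                          sd(grid$medianSI[grid$recovery == r]), 0),
                        nCells = vapply(recs, function(r)
                          sum(grid$recovery == r), 0))
  }
  structure(list(summary = grid, byRecovery = byRec, seed = seed),
            class = "DurationSweep")
}

#' Markov-chain stimulus sweep
#'
#' Responses to two-state Markov sequences over a grid of deviant
#' probabilities and scaled switching metrics: mean deviant and standard
#' spike counts and the SSA index per (p, s) cell. Infeasible cells are
#' skipped with a message.
#'
#' @param p Deviant probabilities.
#' @param s Scaled switching metrics.
#' @param population Population to analyse (`"B"`, or `"D"` for ABD).
#' @param deltaF,ioi,duration Stimulus parameters (ms, octaves). The fast
#'   default rate keeps the response to a deviant sensitive to its
#'   immediate predecessors: at slow rates a single inter-onset interval
#'   restores enough synaptic resource that the thresholded response
#'   saturates and switching effects vanish.
#' @inheritParams runOddballGrid
#' @return A list of class `MarkovSweep`: `summary` (`data.frame` with `p`,
#'   `s`, `meanDeviant`, `meanStandard`, `medianSI`, `pValue`) and
#'   `results`.
#' @export
runMarkovSweep <- function(p = 0.3, s = c(0.25, 0.5, 0.75, 1),
                           architecture = "ABC", population = "B",
                           deltaF = 0.5, nB = 8L, nSub = 24L,
                           nTones = 200L, ioi = 250, duration = 50,
                           weights = NULL, window = NULL, seed = 1L) {
  if (is.null(window)) window <- c(0, duration)
  net <- buildNetwork(architectureSpec(architecture, nB = nB, nSub = nSub,
                                       weights = weights, seed = seed))
  grid <- expand.grid(p = p, s = s)
  ok <- grid$s > 0
  if (any(!ok)) message("skipping frozen (s = 0) cells: ",
                        sum(!ok), " of ", nrow(grid))
  grid <- grid[ok, , drop = FALSE]
  results <- list()
  grid$meanDeviant <- NA_real_; grid$meanStandard <- NA_real_
  grid$medianSI <- NA_real_; grid$pValue <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cs <- .childSeed(seed, i)
    pair <- makeMarkov(markovSpec(grid$p[i], grid$s[i], nTones = nTones,
                                  deltaF = deltaF, ioi = ioi,
                                  duration = duration), seed = cs)
    run <- .runPair(net, pair, population = population, window = window,
                    seed = cs + 1L)
    run$si@condition <- sprintf("p=%g, s=%g", grid$p[i], grid$s[i])
    results[[run$si@condition]] <- run$si
    grid$meanDeviant[i] <- run$meanDeviant
    grid$meanStandard[i] <- run$meanStandard
    grid$medianSI[i] <- run$si@medianSI
    grid$pValue[i] <- run$si@pValue
  }
  structure(list(summary = grid, results = results, seed = seed),
            class = "MarkovSweep")
}

#' Block / sequential / random grid modes
#'
#' Presents the three multi-tone grid configurations (same frequency
#' multiset, different orderings) and compares the per-tone spike-count
#' distributions, optionally repeating the whole set with depression on the
#' input pathway disabled (the non-habituating control).
#'
#' @param nFreq,nRep Grid structure (default 10 x 10).
#' @param octaveSpacing Frequency spacing (octaves).
#' @param withDisabled Also run with A->B depression disabled.
#' @inheritParams runOddballGrid
#' @return A list of class `GridModes`: `summary` (`data.frame` with
#'   `mode`, `depression`, `grandMean`), `perTone` (named list of per-tone
#'   mean-count vectors) and `ks` (`data.frame` of pairwise KS tests within
#'   each depression state).
#' @export
runGridModes <- function(architecture = "ABC", nFreq = 10L, nRep = 10L,
                         octaveSpacing = 0.2, nB = 8L, nSub = 24L,
                         ioi = 250, duration = 50, withDisabled = TRUE,
                         weights = NULL, window = NULL, seed = 1L) {
  net <- buildNetwork(architectureSpec(architecture, nB = nB, nSub = nSub,
                                       weights = weights, seed = seed))
  modes <- c("block", "sequential", "random")
  states <- if (withDisabled) c(TRUE, FALSE) else TRUE
  summary <- expand.grid(mode = modes, depression = states,
                         stringsAsFactors = FALSE)
  summary$grandMean <- NA_real_
  perTone <- list()
  i <- 0L
  for (dep in states) {
    netUse <- setDepressionEnabled(net, "AtoB", dep)
    for (m in modes) {
      i <- i + 1L
      cs <- .childSeed(seed, i)
      sq <- makeGridSequence(m, nFreq = nFreq, nRep = nRep,
                             octaveSpacing = octaveSpacing, ioi = ioi,
                             duration = duration, seed = cs)
      rec <- simulateNetwork(netUse, sq, seed = cs + 1L)
      tab <- countSpikes(rec, sq, window = window)
      pt <- as.numeric(tapply(tab$count, tab$tone, mean))
      key <- sprintf("%s_%s", m, if (dep) "depressing" else "disabled")
      perTone[[key]] <- pt
      row <- summary$mode == m & summary$depression == dep
      summary$grandMean[row] <- mean(tab$count)
    }
  }
  ks <- do.call(rbind, lapply(states, function(dep) {
    suf <- if (dep) "depressing" else "disabled"
    combs <- utils::combn(modes, 2)
    do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- perTone[[sprintf("%s_%s", combs[1, j], suf)]]
      b <- perTone[[sprintf("%s_%s", combs[2, j], suf)]]
      data.frame(mode1 = combs[1, j], mode2 = combs[2, j],
                 depression = dep, p.value = ksCountTest(a, b)$p.value)
    }))
  }))
  structure(list(summary = summary, perTone = perTone, ks = ks, seed = seed),
            class = "GridModes")
}

#' Deviants amongst many standards
#'
#' For each frequency separation, runs the single-standard oddball sequence
#' and its matched many-standards control on an ABD network and compares
#' the mean responses to standards, true (oddball) deviants and control
#' deviants in populations B and D. A crossing point of the two deviant
#' curves, where present, is estimated by piecewise-linear interpolation.
#'
#' @param positions Tone positions (octaves); default six positions spaced
#'   0.5 octaves around the centre of a 3-octave input range.
#' @param conditions `data.frame` with columns `deviantIndex` and
#'   `standardIndex` (indices into `positions`); the default pairs the
#'   upper positions with their mirror-symmetric lower positions.
#' @param nTones,p Sequence length and deviant probability (must satisfy
#'   the balancing divisibility of [makeManyStandards()]).
#' @param ioi,duration Tone timing (ms); the default fast rate keeps SSA in
#'   population B strong enough to engage the second depressing layer.
#' @inheritParams runOddballGrid
#' @return A list of class `ManyStandards`: `summary` (`data.frame` with
#'   `deltaF`, `population`, `meanStandard`, `meanDeviantOddball`,
#'   `meanDeviantControl`) and `crossing` (named numeric: interpolated
#'   crossing deltaF per population, `NA` if the curves do not cross).
#' @export
runManyStandards <- function(positions = c(-1.25, -0.75, -0.25, 0.25, 0.75,
                                           1.25),
                             conditions = NULL, nTones = 200L, p = 0.1,
                             architecture = "ABD", nB = 8L, nSub = 36L,
                             octaveSpan = 3, ioi = 250, duration = 50,
                             weights = NULL, window = NULL, seed = 1L) {
  if (is.null(window)) window <- c(0, duration)
  if (is.null(conditions)) {
    nPos <- length(positions)
    hi <- which(positions > 0)
    conditions <- data.frame(deviantIndex = hi,
                             standardIndex = nPos + 1L - hi)
  }
  net <- buildNetwork(architectureSpec(architecture, nB = nB, nSub = nSub,
                                       octaveSpan = octaveSpan,
                                       weights = weights, seed = seed))
  pops <- intersect(c("B", "D"), names(populationSizes(net)))
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cs <- .childSeed(seed, i)
    di <- conditions$deviantIndex[i]; sx <- conditions$standardIndex[i]
    pair <- makeManyStandards(positions, di, sx, nTones = nTones, p = p,
                              ioi = ioi, duration = duration, seed = cs)
    recOdd <- simulateNetwork(net, pair$oddball, seed = cs + 1L)
    recCtl <- simulateNetwork(net, pair$control, seed = cs + 2L)
    for (pop in pops) {
      tOdd <- countSpikes(recOdd, pair$oddball, window = window,
                          population = pop)
      tCtl <- countSpikes(recCtl, pair$control, window = window,
                          population = pop)
      rows[[length(rows) + 1L]] <- data.frame(
        deltaF = abs(positions[di] - positions[sx]), population = pop,
        meanStandard = mean(tOdd$count[tOdd$role == "standard"]),
        meanDeviantOddball = mean(tOdd$count[tOdd$role == "deviant"]),
        meanDeviantControl = mean(tCtl$count[tCtl$role == "deviant"]))
    }
  }
  summary <- do.call(rbind, rows)
  crossing <- vapply(pops, function(pop) {
    sub <- summary[summary$population == pop, ]
    sub <- sub[order(sub$deltaF), ]
    d <- sub$meanDeviantOddball - sub$meanDeviantControl
    ix <- which(d[-1] * d[-length(d)] < 0)
    if (length(ix) == 0) return(NA_real_)
    i <- ix[1]
    sub$deltaF[i] + (0 - d[i]) * (sub$deltaF[i + 1] - sub$deltaF[i]) /
      (d[i + 1] - d[i])
  }, numeric(1))
  structure(list(summary = summary, crossing = crossing, seed = seed),
            class = "ManyStandards")
}

#' Pathway-weight calibration sweep
#'
#' Replays the hand-tuning workflow: sweeps one pathway weight while all
#' other parameters are held at their defaults and records the median SSA
#' index (and mean counts) in a fixed oddball condition. The shipped weight
#' defaults are selected points of such sweeps.
#'
#' @param pathway Pathway whose weight is swept.
#' @param values Weight values (nS).
#' @param deltaF,p Oddball condition used for the read-out.
#' @inheritParams runOddballGrid
#' @return `data.frame` with `weight`, `medianSI`, `pValue`,
#'   `meanDeviant`, `meanStandard`.
#' @export
runCalibration <- function(pathway = "AtoB", values = c(1, 2, 4, 8),
                           architecture = "ABC", deltaF = 0.5, p = 0.1,
                           nB = 8L, nSub = 24L, nTones = 200L, ioi = 1000,
                           duration = 100, seed = 1L) {
  out <- data.frame(weight = values, medianSI = NA_real_, pValue = NA_real_,
                    meanDeviant = NA_real_, meanStandard = NA_real_)
  for (i in seq_along(values)) {
    w <- setNames(values[i], pathway)
    grid <- runOddballGrid(architecture, deltaF = deltaF, p = p,
                           control = FALSE, nB = nB, nSub = nSub,
                           nTones = nTones, ioi = ioi, duration = duration,
                           weights = w, seed = seed)
    out$medianSI[i] <- grid$summary$medianSI[1]
    out$pValue[i] <- grid$summary$pValue[1]
    out$meanDeviant[i] <- grid$summary$meanDeviant[1]
    out$meanStandard[i] <- grid$summary$meanStandard[1]
  }
  out
}
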