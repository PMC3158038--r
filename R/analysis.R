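#' Per-tone spike counts
#'
#' Counts spikes of one population in a window relative to each tone onset,
#' producing the tone-response table all SSA read-outs are built from.
#' Windows are half-open `[onset + w0, onset + w1)`: a spike exactly at the
#' right edge belongs to the next tone's window. The default window is the
#' full onset-to-onset epoch, which captures both phasic and tonic
#' responses.
#'
#' @param record A [SpikeRecord-class].
#' @param sequence The [ToneSequence-class] that produced it.
#' @param window Numeric length-2: window start and end (ms) relative to
#'   tone onset, within `[0, ioi]`.
#' @param population Population to analyse (default `"B"`).
#' @return A `data.frame` with one row per tone x unit: `tone`, `unit`,
#'   `count`, plus tone metadata `role`, `freq`, `onset`. All units that
#'   ever spiked in the record (or `1:maxUnit`) appear for every tone.
#' @export
countSpikes <- function(record, sequence, window = NULL, population = "B") {
  ev <- sequence@events
  if (is.null(window)) window <- c(0, sequence@ioi)
  .check(length(window) == 2 && window[1] < window[2],
         "window must be an increasing length-2 vector")
  .check(window[1] >= 0 && window[2] <= sequence@ioi + 1e-9,
         "window must lie within [0, inter-onset interval]")
  spk <- spikeEvents(record, population)
  nUnit <- if (nrow(spk) > 0) max(spk$unit) else 1L
  nTone <- nrow(ev)
  counts <- matrix(0L, nTone, nUnit)
  if (nrow(spk) > 0) {
    # tone index by onset; half-open window
    toneIdx <- findInterval(spk$time, ev$onset + window[1])
    rel <- spk$time - ev$onset[pmax(toneIdx, 1)] - window[1]
    ok <- toneIdx >= 1 & rel >= 0 & rel < (window[2] - window[1])
    if (any(ok)) {
      tab <- table(factor(toneIdx[ok], levels = seq_len(nTone)),
                   factor(spk$unit[ok], levels = seq_len(nUnit)))
      counts <- matrix(as.integer(tab), nTone, nUnit)
    }
  }
  data.frame(tone = rep(seq_len(nTone), times = nUnit),
             unit = rep(seq_len(nUnit), each = nTone),
             count = as.integer(counts),
             role = rep(ev$role, times = nUnit),
             freq = rep(ev$freq, times = nUnit),
             onset = rep(ev$onset, times = nUnit))
}

#' Frequency-specific SSA index
#'
#' Normalised contrast between the mean responses to one frequency when
#' deviant (`d`) and when standard (`s`): `(d - s) / (d + s)`, confined to
#' `[-1, 1]`. Undefined (`NA`) when `d + s = 0`.
#'
#' @param d,s Mean spike counts (non-negative).
#' @return The index, or `NA` if undefined. Vectorised.
#' @export
siFrequency <- function(d, s) {
  .check(all(d >= 0) && all(s >= 0), "mean counts must be non-negative")
  out <- (d - s) / (d + s)
  out[d + s == 0] <- NA_real_
  out
}

#' Neuron-specific SSA index
#'
#' Pools both frequencies: `(d1 + d2 - s1 - s2) / (d1 + d2 + s1 + s2)`.
#' Undefined (`NA`) on a zero denominator.
#'
#' @param d1,d2,s1,s2 Mean spike counts for the two frequencies as deviant
#'   and as standard (non-negative).
#' @return The index, or `NA` if undefined. Vectorised.
#' @export
siNeuron <- function(d1, d2, s1, s2) {
  .check(all(c(d1, d2, s1, s2) >= 0), "mean counts must be non-negative")
  den <- d1 + d2 + s1 + s2
  out <- (d1 + d2 - s1 - s2) / den
  out[den == 0] <- NA_real_
  out
}

#' SSA indices from a pair of swapped oddball presentations
#'
#' Combines the tone-response tables of the two presentations of an oddball
#' (or Markov) sequence pair -- in which the roles of the two frequencies
#' are exchanged -- into per-unit mean responses `d(f)` and `s(f)` for each
#' frequency, the frequency-specific and neuron-specific SSA indices, and
#' the population summary (median SI with a two-sided Wilcoxon signed-rank
#' test against zero). Units with undefined indices are excluded from the
#' summary, not imputed.
#'
#' @param tableFirst,tableSecond Tone-response tables from [countSpikes()]
#'   for the two presentations.
#' @param condition Label stored in the result.
#' @return An [SIResult-class]. Frequency 1 is the lower of the two tone
#'   frequencies.
#' @export
computeSI <- function(tableFirst, tableSecond, condition = "") {
  tab <- rbind(tableFirst, tableSecond)
  freqs <- sort(unique(tab$freq))
  .check(length(freqs) == 2, "expected exactly two tone frequencies")
  units <- sort(unique(tab$unit))
  m <- function(f, r) {
    sub <- tab[tab$freq == f & tab$role == r, ]
    out <- tapply(sub$count, factor(sub$unit, levels = units), mean)
    as.numeric(out)
  }
  d1 <- m(freqs[1], "deviant"); s1 <- m(freqs[1], "standard")
  d2 <- m(freqs[2], "deviant"); s2 <- m(freqs[2], "standard")
  si <- siNeuron(d1, d2, s1, s2)
  perUnit <- data.frame(unit = units, d1 = d1, d2 = d2, s1 = s1, s2 = s2,
                        si1 = siFrequency(d1, s1), si2 = siFrequency(d2, s2),
                        si = si)
  ok <- !is.na(si)
  med <- if (any(ok)) median(si[ok]) else NA_real_
  pv <- if (sum(ok) >= 5 && any(si[ok] != 0))
    suppressWarnings(wilcox.test(si[ok], mu = 0)$p.value) else NA_real_
  new("SIResult", perUnit = perUnit, frequencies = freqs, medianSI = med,
      pValue = pv, condition = condition)
}

#' Peri-stimulus time histogram
#'
#' Spike-time histogram aligned to tone onsets, averaged over tones and
#' units and converted to a rate in Hz. Separate traces are returned for
#' standard and deviant tones together with their difference (the excess in
#' the deviant response over the standard).
#'
#' @param record A [SpikeRecord-class].
#' @param sequence The matching [ToneSequence-class].
#' @param bin Bin width (ms), default 2.
#' @param population Population to analyse.
#' @param window Length-2 analysis window relative to onset (default the
#'   full onset-to-onset epoch).
#' @return A `data.frame` with columns `t` (bin start, ms relative to
#'   onset), `all`, `standard`, `deviant` (Hz) and `difference`
#'   (deviant - standard, Hz).
#' @export
psth <- function(record, sequence, bin = 2, population = "B",
                 window = NULL) {
  .check(bin > 0, "bin must be > 0")
  ev <- sequence@events
  if (is.null(window)) window <- c(0, sequence@ioi)
  spk <- spikeEvents(record, population)
  nUnit <- if (nrow(spk) > 0) max(spk$unit) else 1L
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  nb <- length(edges) - 1
  trace <- function(toneSel) {
    n <- sum(toneSel)
    if (n == 0 || nrow(spk) == 0) return(rep(0, nb))
    toneIdx <- findInterval(spk$time, ev$onset)
    keep <- toneIdx >= 1 & toneSel[pmax(toneIdx, 1)]
    rel <- spk$time[keep] - ev$onset[toneIdx[keep]]
    inw <- rel >= window[1] & rel < window[2]
    h <- tabulate(findInterval(rel[inw], edges), nbins = nb)
    h / n / nUnit / (diff(edges) / 1000)
  }
  std <- trace(ev$role == "standard")
  dev <- trace(ev$role == "deviant")
  data.frame(t = edges[-length(edges)], all = trace(rep(TRUE, nrow(ev))),
             standard = std, deviant = dev, difference = dev - std)
}

#' History-conditioned deviant responses
#'
#' Mean response to a deviant conditioned on the number of immediately
#' preceding standards (k = 1, 2, ...; deviants preceded by ten or more
#' standards are pooled into one `10+` bin; deviants directly preceded by
#' another deviant form the k = 0 bin), normalised by the grand mean
#' response over all tones. A saturating exponential trend
#' `a - b * exp(-k / tau)` is fitted by non-linear least squares.
#'
#' @param table A tone-response table from [countSpikes()] (any number of
#'   units; tone order defines history).
#' @param pool Pooling threshold (default 10).
#' @return A list of class `HistoryCurve`: `curve` (a `data.frame` with
#'   `k`, `mean`, `se`, `n`), `grandMean`, and `fit` (the [fitExponential()]
#'   result, or `NULL` if the fit is infeasible). Empty result flag
#'   `noDeviants = TRUE` when the table has no deviants.
#' @export
historyConditioned <- function(table, pool = 10L) {
  tones <- table[!duplicated(table$tone), c("tone", "role")]
  tones <- tones[order(tones$tone), ]
  if (!any(tones$role == "deviant")) {
    return(structure(list(noDeviants = TRUE, curve = NULL, fit = NULL),
                     class = "HistoryCurve"))
  }
  # run length of standards immediately preceding each tone
  nStd <- integer(nrow(tones))
  run <- 0L
  for (i in seq_len(nrow(tones))) {
    nStd[i] <- run
    run <- if (tones$role[i] == "standard") run + 1L else 0L
  }
  kOf <- pmin(nStd, pool)
  perTone <- tapply(table$count, table$tone, mean)   # mean over units
  grand <- mean(perTone)
  devSel <- tones$role == "deviant"
  k <- kOf[devSel]
  resp <- as.numeric(perTone[tones$tone[devSel]]) / grand
  agg <- data.frame(k = sort(unique(k)))
  agg$mean <- vapply(agg$k, function(kk) mean(resp[k == kk]), 0)
  agg$se <- vapply(agg$k, function(kk) {
    x <- resp[k == kk]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  }, 0)
  agg$n <- vapply(agg$k, function(kk) sum(k == kk), 0)
  fit <- NULL
  pts <- agg[agg$k > 0, ]
  if (nrow(pts) >= 3) {
    fit <- tryCatch(fitExponential(pts$k, pts$mean, form = "saturating"),
                    error = function(e) NULL)
  }
  structure(list(noDeviants = FALSE, curve = agg, grandMean = grand,
                 fit = fit),
            class = "HistoryCurve")
}

#' Least-squares exponential trend fit
#'
#' Fits either a decaying form `y = asymptote + scale * exp(-x / tau)`
#' (e.g. SI versus inter-onset interval) or a saturating form
#' `y = asymptote - scale * exp(-x / tau)` (e.g. history-conditioned
#' deviant responses) by non-linear least squares, with starting values
#' from a log-linear regression on the transformed data.
#'
#' @param x,y Data (>= 3 points).
#' @param form `"decay"` or `"saturating"`.
#' @return A list of class `ExpFit`: `asymptote`, `scale`, `rate`
#'   (= 1/tau), `tau`, `residualNorm`, `fitted`, `converged`, and a
#'   `predict(newX)` closure. Non-convergence is flagged (`converged =
#'   FALSE`, residual diagnostics retained), never silent.
#' @export
fitExponential <- function(x, y, form = c("decay", "saturating")) {
  form <- match.arg(form)
  .check(length(x) == length(y) && length(x) >= 3, "need at least 3 points")
  sgn <- if (form == "decay") 1 else -1
  # degenerate: flat data
  if (sd(y) < 1e-12) {
    f <- function(newX) rep(mean(y), length(newX))
    return(structure(list(asymptote = mean(y), scale = 0, rate = 0,
                          tau = Inf, residualNorm = 0, fitted = f(x),
                          converged = TRUE, predict = f), class = "ExpFit"))
  }
  # starting values: asymptote slightly beyond the data range, log-linear
  # regression for the rate
  a0 <- if (form == "decay") min(y) - 0.05 * abs(min(y)) - 1e-6
        else max(y) + 0.05 * abs(max(y)) + 1e-6
  z <- sgn * (y - a0)
  pos <- z > 0
  if (sum(pos) >= 2) {
    ll <- lm(log(z[pos]) ~ x[pos])
    r0 <- max(-coef(ll)[[2]], 1e-6)
    s0 <- exp(coef(ll)[[1]])
  } else {
    r0 <- 1 / max(diff(range(x)), 1e-6)
    s0 <- max(abs(y - a0))
  }
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + sgn2 * b * exp(-r * x),
                      data = cbind(df, sgn2 = sgn),
                      start = list(a = a0, b = s0, r = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    pred <- function(newX) a0 + sgn * s0 * exp(-r0 * newX)
    return(structure(list(asymptote = a0, scale = s0, rate = r0,
                          tau = 1 / r0,
                          residualNorm = sqrt(sum((y - pred(x))^2)),
                          fitted = pred(x), converged = FALSE,
                          predict = pred, message = conditionMessage(fit)),
                     class = "ExpFit"))
  }
  cf <- coef(fit)
  pred <- function(newX) cf[["a"]] + sgn * cf[["b"]] * exp(-cf[["r"]] * newX)
  structure(list(asymptote = cf[["a"]], scale = cf[["b"]], rate = cf[["r"]],
                 tau = 1 / cf[["r"]],
                 residualNorm = sqrt(sum(residuals(fit)^2)),
                 fitted = as.numeric(fitted(fit)), converged = TRUE,
                 predict = pred),
            class = "ExpFit")
}

#' Population-level hypothesis tests
#'
#' The three tests used to summarise SSA at the population level:
#'
#' * `signedRankTest()`: two-sided Wilcoxon signed-rank test of the median
#'   SSA index against zero;
#' * `ksCountTest()`: two-sample Kolmogorov-Smirnov test between the
#'   per-tone spike-count distributions of two conditions;
#' * `scatterMajorityTest()`: counts the units whose frequency-specific
#'   index pair falls strictly above the anti-diagonal
#'   (`si1 + si2 > 0`) and attaches a two-sided sign-test p-value.
#'
#' All refuse fewer than 5 observations.
#'
#' @param si,si1,si2 SSA index vectors.
#' @param counts1,counts2 Per-tone spike-count vectors.
#' @return `signedRankTest` and `ksCountTest` return `htest` objects;
#'   `scatterMajorityTest` returns a list with `nAbove`, `nBelow`, `n` and
#'   `p.value`.
#' @name populationTests
NULL

#' @rdname populationTests
#' @export
signedRankTest <- function(si) {
  si <- si[!is.na(si)]
  .check(length(si) >= 5, "need at least 5 defined indices")
  suppressWarnings(wilcox.test(si, mu = 0))
}

#' @rdname populationTests
#' @export
ksCountTest <- function(counts1, counts2) {
  .check(length(counts1) >= 5 && length(counts2) >= 5,
         "need at least 5 counts per condition")
  suppressWarnings(ks.test(counts1, counts2))
}

#' @rdname populationTests
#' @export
scatterMajorityTest <- function(si1, si2) {
  ok <- !is.na(si1) & !is.na(si2)
  .check(sum(ok) >= 5, "need at least 5 defined index pairs")
  tot <- si1[ok] + si2[ok]
  nAbove <- sum(tot > 0)
  nBelow <- sum(tot < 0)
  p <- if (nAbove + nBelow > 0)
    binom.test(nAbove, nAbove + nBelow)$p.value else 1
  list(nAbove = nAbove, nBelow = nBelow, n = sum(ok), p.value = p)
}

#' Write an SIResult as a tab-separated table
#'
#' Per-unit table with a `#`-prefixed header manifest (condition,
#' frequencies, median, p-value).
#'
#' @param x An [SIResult-class].
#' @param file Path.
#' @return `file`, invisibly.
#' @export
writeSIResult <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# condition\t%s", x@condition),
               sprintf("# frequencies\t%.6g\t%.6g", x@frequencies[1],
                       x@frequencies[2]),
               sprintf("# medianSI\t%.9g", x@medianSI),
               sprintf("# pValue\t%.9g", x@pValue)), con)
  suppressWarnings(write.table(x@perUnit, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}
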