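test_that("tuning curve hits its maximal, half-rise and spontaneous rates", {
  tun <- tuningSpec(nSub = 24L, spontaneousRate = 2, maxRate = 100,
                    bandwidth = 0.4)
  expect_equal(tuningRate(0.3, 0.3, tun), 100)
  # half-rise definition: bandwidth/2 away from best gives the midpoint rate
  expect_equal(tuningRate(0.3 + 0.2, 0.3, tun), (100 + 2) / 2)
  expect_equal(tuningRate(0.3 - 0.2, 0.3, tun), (100 + 2) / 2)
  expect_equal(tuningRate(10, 0.3, tun), 2, tolerance = 1e-6)
  # symmetry about the tone frequency
  expect_equal(tuningRate(0.1, 0.1 + 0.15, tun), tuningRate(0.1, 0.1 - 0.15, tun))
})

test_that("oddball pairs share the role pattern with frequencies exchanged", {
  pair <- makeOddball(0.4, 0.2, nTones = 300L, seed = 8)
  e1 <- toneEvents(pair$first); e2 <- toneEvents(pair$second)
  expect_identical(e1$role, e2$role)
  expect_setequal(unique(e1$freq), c(-0.2, 0.2))
  swap <- ifelse(e1$freq > 0, -0.2, 0.2)
  expect_equal(e2$freq, swap)
  # deviants sit on one frequency per presentation
  expect_true(all(e1$freq[e1$role == "deviant"] == 0.2))
  expect_true(all(e2$freq[e2$role == "deviant"] == -0.2))
  expect_error(makeOddball(0.4, 0.6), "0.5")
})

test_that("oddball deviant counts follow the binomial sampling law", {
  pair <- makeOddball(0.5, 0.1, nTones = 800L, seed = 21)
  k <- sum(toneEvents(pair$first)$role == "deviant")
  expect_lt(abs(k - 80), 3 * sqrt(800 * 0.1 * 0.9))
  # determinism
  pair2 <- makeOddball(0.5, 0.1, nTones = 800L, seed = 21)
  expect_identical(toneEvents(pair$first), toneEvents(pair2$first))
})

test_that("Markov transition matrix is stochastic with stationary distribution (p, 1-p)", {
  for (p in c(0.1, 0.3, 0.5)) for (s in c(0.25, 0.5, 0.75, 1)) {
    m <- markovTransitionMatrix(p, s)
    expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-12)
    expect_lt(max(abs(stationaryByPowerIteration(m) - c(p, 1 - p))), 1e-10)
  }
  # the i.i.d. oddball point: both rows equal (p, 1-p)
  p <- 0.3
  m <- markovTransitionMatrix(p, attr(markovTransitionMatrix(p, 1), "oddballS"))
  expect_equal(unname(m[1, ]), unname(m[2, ]), tolerance = 1e-12)
  expect_equal(unname(m[1, ]), c(p, 1 - p), tolerance = 1e-12)
  # maximal switching at equiprobability is strict alternation
  m <- markovTransitionMatrix(0.5, 1)
  expect_equal(unname(m), matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_true(attr(markovTransitionMatrix(0.2, 0), "frozen"))
})

test_that("Markov realizations reproduce the chain statistics", {
  spec <- markovSpec(0.2, 0.5, nTones = 1e5L)
  sq <- makeMarkov(spec, seed = 13)$first
  r <- toneEvents(sq)$role == "deviant"
  m <- markovTransitionMatrix(0.2, 0.5)
  # transition frequencies within 3 binomial standard errors
  fromDev <- which(r[-length(r)])
  pDD <- mean(r[fromDev + 1])
  expect_lt(abs(pDD - m[1, 1]), 3 * sqrt(m[1, 1] * m[1, 2] / length(fromDev)))
  expect_lt(abs(mean(r) - 0.2), 3 * sqrt(0.2 * 0.8 / length(r)))
  # lower s clumps deviants into longer runs
  runLen <- function(s) {
    rr <- toneEvents(makeMarkov(markovSpec(0.2, s, nTones = 2e4L),
                                seed = 5)$first)$role == "deviant"
    with(rle(rr), mean(lengths[values]))
  }
  expect_gt(runLen(0.25), runLen(1))
  expect_error(makeMarkov(markovSpec(0.2, 0)), "initialState")
})

test_that("grid sequences have the printed predecessor combinatorics", {
  adjCount <- function(sq, same) {
    e <- toneEvents(sq)
    idx <- as.integer(e$role)
    d <- abs(diff(idx))
    if (same) sum(d == 0) else sum(d == 1)
  }
  blk <- makeGridSequence("block", 10L, 10L)
  expect_equal(adjCount(blk, TRUE), 90)
  expect_equal(adjCount(blk, FALSE), 9)
  sq <- makeGridSequence("sequential", 10L, 10L)
  expect_equal(adjCount(sq, FALSE), 90)
  expect_equal(sum(abs(diff(as.integer(toneEvents(sq)$role))) > 1), 9)
  rnd <- makeGridSequence("random", 10L, 10L, seed = 2)
  expect_identical(sort(toneEvents(rnd)$freq), sort(toneEvents(blk)$freq))
  for (m in c("block", "sequential", "random")) {
    tab <- table(toneEvents(makeGridSequence(m, 7L, 4L, seed = 3))$role)
    expect_true(all(tab == 4))
  }
})

test_that("many-standards control matches the oddball deviant slots with balanced standards", {
  pos <- seq(-1.25, 1.25, by = 0.5)
  pair <- makeManyStandards(pos, deviantIndex = 5L, standardIndex = 2L,
                            nTones = 1000L, p = 0.1, seed = 4)
  eo <- toneEvents(pair$oddball); ec <- toneEvents(pair$control)
  devSlots <- which(eo$role == "deviant")
  expect_identical(devSlots, which(ec$role == "deviant"))
  expect_true(all(eo$freq[devSlots] == pos[5]))
  expect_true(all(ec$freq[devSlots] == pos[5]))
  # single standard frequency in the oddball sequence
  expect_identical(unique(eo$freq[eo$role == "standard"]), pos[2])
  # balanced counts over the non-deviant positions in the control
  tab <- table(ec$freq[ec$role == "standard"])
  expect_true(all(tab == 180))
  # 990 tones give 891 standards, which do not split evenly over 5 positions
  expect_error(makeManyStandards(pos, 5L, 2L, nTones = 990L, p = 0.1),
               "feasible")
})

test_that("drive rates follow the tone schedule", {
  tun <- tuningSpec(nSub = 9L, octaveSpan = 2)
  sq <- toneSequence(c(0, 500), c(100, 100), c(-0.5, 0.5), c("standard", "deviant"),
                     ioi = 500)
  gap <- driveRates(sq, tun, 300)
  expect_equal(gap, rep(tun$spontaneousRate, 9))
  during <- driveRates(sq, tun, 50)
  expect_equal(during[which.min(abs(tun$bestFreq + 0.5))], tun$maxRate,
               tolerance = 1e-6)
  expect_equal(during, rev(driveRates(sq, tun, 550)))  # mirror tone
})

test_that("tone sequences round-trip through the annotation file", {
  pair <- makeOddball(0.5, 0.25, nTones = 50L, seed = 6)
  f <- tempfile(fileext = ".tsv")
  writeToneSequence(pair$first, f)
  back <- readToneSequence(f)
  expect_equal(toneEvents(back), toneEvents(pair$first))
  expect_equal(back@ioi, pair$first@ioi)
  expect_identical(back@protocol, pair$first@protocol)
  expect_identical(back@seed, pair$first@seed)
})
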