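test_that("full-scale builds satisfy the architecture degree constraints exactly", {
  ab <- buildNetwork(architectureSpec("AB", nB = 48L, nSub = 96L, seed = 1))
  expect_equal(unname(populationSizes(ab)["A"]), 96L * 48L)
  expect_true(all(tabulate(networkPathway(ab, "AtoB")$post, 48) == 96))

  abc <- buildNetwork(architectureSpec("ABC", nB = 48L, nSub = 96L, seed = 1))
  cb <- networkPathway(abc, "CtoB")
  expect_true(all(tabulate(cb$post, 48) == 16))
  expect_equal(anyDuplicated(cb[, c("pre", "post")]), 0L)

  abd <- buildNetwork(architectureSpec("ABD", nB = 48L, nSub = 144L,
                                       octaveSpan = 3, seed = 1))
  expect_equal(nrow(networkPathway(abd, "BtoD")), 48L^2)
  expect_true(all(tabulate(networkPathway(abd, "BtoD")$post, 48) == 48))
  cs <- connectivitySummary(abc)
  expect_equal(cs$inDegreeMin[cs$pathway == "CtoB"], 16)
  expect_equal(cs$inDegreeMax[cs$pathway == "CtoB"], 16)
})

test_that("builds are pure functions of the spec seed and invalid specs are rejected", {
  n1 <- buildNetwork(architectureSpec("ABC", nB = 6L, nSub = 12L, seed = 9))
  n2 <- buildNetwork(architectureSpec("ABC", nB = 6L, nSub = 12L, seed = 9))
  expect_identical(n1@pathways, n2@pathways)
  n3 <- buildNetwork(architectureSpec("ABC", nB = 6L, nSub = 12L, seed = 10))
  expect_false(identical(n1@pathways$AtoB$weight, n3@pathways$AtoB$weight))
  expect_error(architectureSpec("ABC", nB = 8L, inhibitoryInDegree = 20L),
               "in-degree")
})

test_that("simulation is deterministic given the seed", {
  net <- buildNetwork(architectureSpec("ABC", nB = 4L, nSub = 8L, seed = 3))
  sq <- makeOddball(0.5, 0.25, nTones = 5L, ioi = 400, duration = 50,
                    seed = 2)$first
  r1 <- simulateNetwork(net, sq, seed = 7)
  r2 <- simulateNetwork(net, sq, seed = 7)
  expect_identical(r1@events, r2@events)
  r3 <- simulateNetwork(net, sq, seed = 8)
  expect_false(identical(r1@events, r3@events))
})

test_that("with zero pathway weights population B fires at the noise-only rate", {
  net <- buildNetwork(architectureSpec("AB", nB = 4L, nSub = 8L,
                                       weights = c(AtoB = 0), seed = 3))
  sq <- toneSequence(0, 20000, 0, "standard", ioi = 20000)
  rec <- simulateNetwork(net, sq, seed = 5)
  rate <- nrow(spikeEvents(rec, "B")) / 4 / 20
  expect_gt(rate, 2)   # the high-spontaneous preset is calibrated near 5 Hz
  expect_lt(rate, 9)
})

test_that("the compiled engine matches an R-level step-by-step integration", {
  # 1 sub-population, 1 unit, no noise, no jitter, imposed input spikes:
  # the engine and an R loop over the exported single-step operations must
  # produce the same spike train
  net <- buildNetwork(architectureSpec("AB", nB = 1L, nSub = 1L,
                                       noisePreset = NULL,
                                       jitter = jitterSpec(0),
                                       weights = c(AtoB = 60), seed = 1))
  dur <- 2000; dt <- 0.1; nStep <- dur / dt
  sq <- toneSequence(.onsets <- seq(0, 1600, by = 400), rep(100, 5),
                     rep(0, 5), rep("standard", 5), ioi = 400)
  set.seed(31)
  aSpikes <- matrix(0L, nStep, 1)
  tun <- tuningSpec(nSub = 1L, octaveSpan = 2)
  for (k in seq_len(nStep)) {
    r <- driveRates(sq, tun, (k - 1) * dt)
    set.seed(1000 + k)
    aSpikes[k, 1] <- as.integer(poissonSpike(r, dt))
  }
  rec <- simulateNetwork(net, sq, tuning = tun, dt = dt, tEnd = dur,
                         seed = 99, aSpikes = aSpikes)
  engineSpikes <- spikeEvents(rec, "B")$time

  synPar <- synapseParams("depressing", pathway = "AtoB", weight = 60)
  adexPar <- adexParams()
  syn <- synapseState()
  st <- adexState(adexPar$leakReversal, 0)
  oracle <- numeric(0)
  for (k in seq_len(nStep)) {
    syn <- synapseStep(syn, synPar, presynSpike = aSpikes[k, 1] == 1, dt = dt)
    cur <- synapticCurrent(syn, synPar, st[["v"]])
    out <- adexStep(st, adexPar, inputCurrent = cur, dt = dt)
    st <- out$state
    if (out$spike) oracle <- c(oracle, k * dt)
  }
  expect_equal(engineSpikes, oracle, tolerance = 1e-9)
})

test_that("repeated identical tones depress the response, and disabling depression undoes it", {
  net <- buildNetwork(architectureSpec("AB", nB = 8L, nSub = 12L, seed = 4))
  n <- 10
  sq <- toneSequence((seq_len(n) - 1) * 250, rep(50, n), rep(0, n),
                     rep("standard", n), ioi = 250)
  rec <- simulateNetwork(net, sq, seed = 11)
  counts <- tapply(countSpikes(rec, sq, window = c(0, 50))$count,
                   countSpikes(rec, sq, window = c(0, 50))$tone, mean)
  expect_gt(counts[1], mean(counts[6:10]))   # habituation across tones

  netOff <- setDepressionEnabled(net, "AtoB", FALSE)
  recOff <- simulateNetwork(netOff, sq, seed = 11)
  tabOff <- countSpikes(recOff, sq, window = c(0, 50))
  expect_gt(mean(tabOff$count), mean(counts))  # more transmitter available

  # re-enabling restores the original record exactly (same seed)
  netOn <- setDepressionEnabled(netOff, "AtoB", TRUE)
  expect_identical(simulateNetwork(netOn, sq, seed = 11)@events, rec@events)
  expect_error(setDepressionEnabled(net, "XtoY", FALSE), "unknown pathway")
})

test_that("spike records round-trip through the event-table file", {
  net <- buildNetwork(architectureSpec("AB", nB = 2L, nSub = 6L, seed = 5))
  sq <- makeOddball(0.5, 0.25, nTones = 4L, ioi = 300, duration = 50,
                    seed = 2)$first
  rec <- simulateNetwork(net, sq, seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeSpikeRecord(rec, f)
  back <- readSpikeRecord(f)
  expect_equal(back@events$time, rec@events$time)
  expect_identical(back@events$unit, rec@events$unit)
  expect_equal(back@dt, rec@dt)
})
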