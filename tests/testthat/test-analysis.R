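test_that("spike counting uses half-open windows and matches a constructed fixture", {
  sq <- toneSequence(c(0, 500, 1000), rep(100, 3), c(-0.2, 0.2, -0.2),
                     c("standard", "deviant", "standard"), ioi = 500)
  counts <- matrix(c(2, 0, 3,
                     1, 4, 0), nrow = 3)
  rec <- syntheticRecord(sq, counts)
  tab <- countSpikes(rec, sq)
  got <- matrix(tab$count, nrow = 3)
  expect_equal(got, counts)

  # empty record
  emptyRec <- new("SpikeRecord", events = data.frame(population = character(),
                                                     unit = integer(),
                                                     time = numeric()),
                  dt = 0.1, duration = 1500)
  expect_true(all(countSpikes(emptyRec, sq)$count == 0))

  # a spike exactly on the right edge belongs to the next tone's window
  edge <- new("SpikeRecord",
              events = data.frame(population = "B", unit = 1L, time = 500),
              dt = 0.1, duration = 1500)
  tabE <- countSpikes(edge, sq, window = c(0, 500))
  expect_equal(tabE$count, c(0L, 1L, 0L))

  expect_error(countSpikes(rec, sq, window = c(0, 600)), "within")
  expect_error(countSpikes(rec, sq, window = c(100, 50)), "increasing")
})

test_that("SSA index formulas honour their bounds, symmetries and undefined cases", {
  expect_equal(siFrequency(2, 2), 0)
  expect_equal(siFrequency(3, 0), 1)
  expect_equal(siFrequency(0, 3), -1)
  expect_equal(siFrequency(3, 1), 0.5)
  expect_true(is.na(siFrequency(0, 0)))
  expect_error(siFrequency(-1, 2), "non-negative")

  expect_equal(siNeuron(1, 1, 1, 1), 0)
  expect_equal(siNeuron(2, 3, 0, 0), 1)
  expect_true(is.na(siNeuron(0, 0, 0, 0)))
  # joint swap of the frequency labels leaves the index unchanged
  expect_equal(siNeuron(2, 5, 1, 3), siNeuron(5, 2, 3, 1))
  # reduces to the frequency-specific index when responses are identical
  expect_equal(siNeuron(3, 3, 1, 1), siFrequency(3, 1))

  set.seed(2)
  d <- runif(200, 0, 10); s <- runif(200, 0, 10)
  expect_true(all(abs(siFrequency(d, s)) <= 1))
  expect_true(all(abs(siNeuron(d, s, rev(d), rev(s))) <= 1))
})

test_that("computeSI pools the swapped presentations into per-unit indices", {
  sq1 <- toneSequence(c(0, 500, 1000, 1500), rep(100, 4),
                      c(-0.2, 0.2, -0.2, -0.2),
                      c("standard", "deviant", "standard", "standard"),
                      ioi = 500)
  sq2 <- toneSequence(c(0, 500, 1000, 1500), rep(100, 4),
                      c(0.2, -0.2, 0.2, 0.2),
                      c("standard", "deviant", "standard", "standard"),
                      ioi = 500)
  # unit responds 4 to deviants, 1 to standards everywhere
  c1 <- matrix(ifelse(toneEvents(sq1)$role == "deviant", 4, 1), ncol = 1)
  t1 <- countSpikes(syntheticRecord(sq1, c1), sq1)
  t2 <- countSpikes(syntheticRecord(sq2, c1), sq2)
  si <- computeSI(t1, t2)
  pu <- siPerUnit(si)
  expect_equal(pu$d1, 4); expect_equal(pu$d2, 4)
  expect_equal(pu$s1, 1); expect_equal(pu$s2, 1)
  expect_equal(pu$si, 0.6)   # (4+4-1-1)/(4+4+1+1)
  expect_equal(si@medianSI, 0.6)
})

test_that("PSTH is flat for homogeneous Poisson spiking and conserves spike mass", {
  n <- 50L
  sq <- toneSequence((seq_len(n) - 1) * 500, rep(100, n), rep(0, n),
                     rep(c("standard", "deviant"), length.out = n), ioi = 500)
  set.seed(9)
  rate <- 40
  events <- data.frame(population = "B", unit = 1L,
                       time = sort(runif(rpois(1, rate * n * 0.5),
                                         0, n * 500)))
  rec <- new("SpikeRecord", events = events, dt = 0.1, duration = n * 500)
  ps <- psth(rec, sq, bin = 10)
  expect_lt(abs(mean(ps$all) - rate), 0.15 * rate)
  expect_lt(max(abs(ps$all - rate)), rate)   # no bin wildly off
  # difference of identical role statistics fluctuates around zero
  expect_lt(abs(mean(ps$difference)), 0.2 * rate)
  # conservation: PSTH mass x bin width = mean spike count per epoch
  tab <- countSpikes(rec, sq)
  expect_equal(sum(ps$all * diff(c(ps$t, 500))) / 1000, mean(tab$count),
               tolerance = 1e-9)
})

test_that("history-conditioned analysis pools long runs and recovers a saturating trend", {
  set.seed(4)
  n <- 4000L
  roles <- ifelse(runif(n) < 0.25, "deviant", "standard")
  sq <- toneSequence((seq_len(n) - 1) * 200, rep(50, n), rep(0.2, n), roles,
                     ioi = 200)
  # deterministic counts: deviant response follows a(1 - exp(-k / tau))
  run <- 0L; k <- integer(n)
  for (i in seq_len(n)) {
    k[i] <- run
    run <- if (roles[i] == "standard") run + 1L else 0L
  }
  a <- 6; tau <- 3
  counts <- matrix(ifelse(roles == "deviant",
                          round(a * (1 - exp(-pmin(k, 10) / tau)) * 10),
                          10), ncol = 1)
  tab <- countSpikes(syntheticRecord(sq, counts, spacing = 1), sq,
                     window = c(0, 150))
  h <- historyConditioned(tab)
  expect_false(h$noDeviants)
  expect_true(max(h$curve$k) == 10)
  expect_equal(sum(h$curve$n), sum(roles == "deviant"))
  fit <- h$fit
  expect_true(fit$converged)
  # recovery of the saturation rate within 10 %
  expect_lt(abs(fit$tau - tau) / tau, 0.1)

  # flat (history-independent) responses give a flat curve at the
  # deviant-to-grand-mean ratio
  flat <- matrix(ifelse(roles == "deviant", 20, 10), ncol = 1)
  tabF <- countSpikes(syntheticRecord(sq, flat, spacing = 1), sq,
                      window = c(0, 150))
  hF <- historyConditioned(tabF)
  ratio <- 20 / mean(flat)
  expect_true(all(abs(hF$curve$mean - ratio) < 1e-9))

  noDev <- tab[tab$role == "standard", ]
  expect_true(historyConditioned(noDev)$noDeviants)
})

test_that("exponential fits recover noiseless parameters and degrade gracefully", {
  x <- seq(0, 10, by = 0.5)
  y <- 0.3 + 2 * exp(-x / 2.5)
  fit <- fitExponential(x, y, "decay")
  expect_true(fit$converged)
  expect_equal(fit$asymptote, 0.3, tolerance = 1e-6)
  expect_equal(fit$tau, 2.5, tolerance = 1e-6)
  expect_equal(fit$predict(20), 0.3 + 2 * exp(-20 / 2.5), tolerance = 1e-6)

  ys <- 5 - 3 * exp(-x / 4)
  fitS <- fitExponential(x, ys, "saturating")
  expect_equal(fitS$asymptote, 5, tolerance = 1e-6)
  expect_equal(fitS$tau, 4, tolerance = 1e-6)

  flat <- fitExponential(x, rep(2, length(x)), "decay")
  expect_equal(flat$asymptote, 2)
  expect_equal(flat$rate, 0)

  # noisy recovery: estimates concentrate near the truth
  set.seed(8)
  taus <- replicate(50, {
    yn <- 0.3 + 2 * exp(-x / 2.5) + rnorm(length(x), 0, 0.05)
    fitExponential(x, yn, "decay")$tau
  })
  expect_lt(abs(median(taus) - 2.5), 0.3)
  expect_error(fitExponential(1:2, 1:2), "3 points")
})

test_that("population tests match their closed forms and refuse tiny samples", {
  expect_error(signedRankTest(c(0.1, 0.2)), "at least 5")
  expect_lt(signedRankTest(rep(c(0.2, 0.3), 10))$p.value, 0.01)

  expect_equal(ksCountTest(1:20, 1:20)$p.value, 1)
  expect_error(ksCountTest(1:3, 1:10), "at least 5")

  sm <- scatterMajorityTest(rep(0.2, 10), rep(0.1, 10))
  expect_equal(sm$nAbove, 10)
  # all pairs above the anti-diagonal: two-sided sign test p = 2^(1-n)
  expect_equal(sm$p.value, 2^(1 - 10))

  # type-I error of the signed-rank test near nominal under a symmetric null
  set.seed(12)
  rej <- mean(replicate(400, signedRankTest(rnorm(12))$p.value < 0.05))
  expect_gt(rej, 0.005); expect_lt(rej, 0.12)
})
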