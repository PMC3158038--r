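test_that("a never-stimulated synapse stays fully recovered", {
  p <- synapseParams("depressing", pathway = "AtoB")
  st <- synapseState()
  for (k in 1:1000) st <- synapseStep(st, p, presynSpike = FALSE)
  expect_identical(unname(st[c("R", "E", "I")]), c(1, 0, 0))
})

test_that("resource mass is conserved under arbitrary spike trains", {
  set.seed(7)
  for (cls in c("depressing", "excitatory", "inhibitory")) {
    p <- synapseParams(cls, tauRec = 200)
    for (rep in 1:5) {
      st <- synapseState()
      spikes <- runif(2000) < 0.05
      worstMass <- 0; worstBound <- 0
      for (k in seq_len(2000)) {
        st <- synapseStep(st, p, presynSpike = spikes[k], dt = 0.1)
        f <- st[c("R", "E", "I")]
        worstMass <- max(worstMass, abs(sum(f) - 1))
        worstBound <- max(worstBound, -min(f), max(f) - 1)
      }
      expect_lt(worstMass, 1e-6)
      expect_lte(worstBound, 1e-9)
    }
  }
})

test_that("single-pulse peak matches a 10x refined-step integration within 1%", {
  p <- synapseParams("depressing", pathway = "AtoB")
  coarse <- max(integrateSynapse(p, 5, dt = 0.1, tEnd = 30)[, "E"])
  fine <- max(integrateSynapse(p, 5, dt = 0.01, tEnd = 30)[, "E"])
  expect_lt(abs(coarse - fine) / fine, 0.01)
})

test_that("paired pulses depress: the second peak is smaller and matches the oracle", {
  p <- synapseParams("depressing", tauRec = 800)
  tr <- integrateSynapse(p, c(5, 55), dt = 0.1, tEnd = 110)
  peak1 <- max(tr[1:500, "E"])
  peak2 <- max(tr[501:1100, "E"])
  expect_lt(peak2, peak1)
  trF <- integrateSynapse(p, c(5, 55), dt = 0.01, tEnd = 110)
  peak2F <- max(trF[5001:11000, "E"])
  expect_lt(abs(peak2 - peak2F) / peak2F, 0.01)
})

test_that("recovery curve is monotone and its fit recovers the recovery constant", {
  p <- synapseParams("depressing", tauRec = 400)
  curve <- recoveryCurve(p, conditioningTrain = seq(0, 200, by = 50),
                         probeDelays = c(100, 200, 400, 800, 1600))
  expect_true(all(diff(curve$ratio) > 0))
  expect_true(all(curve$ratio <= 1 + 1e-6))
  tau <- fitRecoveryTau(curve)
  expect_lt(abs(tau - 400) / 400, 0.1)
  expect_error(recoveryCurve(p, 0, numeric(0)), "empty")
})

test_that("a non-depressing synapse shows no paired-pulse depression", {
  p <- synapseParams("excitatory")
  curve <- recoveryCurve(p, conditioningTrain = seq(0, 200, by = 50),
                         probeDelays = c(50, 200, 800))
  expect_true(all(abs(curve$ratio - 1) < 1e-3))
})

test_that("the depressing model converges to the non-depressing synapse as recovery becomes fast", {
  spikes <- c(3, 20, 24, 60)
  fast <- integrateSynapse(synapseParams("excitatory"), spikes,
                           dt = 0.01, tEnd = 100)
  err <- vapply(c(10, 1, 0.02), function(tr) {
    dep <- integrateSynapse(synapseParams("depressing", tauRec = tr), spikes,
                            dt = 0.01, tEnd = 100)
    max(abs(dep[, "E"] - fast[, "E"]))
  }, numeric(1))
  expect_true(all(diff(err) < 0))   # monotone convergence
  expect_lt(err[3], 5e-3)
})

test_that("synaptic current is linear in weight and vanishes at the reversal potential", {
  st <- synapseState(0.6, 0.3, 0.1, 0)
  p1 <- synapseParams("depressing", weight = 5, reversal = 0)
  expect_equal(synapticCurrent(st, p1, -60), 5 * 0.3 * 60)
  p2 <- synapseParams("depressing", weight = 10, reversal = 0)
  expect_equal(synapticCurrent(st, p2, -60), 2 * synapticCurrent(st, p1, -60))
  expect_equal(synapticCurrent(st, p1, 0), 0)
  expect_equal(synapticCurrent(synapseState(), p1, -60), 0)  # E = 0
})

test_that("log-normal jitter preserves the median and positivity, and zero sd is the identity", {
  p <- synapseParams("depressing", pathway = "AtoB")
  expect_identical(jitterParams(p, jitterSpec(0)), p)
  set.seed(3)
  w <- replicate(1e4, jitterParams(p, jitterSpec(0.1))$weight)
  expect_lt(abs(median(w) - p$weight) / p$weight, 0.02)
  tr <- replicate(200, jitterParams(p, jitterSpec(0.5))$tauRise)
  expect_true(all(tr > 0))
})
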