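test_that("make-stimulus CLI is deterministic and validates its arguments", {
  f1 <- tempfile(); f2 <- tempfile()
  argv <- c("make-stimulus", "--protocol", "markov", "--p", "0.1", "--s", "1.0",
            "--n", "100", "--seed", "7")
  expect_equal(suppressMessages(cliMain(c(argv, "--out", f1))), 0L)
  expect_equal(suppressMessages(cliMain(c(argv, "--out", f2))), 0L)
  expect_identical(readLines(f1), readLines(f2))
  sq <- readToneSequence(f1)
  expect_equal(length(sq), 100L)
  expect_equal(suppressMessages(cliMain("no-such-command")), 1L)
  expect_equal(suppressMessages(cliMain(c("make-stimulus", "--protocol",
                                          "nope", "--out", f1))), 1L)
})

test_that("run-experiment CLI writes a manifest and summary at small scale", {
  out <- file.path(tempfile(), "grid")
  code <- suppressMessages(cliMain(c("run-experiment", "--name", "grid_modes",
                                     "--scale", "0.05", "--seed", "3",
                                     "--outdir", out)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  summ <- read.table(file.path(out, "summary.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(summ), 6)
  expect_setequal(unique(summ$mode), c("block", "sequential", "random"))
  man <- readLines(file.path(out, "manifest.tsv"))
  expect_true(any(grepl("^seed\t3", man)))
})

test_that("the analyze CLI reproduces countSpikes and computeSI on stored files", {
  net <- buildNetwork(architectureSpec("AB", nB = 2L, nSub = 6L, seed = 5))
  pair <- makeOddball(0.5, 0.25, nTones = 20L, ioi = 300, duration = 50,
                      seed = 2)
  rec1 <- simulateNetwork(net, pair$first, seed = 3)
  rec2 <- simulateNetwork(net, pair$second, seed = 4)
  d <- tempfile(); dir.create(d)
  writeSpikeRecord(rec1, file.path(d, "r1.tsv"))
  writeSpikeRecord(rec2, file.path(d, "r2.tsv"))
  writeToneSequence(pair$first, file.path(d, "s1.tsv"))
  writeToneSequence(pair$second, file.path(d, "s2.tsv"))

  out <- file.path(d, "counts.tsv")
  code <- suppressMessages(cliMain(c("analyze", "--record", file.path(d, "r1.tsv"),
                                     "--sequence", file.path(d, "s1.tsv"),
                                     "--out", out)))
  expect_equal(code, 0L)
  tab <- read.table(out, sep = "\t", header = TRUE)
  direct <- countSpikes(rec1, pair$first)
  expect_equal(tab$count, direct$count)

  outSI <- file.path(d, "si.tsv")
  code <- suppressMessages(cliMain(c("analyze", "--record", file.path(d, "r1.tsv"),
                                     "--sequence", file.path(d, "s1.tsv"),
                                     "--record2", file.path(d, "r2.tsv"),
                                     "--sequence2", file.path(d, "s2.tsv"),
                                     "--out", outSI)))
  expect_equal(code, 0L)
  hdr <- readLines(outSI, n = 4)
  si <- computeSI(countSpikes(rec1, pair$first), countSpikes(rec2, pair$second))
  expect_match(hdr[3], sprintf("%.9g", si@medianSI), fixed = TRUE)
})

test_that("experiment child seeds are deterministic and distinct", {
  expect_identical(ssanet:::.childSeed(5, 3), ssanet:::.childSeed(5, 3))
  seeds <- vapply(1:50, function(i) ssanet:::.childSeed(1, i), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("calibration sweep reports the SI read-out per weight", {
  out <- runCalibration("AtoB", values = c(0, 20), nB = 4L, nSub = 12L,
                        nTones = 40L, ioi = 250, duration = 50, seed = 2)
  expect_equal(nrow(out), 2)
  expect_true(all(is.finite(out$meanDeviant)))
  # with the pathway silenced the responses are pure noise
  expect_lt(out$meanDeviant[1] + out$meanStandard[1],
            out$meanDeviant[2] + out$meanStandard[2])
})
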