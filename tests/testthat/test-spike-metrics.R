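test_that("matchSpikes handles the canonical hand-checkable cases", {
  t5 <- SpikeTrain(c(0.1, 0.2, 0.3, 0.4, 0.5))
  m <- matchSpikes(t5, t5, 0.010)
  expect_equal(m@nTp, 5L)
  expect_equal(m@nFp, 0L)
  expect_equal(m@nFn, 0L)
  expect_equal(m@pairs$offset, rep(0, 5))

  shifted <- SpikeTrain(spikeTimes(t5) + 0.004)
  m2 <- matchSpikes(shifted, t5, 0.010)
  expect_equal(m2@nTp, 5L)
  expect_equal(m2@pairs$offset, rep(0.004, 5), tolerance = 1e-12)

  ## two imputed near one truth spike: uniqueness forces one FP
  m3 <- matchSpikes(SpikeTrain(c(0.100, 0.106)), SpikeTrain(0.102), 0.010)
  expect_equal(m3@nTp, 1L)
  expect_equal(m3@nFp, 1L)
  expect_equal(m3@nFn, 0L)

  ## pairs beyond the window are never formed
  m4 <- matchSpikes(SpikeTrain(0.1), SpikeTrain(0.2), 0.010)
  expect_equal(m4@nTp, 0L)
  expect_equal(m4@nFp, 1L)
  expect_equal(m4@nFn, 1L)

  ## empty trains are valid
  m5 <- matchSpikes(SpikeTrain(), SpikeTrain(), 0.010)
  expect_equal(c(m5@nTp, m5@nFp, m5@nFn), c(0L, 0L, 0L))
})

test_that("matchSpikes equals brute-force assignment on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    a <- sort(runif(n, 0, 0.12))
    b <- sort(runif(m, 0, 0.12))
    res <- matchSpikes(SpikeTrain(a), SpikeTrain(b), 0.010)
    expect_equal(matchCost(res), bruteForceMatchCost(a, b, 0.010),
                 tolerance = 1e-12)
    ## uniqueness of pairing
    expect_true(!anyDuplicated(res@pairs$imputed))
    expect_true(!anyDuplicated(res@pairs$truth))
  }
})

test_that("classification metrics follow the counting conventions", {
  m <- new("MatchResult", pairs = data.frame(imputed = numeric(8),
                                             truth = numeric(8),
                                             offset = numeric(8)),
           nTp = 8L, nFp = 2L, nFn = 2L, maxDt = 0.01)
  cm <- classificationMetrics(m)
  expect_equal(cm$precision, 0.8)
  expect_equal(cm$recall, 0.8)
  expect_equal(cm$fScore, 0.8)
  expect_equal(cm$accuracy, 8 / 12)

  perfect <- matchSpikes(SpikeTrain(1:3 / 10), SpikeTrain(1:3 / 10))
  expect_equal(unlist(classificationMetrics(perfect)),
               c(precision = 1, recall = 1, fScore = 1, accuracy = 1))

  ## no imputed spikes: recall 0, precision undefined
  none <- matchSpikes(SpikeTrain(), SpikeTrain(c(0.1, 0.2)))
  cmn <- classificationMetrics(none)
  expect_true(is.na(cmn$precision))
  expect_equal(cmn$recall, 0)

  ## both empty: everything undefined
  cme <- classificationMetrics(matchSpikes(SpikeTrain(), SpikeTrain()))
  expect_true(all(is.na(unlist(cme))))
})

test_that("swapping imputed and truth swaps precision/recall, keeps F", {
  set.seed(7)
  for (rep in 1:10) {
    a <- sort(runif(sample(1:8, 1), 0, 0.3))
    b <- sort(runif(sample(1:8, 1), 0, 0.3))
    f <- classificationMetrics(matchSpikes(SpikeTrain(a), SpikeTrain(b)))
    r <- classificationMetrics(matchSpikes(SpikeTrain(b), SpikeTrain(a)))
    expect_equal(f$precision, r$recall)
    expect_equal(f$recall, r$precision)
    expect_equal(f$fScore, r$fScore)
  }
})

test_that("timing statistics report median bias and uncertainty", {
  t <- SpikeTrain(c(0.1, 0.2, 0.3))
  same <- timingStats(t, t)
  expect_equal(same$biasMs, 0)
  expect_equal(same$uncertaintyMs, 0)

  lag <- timingStats(SpikeTrain(spikeTimes(t) + 0.005), t)
  expect_equal(lag$biasMs, 5, tolerance = 1e-9)
  expect_equal(lag$uncertaintyMs, 5, tolerance = 1e-9)

  ## offsets {-3, +1, +4} ms -> bias +1, uncertainty 3
  imp <- SpikeTrain(c(0.097, 0.201, 0.304))
  ts <- timingStats(imp, t, mode = "nearest")
  expect_equal(ts$biasMs, 1, tolerance = 1e-9)
  expect_equal(ts$uncertaintyMs, 3, tolerance = 1e-9)
  ## positive sign means imputed later than truth
  expect_equal(sort(ts$offsets * 1000), c(-3, 1, 4), tolerance = 1e-9)
})

test_that("filtered correlation behaves as a Pearson r on smoothed signals", {
  rate <- 100
  truth <- SpikeTrain(sort(runif(30, 0, 10)))
  prob <- binSpikes(truth, 1000, rate)
  r <- filteredCorrelation(prob, truth, c(0.01, 0.05), rate)
  expect_equal(unname(r), c(1, 1), tolerance = 1e-12)

  ## positive scaling leaves r unchanged
  r2 <- filteredCorrelation(2.5 * prob, truth, c(0.01, 0.05), rate)
  expect_equal(r, r2, tolerance = 1e-12)

  ## shuffled probabilities decorrelate at large widths
  set.seed(1)
  truthLong <- sampleSpikeTrain(10, 60, seed = 5)
  counts <- binSpikes(truthLong, 6000, rate)
  shuffled <- sample(counts)
  rs <- filteredCorrelation(shuffled, truthLong, 0.05, rate)
  expect_lt(abs(rs), 0.2)

  ## constant signal gives NA
  expect_true(is.na(filteredCorrelation(rep(1, 100),
                                        SpikeTrain(c(0.1, 0.5)),
                                        0.02, rate)))
})

test_that("robust summary matches the MAD/0.6745 definition", {
  s <- robustSummary(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$robustSd, 1 / 0.6745)

  expect_equal(robustSummary(rep(4, 10))$robustSd, 0)
  expect_error(robustSummary(numeric(0)), "nonempty")

  set.seed(3)
  x <- rnorm(1e5, 0, 2.3)
  expect_equal(robustSummary(x)$robustSd, 2.3, tolerance = 0.02)
})
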