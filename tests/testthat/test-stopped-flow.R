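test_that("stopped-flow simulation honours protocol semantics", {
  s <- testSensor()
  ## equal pre/post calcium: flat trace at the steady normalized level
  p <- StoppedFlowProtocol(caPre = 0.5, caPost = 0.5, duration = 0.2,
                           rate = 2000)
  tr <- simulateStoppedFlow(s, p)
  lvl <- fluorescence(steadyState(s, 0.5), s, "stopped_flow")
  expect_lt(diff(range(tr@dff)), 1e-9)
  expect_equal(tr@dff[1], lvl, tolerance = 1e-9)
  ## first reported sample at or after the dead time
  expect_gte(tr@time[1], p@deadTime)

  ## step up approaches the post-step steady level
  p2 <- StoppedFlowProtocol(caPre = 0, caPost = 5, duration = 2, rate = 2000)
  tr2 <- simulateStoppedFlow(s, p2)
  expect_equal(tail(tr2@dff, 1),
               fluorescence(steadyState(s, 5), s, "stopped_flow"),
               tolerance = 1e-4)
  expect_true(all(tr2@dff >= -1e-9 & tr2@dff <= 1 + 1e-9))
})

test_that("multi-exponential fitting recovers known time constants", {
  rate <- 5000
  t <- seq(0, 0.5, by = 1 / rate)
  ## single rising exponential, tau = 10 ms
  tr <- FluorescenceTrace(dff = 1 - exp(-t / 0.010), rate = rate, time = t)
  f1 <- fitMultiExponential(tr, 1, "rise")
  expect_equal(f1@taus, 0.010, tolerance = 1e-4)
  expect_equal(f1@offset + sum(f1@amplitudes), 0, tolerance = 1e-6)

  ## two-component decay, taus 20 and 200 ms, recovered within 1%
  tr2 <- FluorescenceTrace(dff = 0.6 * exp(-t / 0.02) + 0.4 * exp(-t / 0.2),
                           rate = rate, time = t)
  f2 <- fitMultiExponential(tr2, 2, "decay")
  expect_equal(f2@taus, c(0.02, 0.2), tolerance = 0.01)
  expect_equal(f2@amplitudes, c(0.6, 0.4), tolerance = 0.01)
  expect_lt(f2@residualRms, 1e-8)

  ## taus are returned ascending for arbitrary inputs
  set.seed(9)
  noisy <- FluorescenceTrace(dff = rnorm(200), rate = 1000)
  f3 <- fitMultiExponential(noisy, 2)
  expect_true(!is.unsorted(f3@taus))
})

test_that("a biphasic sensor needs two exponentials for its rise", {
  s <- defaultSensor("jGCaMP8f")
  p <- StoppedFlowProtocol(caPre = 0, caPost = 10, deadTime = 1e-3,
                           duration = 1.5, rate = 5000)
  tr <- simulateStoppedFlow(s, p)
  f1 <- fitMultiExponential(tr, 1, "rise")
  f2 <- fitMultiExponential(tr, 2, "rise")
  expect_gt(f1@residualRms / f2@residualRms, 5)
})

test_that("Hill fits recover generating parameters", {
  ca <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 10)
  gen <- function(kd, h, lo, hi) lo + (hi - lo) * ca^h / (kd^h + ca^h)
  f <- fitHill(ca, gen(0.2, 2.5, 0.05, 1))
  expect_equal(f@kd, 0.2, tolerance = 1e-3)
  expect_equal(f@hill, 2.5, tolerance = 1e-3)
  expect_equal(f@fMin, 0.05, tolerance = 1e-3)
  expect_equal(f@fMax, 1, tolerance = 1e-3)
  ## hyperbola special case
  f2 <- fitHill(ca, gen(0.5, 1, 0, 1))
  expect_equal(f2@hill, 1, tolerance = 1e-3)
  ## midpoint identity on the fitted curve
  expect_equal(predictHillFit(f, f@kd), (f@fMin + f@fMax) / 2,
               tolerance = 1e-9)
  expect_error(fitHill(ca, rep(1, length(ca))), "flat")
  expect_error(fitHill(c(0.1, 0.2, 0.1), c(1, 2, 1)), "4 distinct")
})

test_that("global sensor fitting recovers a known model", {
  s <- testSensor()
  protos <- list(StoppedFlowProtocol(0, 0.5, duration = 0.4, rate = 1000),
                 StoppedFlowProtocol(0, 5, duration = 0.4, rate = 1000),
                 StoppedFlowProtocol(10, 0, duration = 0.4, rate = 1000))
  traces <- lapply(protos, function(p)
    list(protocol = p, trace = simulateStoppedFlow(s, p)))
  fit <- globalFitSensor(traces, nStarts = 4, seed = 3, maxit = 250,
                         extraStarts = list(s))
  ## with the truth in the start set, descent keeps loss at numerical zero
  expect_lt(fit$loss, 1e-6)
  for (tr in traces) {
    sim <- simulateStoppedFlow(fit$sensor, tr$protocol)
    expect_lt(max(abs(sim@dff - tr$trace@dff)), 1e-3)
  }
  ## determinism
  fit2 <- globalFitSensor(traces, nStarts = 4, seed = 3, maxit = 250,
                          extraStarts = list(s))
  expect_identical(fit$loss, fit2$loss)
  expect_equal(biospike:::.packSensor(fit$sensor),
               biospike:::.packSensor(fit2$sensor))
})

test_that("half-rise times shorten with step size (shipped sensors)", {
  for (nm in c("jGCaMP8f", "GCaMP6f")) {
    s <- defaultSensor(nm)
    hr <- vapply(c(0.5, 2, 10), function(ca) {
      p <- StoppedFlowProtocol(0, ca, deadTime = 0, duration = 3,
                               rate = 2000)
      halfRiseTime(simulateStoppedFlow(s, p))
    }, numeric(1))
    expect_true(all(diff(hr) < 0))
  }
})

test_that("cell-parameter fitting recovers influx and concentration", {
  s <- testSensor()
  truth <- testCell(aCa = 14, gTotal = 15)
  spikes <- SpikeTrain(c(0.2, 0.9, 1.5))
  rec <- simulateCell(truth, s, spikes, 2, 200)
  fits <- fitCellParams(list(list(trace = rec, spikes = spikes)), s,
                        cell0 = testCell(), whichPars = c("aCa", "gTotal"),
                        seed = 2, nStarts = 3)
  f <- fits[[1]]
  expect_equal(f$cell@aCa, 14, tolerance = 0.1)
  expect_equal(f$cell@gTotal, 15, tolerance = 0.1)
  ## best-so-far loss trajectory is non-increasing
  expect_true(all(diff(f$trajectory) <= 0))

  ## flat zero-spike trace: baseline-consistent parameters, near-zero loss
  flat <- simulateCell(testCell(), s, SpikeTrain(), 1, 200)
  f0 <- fitCellParams(list(list(trace = flat, spikes = SpikeTrain())), s,
                      cell0 = testCell(), whichPars = "aCa", seed = 1,
                      nStarts = 1)[[1]]
  expect_lt(f0$loss, 1e-10)
})

test_that("the accessible-slowing surrogate ranks sensors sensibly", {
  ## a sensor with a stickier slow pathway scores higher
  sticky <- testSensor()
  sticky@lobeC@koffPep <- 0.4
  expect_gt(accessibleSlowing(sticky), accessibleSlowing(testSensor()))
})
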