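# Shared small-scale SMC fixtures: a fast test sensor at 250 Hz keeps the
# conditional sweeps cheap while exercising the full code path.

smcTheta <- function(cell, sensor, sigma = 0.02, rateHz = 2) {
  list(aCa = cell@aCa, gTotal = cell@gTotal, pumpVmax = cell@pumpVmax,
       Rf = sensor@Rf, sigma = sigma, rateHz = rateHz, driftScale = 0.005)
}

test_that("the observation log-likelihood is a Gaussian log-density", {
  expect_equal(obsLogLik(0.3, 0.3, 0.1), -0.5 * log(2 * pi * 0.01))
  expect_equal(obsLogLik(0.3 + 0.05, 0.3, 0.1),
               obsLogLik(0.3 - 0.05, 0.3, 0.1))
  set.seed(1)
  y <- rnorm(100); pred <- rnorm(100)
  oracle <- -50 * log(2 * pi * 0.04) - sum((y - pred)^2) / (2 * 0.04)
  expect_equal(obsLogLik(y, pred, 0.2), oracle)
  expect_error(obsLogLik(1, 1, 0), "> 0")
})

test_that("the fast binned dynamics track the reference integrator", {
  s <- testSensor()
  cell <- testCell()
  rate <- 500
  spikes <- SpikeTrain(c(0.3, 0.8, 0.82, 1.4))
  ref <- suppressWarnings(simulateCell(cell, s, spikes, 2, rate))
  ctx <- biospike:::.smcContext(s, cell, 1 / rate)
  bins <- binSpikes(spikes, 2 * rate, rate)
  fast <- biospike:::.predictBins(bins, smcTheta(cell, s), ctx)
  err <- abs(fast - ref@dff[-1])
  expect_lt(max(err), 1e-2)
  ## away from spike bins the agreement is much tighter
  spikeBins <- floor(spikeTimes(spikes) * rate) + 1
  near <- unique(pmin(pmax(rep(spikeBins, each = 3) + (-1:1), 1),
                      length(err)))
  expect_lt(max(err[-near]), 1.5e-3)
})

test_that("conditional SMC finds a single spike in the low-noise limit", {
  s <- testSensor()
  cell <- testCell()
  rate <- 250
  spikes <- SpikeTrain(0.5)
  trace <- simulateCell(cell, s, spikes, 2, rate)
  cfg <- inferenceConfig(nParticles = 64, seed = 1)
  ctx <- biospike:::.smcContext(s, cell, 1 / rate)
  theta <- smcTheta(cell, s, sigma = 1e-4)
  trueBin <- floor(0.5 * rate) + 1
  set.seed(42)
  ## run a proper particle-Gibbs chain: the sampled trajectory becomes the
  ## next sweep's reference; after a short burn-in the chain should sit on
  ## the true spike bin essentially always
  traj <- list(spikes = integer(length(trace@dff)),
               baseline = numeric(length(trace@dff)))
  hits <- 0
  for (k in 1:30) {
    traj <- conditionalSMC(trace, theta, traj, cfg, ctx)
    if (k <= 5) next
    found <- which(traj$spikes == 1)
    if (length(found) == 1 && found == trueBin) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
})

test_that("a flat trace with a tight rate prior yields empty trajectories", {
  s <- testSensor()
  cell <- testCell()
  rate <- 250
  trace <- FluorescenceTrace(dff = numeric(250), rate = rate)
  cfg <- inferenceConfig(nParticles = 48, seed = 2)
  ctx <- biospike:::.smcContext(s, cell, 1 / rate)
  theta <- smcTheta(cell, s, sigma = 0.01, rateHz = 0.02)
  ref <- list(spikes = integer(250), baseline = numeric(250))
  set.seed(7)
  allZero <- vapply(1:20, function(k)
    sum(conditionalSMC(trace, theta, ref, cfg, ctx)$spikes) == 0, logical(1))
  expect_gte(mean(allZero), 0.95)
})

test_that("parameter updates satisfy their degenerate limits", {
  s <- testSensor()
  cell <- testCell()
  rate <- 250
  trace <- FluorescenceTrace(dff = rnorm(50, 0, 0.02), rate = rate)
  ctx <- biospike:::.smcContext(s, cell, 1 / rate)
  traj <- list(spikes = integer(50), baseline = numeric(50))
  theta <- smcTheta(cell, s)
  ## zero proposal scale: theta unchanged
  cfg0 <- inferenceConfig(seed = 1,
                          priors = biospike:::.defaultPriors(cell, s),
                          proposalScales = list(aCa = 0))
  up <- updateParameters(trace, traj, theta, cfg0, ctx, update = "aCa")
  expect_identical(up$theta, theta)
  expect_true(is.finite(up$logPost))
})

test_that("under a flat likelihood the sampler recovers the prior", {
  s <- testSensor()
  cell <- testCell()
  rate <- 250
  trace <- FluorescenceTrace(dff = numeric(10), rate = rate)
  ctx <- biospike:::.smcContext(s, cell, 1 / rate)
  traj <- list(spikes = integer(10), baseline = numeric(10))
  prior <- list(meanlog = log(10), sdlog = 0.4)
  cfg <- inferenceConfig(seed = 1,
                         priors = utils::modifyList(
                           biospike:::.defaultPriors(cell, s),
                           list(aCa = prior)),
                         proposalScales = list(aCa = 0.6))
  theta <- smcTheta(cell, s, sigma = 1e6)  # likelihood flat in aCa
  set.seed(31)
  draws <- numeric(3000)
  for (k in seq_along(draws)) {
    up <- updateParameters(trace, traj, theta, cfg, ctx, update = "aCa")
    theta <- up$theta
    draws[k] <- theta$aCa
  }
  thin <- draws[seq(500, 3000, by = 5)]
  ## rejected proposals leave duplicate values; the tie warning is expected
  ks <- suppressWarnings(
    ks.test(log(thin), "pnorm", prior$meanlog, prior$sdlog))
  expect_gt(ks$p.value, 0.01)
})

test_that("pgasInfer is seed-deterministic and numerically sane", {
  s <- testSensor()
  cell <- testCell()
  pre <- tracePreset("excitatory", rate = 4, duration = 4, sampleRate = 250,
                     sigma = 0.02, driftAmp = 0.005)
  gen <- generateTrace(pre, s, cell, seed = 5)
  cfg <- inferenceConfig(nParticles = 32, nIterations = 8, seed = 99)
  p1 <- pgasInfer(gen$trace, s, cfg, cell)
  p2 <- pgasInfer(gen$trace, s, cfg, cell)
  expect_identical(p1@spikeProb, p2@spikeProb)
  expect_identical(p1@paramSamples, p2@paramSamples)
  expect_identical(spikeTimes(p1@mapSpikes), spikeTimes(p2@mapSpikes))
  expect_true(all(is.finite(p1@logPost)))
  expect_true(all(p1@spikeProb >= 0 & p1@spikeProb <= 1))
  expect_true(!is.unsorted(spikeTimes(p1@mapSpikes), strictly = TRUE))
})

test_that("MAP extraction thresholds and merges adjacent bins", {
  expect_length(spikeTimes(mapSpikes(numeric(100), rate = 100)), 0)
  p <- numeric(100); p[40] <- 0.9
  expect_equal(spikeTimes(mapSpikes(p, rate = 100)), 39.5 / 100)
  ## adjacent bins 0.6 and 0.8 merge at the probability-weighted centroid
  p2 <- numeric(100); p2[40] <- 0.6; p2[41] <- 0.8
  expected <- (39.5 * 0.6 + 40.5 * 0.8) / (1.4 * 100)
  expect_equal(spikeTimes(mapSpikes(p2, rate = 100)), expected)
})

test_that("the AR(2) plug-in matches its closed form and infers its own
           simulations", {
  h <- arImpulseResponse(2, 1.2, -0.32, 12)
  phi <- numeric(12); phi[1] <- 1; phi[2] <- 1.2
  for (t in 3:12) phi[t] <- 1.2 * phi[t - 1] - 0.32 * phi[t - 2]
  expect_equal(h, 2 * phi)

  ## self-consistency: a single-spike AR trace is recovered
  rate <- 250
  n <- 500
  spikes <- integer(n); spikes[125] <- 1L
  kernel <- fitArKernel(testSensor(), testCell(), rate)
  clean <- as.numeric(biospike:::.cppSimBinsAr(spikes, kernel$A,
                                               kernel$a1, kernel$a2))
  set.seed(3)
  trace <- FluorescenceTrace(dff = clean + rnorm(n, 0, 0.002), rate = rate)
  cfg <- inferenceConfig(nParticles = 48, nIterations = 10, seed = 17,
                         generativeModel = "linear_ar")
  post <- pgasInfer(trace, testSensor(), cfg, testCell())
  m <- matchSpikes(post@mapSpikes, SpikeTrain(124 / rate), maxDt = 0.012)
  expect_equal(m@nTp, 1L)
  expect_lte(m@nFp, 1L)
})
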