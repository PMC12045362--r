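test_that("spike influx splits between free calcium and buffer", {
  s <- testSensor()
  st <- restingState(testCell(), s)
  up <- applySpike(st, 41, 40)
  expect_equal(up@caFree - st@caFree, 1)
  expect_equal(up@bCa - st@bCa, 40)
  expect_equal(up@caSlow, st@caSlow)
  expect_equal(up@caStore, st@caStore)

  up0 <- applySpike(st, 5, 0)
  expect_equal(up0@caFree - st@caFree, 5)
  expect_equal(up0@bCa, st@bCa)

  set.seed(2)
  for (kB in runif(5, 0, 100)) {
    u <- applySpike(st, 7, kB)
    expect_equal((u@caFree - st@caFree) + (u@bCa - st@bCa), 7,
                 tolerance = 1e-12)
  }
})

test_that("the resting state is an exact fixed point", {
  s <- testSensor()
  cellVariants <- list(
    testCell(),
    testCell(storeInVmax = 5, storeInKm = 0.3, storeOutVmax = 5,
             storeOutKm = 50, storeCaBasal = 50),
    testCell(slowFrac = 0.3, slowK = 10))
  for (cell in cellVariants) {
    d <- calciumDerivatives(restingState(cell, s), cell, s)
    expect_lt(max(abs(d)), 1e-9)
  }
  ## extrusion saturates: at ca >> Km with the sensor equilibrated and the
  ## slow pool matched, the free-calcium derivative approaches the
  ## Vmax-limited value (leak - Vmax) / (1 + kappaB)
  cell <- testCell()
  for (ca in c(1e4, 1e6)) {
    hi <- CellState(caFree = ca, caSlow = ca, bCa = cell@kappaB * ca,
                    caStore = cell@storeCaBasal,
                    sensor = steadyState(s, ca))
    d <- calciumDerivatives(hi, cell, s)
    expect_equal(d[["caFree"]],
                 (biospike:::.leakRate(cell) - cell@pumpVmax) /
                   (1 + cell@kappaB),
                 tolerance = 1e-3)
  }
})

test_that("total calcium is conserved when transport is disabled", {
  s <- testSensor()
  cell <- testCell(pumpVmax = 0, slowFrac = 0.2, slowK = 5)
  ## leak is zero when the pump and store are off
  expect_equal(biospike:::.leakRate(cell), 0)
  out <- suppressWarnings(
    simulateCell(cell, s, SpikeTrain(0.1), 1, 1000, returnLatents = TRUE))
  st <- out$states  # rows: ca, caSlow, caStore, bCa, x1..x9
  vr <- cell@slowFrac / (1 - cell@slowFrac)
  boundPerSensor <- 2 - colSums(st[5:7, ]) - st[5, ] - st[8, ] - st[11, ]
  total <- st[1, ] + st[4, ] + vr * st[2, ] + st[3, ] +
    cell@gTotal * s@nCaPerLobe * boundPerSensor
  after <- out$time > 0.1  # strictly post-influx
  expect_lt(diff(range(total[after])), 1e-7 * max(total))
})

test_that("no spikes and no noise give an identically flat trace", {
  s <- testSensor()
  tr <- simulateCell(testCell(), s, SpikeTrain(), 0.5, 500)
  expect_lt(max(abs(tr@dff)), 1e-9)
  expect_error(simulateCell(testCell(), s, SpikeTrain(2), 1, 500),
               "within")
})

test_that("noise is reproducible given a seed", {
  s <- testSensor()
  cell <- testCell(sigma = 0.05)
  t1 <- suppressWarnings(simulateCell(cell, s, SpikeTrain(0.1), 0.4, 500,
                                      noiseSeed = 42))
  t2 <- suppressWarnings(simulateCell(cell, s, SpikeTrain(0.1), 0.4, 500,
                                      noiseSeed = 42))
  expect_identical(t1@dff, t2@dff)
})

test_that("summary statistics match closed forms", {
  rate <- 1000
  t <- seq(0, 1, by = 1 / rate)
  ## pure exponential decay from peak: half-decay = tau ln 2
  tau <- 0.08
  tr <- FluorescenceTrace(dff = exp(-t / tau), rate = rate, time = t)
  st <- summaryStats(tr)
  expect_equal(st$halfDecay, tau * log(2), tolerance = 1e-3)
  expect_equal(st$peak, 1)

  ## linear ramp 0 -> 1 over 10 ms: 10-90% rise = 8 ms
  ramp <- pmin(t / 0.010, 1)
  st2 <- summaryStats(FluorescenceTrace(dff = ramp, rate = rate, time = t))
  expect_equal(st2$riseTime, 0.008, tolerance = 1e-6)

  ## biexponential decay: half-decay equals the numeric root
  f <- function(tt) 0.6 * exp(-tt / 0.02) + 0.4 * exp(-tt / 0.2)
  tr3 <- FluorescenceTrace(dff = f(t), rate = rate, time = t)
  st3 <- summaryStats(tr3)
  oracle <- uniroot(function(tt) f(tt) - 0.5, c(0, 1), tol = 1e-10)$root
  expect_equal(st3$halfDecay, oracle, tolerance = 1e-3)

  ## events at the trace edge yield NA, not extrapolation
  rising <- FluorescenceTrace(dff = t, rate = rate, time = t)
  expect_true(is.na(summaryStats(rising)$halfDecay))
})

test_that("responses sum linearly for weak, well-separated spikes", {
  s <- testSensor()
  cell <- testCell(aCa = 0.05)  # far-subsaturating influx
  rate <- 500
  single <- simulateCell(cell, s, SpikeTrain(0.05), 1.2, rate)
  pair <- simulateCell(cell, s, SpikeTrain(c(0.05, 0.55)), 1.2, rate)
  ## superposition: the pair response equals the sum of two shifted
  ## single responses to within 2% of the single-spike peak
  shiftBins <- 0.5 * rate
  shifted <- c(numeric(shiftBins), single@dff[1:(length(single@dff) - shiftBins)])
  super <- single@dff + shifted
  expect_lt(max(abs(pair@dff - super)), 0.02 * max(single@dff))
})
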