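test_that("the on-rate law reproduces its defining identities", {
  l <- LobeKinetics(koffCa = 100, Ka = 0.2, hill = 1, konPep = 1,
                    koffPep = 1)
  expect_equal(lobeOnRate(l, 0.2), 100)   # ca = Ka forces kon = koff
  expect_equal(lobeOnRate(l, 0), 0)
  l2 <- LobeKinetics(koffCa = 50, Ka = 1, hill = 2, konPep = 1, koffPep = 1)
  expect_equal(lobeOnRate(l2, 2), 200)    # 50 * 2^2
  ## strictly increasing in calcium
  ca <- seq(0, 5, by = 0.25)
  expect_true(all(diff(lobeOnRate(l2, ca)) > 0))
  expect_error(lobeOnRate(l, -1), "nonnegative")
})

test_that("the joint generator conserves probability and only allows
           single-lobe single-step transitions", {
  set.seed(11)
  nIdx <- rep(1:3, each = 3); cIdx <- rep(1:3, times = 3)
  for (rep in 1:5) {
    s <- randomSensor()
    for (ca in c(0, 0.1, 1, 50)) {
      Q <- buildGenerator(s, ca)
      expect_lt(max(abs(colSums(Q))) / max(abs(Q), 1), 1e-12)
      off <- Q - diag(diag(Q))
      expect_true(all(off >= 0))
      ## allowed: exactly one lobe moves by one step
      for (from in 1:9) for (to in 1:9) {
        if (from == to) next
        dN <- abs(nIdx[to] - nIdx[from]); dC <- abs(cIdx[to] - cIdx[from])
        allowed <- (dN + dC == 1)
        if (!allowed) expect_equal(Q[to, from], 0)
      }
    }
  }
})

test_that("zero calcium drains the sensor to the doubly-apo state", {
  s <- testSensor()
  ss <- steadyState(s, 0)
  expect_equal(unname(occupancy(ss)[1]), 1)
  ## dynamics also converge there from a loaded state
  loaded <- SensorState(rep(1 / 9, 9))
  tr <- propagateSensor(s, loaded, rep(0, 6000), 2e-3)
  expect_equal(unname(tr[1, ncol(tr)]), 1, tolerance = 1e-5)
})

test_that("steady state agrees with long-time integration and is
           monotone in calcium", {
  set.seed(21)
  for (rep in 1:5) {
    s <- randomSensor()
    ss <- occupancy(steadyState(s, 1))
    ## long-time integration oracle from a different start
    tr <- propagateSensor(s, SensorState(c(1, rep(0, 8))), rep(1, 6000),
                          5e-3)
    expect_equal(unname(tr[, ncol(tr)]), unname(ss), tolerance = 1e-8)
  }
  ## fluorescent-class occupancy non-decreasing over a 0-10 uM sweep
  s <- testSensor()
  grid <- c(0, 10^seq(-2, 1, length.out = 25))
  phi <- vapply(grid, function(ca)
    sum(occupancy(steadyState(s, ca))[c(3, 6, 7, 8, 9)]), numeric(1))
  expect_true(all(diff(phi) >= -1e-12))
})

test_that("propagation matches a dense matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(33)
  for (rep in 1:8) {
    s <- randomSensor()
    ca <- exp(runif(1, log(0.05), log(5)))
    x0 <- occupancy(steadyState(s, 0.02))
    tr <- propagateSensor(s, SensorState(x0), rep(ca, 40), 2e-3)
    Q <- buildGenerator(s, ca)
    for (k in c(10, 40)) {
      oracle <- as.numeric(Matrix::expm(Q * k * 2e-3) %*% x0)
      expect_equal(unname(tr[, k + 1]), oracle, tolerance = 1e-7)
    }
  }
})

test_that("duplicated lobes give marginals equal to the 3-state chain", {
  skip_if_not_installed("Matrix")
  lob <- LobeKinetics(koffCa = 80, Ka = 0.4, hill = 1.3, konPep = 150,
                      koffPep = 12)
  s <- SensorModel(lobeN = lob, lobeC = lob, Rf = 5, name = "dup")
  x0 <- c(1, rep(0, 8))
  tr <- propagateSensor(s, SensorState(x0), rep(0.6, 50), 1e-3)
  G3 <- rbind(c(-lobeOnRate(lob, 0.6), 80, 0),
              c(lobeOnRate(lob, 0.6), -(80 + 150), 12),
              c(0, 150, -12))
  for (k in c(5, 25, 50)) {
    marginalN <- c(sum(tr[1:3, k + 1]), sum(tr[4:6, k + 1]),
                   sum(tr[7:9, k + 1]))
    oracle <- as.numeric(Matrix::expm(G3 * k * 1e-3) %*% c(1, 0, 0))
    expect_equal(marginalN, oracle, tolerance = 1e-8)
  }
})

test_that("occupancy stays a probability vector along long trajectories", {
  s <- testSensor()
  x0 <- steadyState(s, 0.05)
  ## constant calcium, 1e5 steps
  tr <- propagateSensor(s, x0, rep(0.8, 1e5), 1e-4)
  sums <- colSums(tr)
  expect_lt(max(abs(sums - 1)), 1e-8)
  expect_true(all(tr > -1e-12))
  ## time-varying calcium
  set.seed(5)
  caTraj <- exp(sin(seq(0, 20, length.out = 2000))) * 0.5
  tr2 <- propagateSensor(s, x0, caTraj, 1e-3)
  expect_lt(max(abs(colSums(tr2) - 1)), 1e-8)
})

test_that("a single-lobe sensor without peptide steps reduces to 2-state
           analytic kinetics", {
  eps <- 1e-9
  lobN <- LobeKinetics(koffCa = 50, Ka = 0.5, hill = 1, konPep = eps,
                       koffPep = 1)
  lobC <- LobeKinetics(koffCa = eps, Ka = 1e6, hill = 1, konPep = eps,
                       koffPep = 1)
  s <- SensorModel(lobeN = lobN, lobeC = lobC, Rf = 5, name = "2state")
  ca <- 0.5  # kon = koff = 50
  kon <- lobeOnRate(lobN, ca)
  tr <- propagateSensor(s, SensorState(c(1, rep(0, 8))), rep(ca, 200),
                        5e-4)
  t <- (0:200) * 5e-4
  bound <- colSums(tr[4:6, , drop = FALSE])
  analytic <- kon / (kon + 50) * (1 - exp(-(kon + 50) * t))
  expect_equal(unname(bound), analytic, tolerance = 1e-6)
})

test_that("fluorescence scaling and dF/F arithmetic are exact", {
  s <- testSensor(Rf = 5)
  s0 <- steadyState(s, 0)
  expect_equal(fluorescence(s0, s, "cell"), 1)
  sat <- steadyState(s, 1e6)
  expect_equal(fluorescence(sat, s, "cell"), 5, tolerance = 1e-9)
  expect_equal(fluorescence(s0, s, "stopped_flow"), 0)
  expect_equal(fluorescence(sat, s, "stopped_flow"), 1, tolerance = 1e-12)
  ## state midway in fluorescent occupancy -> midway F
  mid <- SensorState((occupancy(s0) + occupancy(sat)) / 2)
  expect_equal(fluorescence(mid, s, "cell"), 3, tolerance = 1e-9)

  expect_equal(dffValue(2, 1), 1)
  expect_equal(dffValue(pi, pi), 0)
  expect_error(dffValue(1, 0), "> 0")
})

test_that("state classes partition the occupancy everywhere", {
  apoapo <- SensorState(c(1, rep(0, 8)))
  expect_equal(unname(classifyStates(apoapo)), c(0, 0, 0, 1))
  ## all mass on (N = Ca+pep, C = apo): fast fluorescent
  fast <- SensorState(c(rep(0, 6), 1, 0, 0))
  expect_equal(unname(classifyStates(fast)), c(1, 0, 0, 0))
  ## classes sum to one along a driven trajectory
  s <- testSensor()
  caTraj <- rep(c(0.05, 2), each = 500)
  tr <- propagateSensor(s, steadyState(s, 0.05), caTraj, 1e-3)
  cls <- classifyStates(tr)
  expect_equal(dim(cls), c(4L, ncol(tr)))
  expect_lt(max(abs(colSums(cls) - 1)), 1e-9)
})
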