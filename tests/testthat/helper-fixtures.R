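# Small, fast synthetic fixtures used across the suite. These are NOT the
# calibrated variant parameter sets (loaded with defaultSensor()); they are
# round-number sensors whose kinetics keep test integrations cheap.

testSensor <- function(Rf = 5) {
  SensorModel(
    lobeN = LobeKinetics(koffCa = 200, Ka = 0.3, hill = 1.2,
                         konPep = 400, koffPep = 40),
    lobeC = LobeKinetics(koffCa = 10, Ka = 1.0, hill = 1.0,
                         konPep = 20, koffPep = 4),
    Rf = Rf, name = "test-sensor")
}

testCell <- function(...) {
  args <- utils::modifyList(
    list(gTotal = 10, aCa = 10, kappaB = 40, pumpVmax = 800,
         pumpKm = 0.5, storeInVmax = 0, storeOutVmax = 0,
         slowFrac = 0.1, slowK = 2, caBasal = 0.05),
    list(...))
  do.call(CellParams, args)
}

# A random sensor with rates spread over orders of magnitude (seeded by
# the caller through withr-style set.seed).
randomSensor <- function() {
  r <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  SensorModel(
    lobeN = LobeKinetics(r(50, 2000), r(0.05, 1), runif(1, 0.6, 2.5),
                         r(50, 2000), r(5, 200)),
    lobeC = LobeKinetics(r(1, 50), r(0.2, 5), runif(1, 0.6, 2.5),
                         r(1, 50), r(0.5, 20)),
    Rf = r(2, 50), name = "random")
}

# Brute-force optimal assignment for spike matching on tiny instances:
# enumerate all one-to-one assignments respecting the window and return the
# minimum of matched |offset| + (maxDt/2) * number of unmatched spikes.
bruteForceMatchCost <- function(a, b, maxDt) {
  u <- maxDt / 2
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, usedB, cost) {
    if (cost >= best) return()
    if (i > n) {
      tot <- cost + u * sum(!usedB)
      if (tot < best) best <<- tot
      return()
    }
    recurse(i + 1, usedB, cost + u)  # leave imputed i unmatched
    for (j in seq_len(m)) {
      if (!usedB[j] && abs(a[i] - b[j]) <= maxDt) {
        usedB2 <- usedB; usedB2[j] <- TRUE
        recurse(i + 1, usedB2, cost + abs(a[i] - b[j]))
      }
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

matchCost <- function(match) {
  sum(abs(match@pairs$offset)) + (match@maxDt / 2) * (match@nFp + match@nFn)
}
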