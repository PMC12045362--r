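#' @include AllClasses.R cell-model.R stopped-flow.R
NULL

#' Slice-transient statistic bundle for a sensor/cell pair
#'
#' Computes, from noise-free simulations at 1 kHz, the statistics used to
#' characterize indicator transients in single boutons: single-spike 10-90%
#' rise time, half-decay time and peak dF/F; the 10-spike (100 Hz)
#' half-decay and 10:1 peak-amplitude ratio; and the paired-pulse ratio at
#' 10 ms inter-spike interval.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param cell a \linkS4class{CellParams}
#' @param rate sampling rate (Hz), default 1000
#' @param onset time of the first spike (s)
#' @param what which statistics to compute ("all" or a subset of the output
#'   names); unneeded simulations are skipped
#' @return list with riseTime, halfDecay1, halfDecay10, peak1, ratio10to1,
#'   ppr10ms (times in seconds)
#' @export
sliceStats <- function(sensor, cell, rate = 1000, onset = 0.05,
                       what = "all") {
  all <- c("riseTime", "halfDecay1", "halfDecay10", "peak1", "ratio10to1",
           "ppr10ms")
  if (identical(what, "all")) what <- all
  cell@sigma <- 0
  s1 <- simulateCell(cell, sensor, SpikeTrain(onset), onset + 0.45, rate)
  st1 <- summaryStats(s1, SpikeTrain(onset))
  out <- list(riseTime = st1$riseTime, halfDecay1 = st1$halfDecay,
              peak1 = st1$peak)
  if (any(c("halfDecay10", "ratio10to1") %in% what)) {
    train <- SpikeTrain(onset + (0:9) / 100)
    s10 <- simulateCell(cell, sensor, train, onset + 0.75, rate)
    st10 <- summaryStats(s10, train)
    out$halfDecay10 <- st10$halfDecay
    out$ratio10to1 <- st10$peak / st1$peak
  }
  if ("ppr10ms" %in% what) {
    pair <- SpikeTrain(c(onset, onset + 0.010))
    s2 <- simulateCell(cell, sensor, pair, onset + 0.30, rate)
    out$ppr10ms <- pairedPulseRatio(s2, s1)
  }
  out[intersect(all, union(names(out)[!vapply(out, is.null, TRUE)], what))]
}

## Loss: sum of squared log-ratios over the supplied targets.
.sliceLoss <- function(stats, targets, weights = NULL) {
  tot <- 0
  for (nm in names(targets)) {
    v <- stats[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0) return(1e6)
    w <- if (!is.null(weights) && !is.null(weights[[nm]])) weights[[nm]] else 1
    tot <- tot + w * log(v / targets[[nm]])^2
  }
  tot
}

## Cheap biphasicness index of the saturating stopped-flow rise: RMS of a
## 1-exponential fit over RMS of a 2-exponential fit (grid-only, no polish).
.biphasicRatio <- function(sensor) {
  p <- StoppedFlowProtocol(0, 10, deadTime = 1e-3, duration = 1.5,
                           rate = 2000)
  tr <- simulateStoppedFlow(sensor, p)
  t <- tr@time - tr@time[1]
  grid <- exp(seq(log(5e-4), log(3), length.out = 10))
  best <- function(k) {
    combos <- utils::combn(length(grid), k)
    rss <- Inf
    for (j in seq_len(ncol(combos))) {
      cand <- .ampsForTaus(t, tr@dff, grid[combos[, j]])
      if (!is.null(cand) && cand$rss < rss) rss <- cand$rss
    }
    sqrt(rss / length(t))
  }
  best(1) / best(2)
}

#' Calibrate sensor kinetics against slice-transient statistics
#'
#' Fits the ten lobe kinetic parameters and the dynamic range Rf so that
#' the simulated bouton transients reproduce a set of target statistics
#' (squared-log-ratio loss), with the cell model held fixed. This is the
#' fit that produces the shipped per-variant parameter sets: a single
#' parameter set per variant must reproduce all of that variant's transient
#' statistics simultaneously.
#'
#' @param targets named list of target values; any subset of the names
#'   returned by \code{\link{sliceStats}}
#' @param cell fixed \linkS4class{CellParams}
#' @param start starting \linkS4class{SensorModel}
#' @param maxit Nelder-Mead iteration cap
#' @param weights optional named list of per-target loss weights
#' @param rate simulation sampling rate (Hz)
#' @param constrain add soft penalties keeping the fit in the physical
#'   regime: the N-lobe binds calcium faster than the C-lobe at matched
#'   (0.5 uM) calcium, Hill exponents stay above 0.1, and the dynamic
#'   range stays below ~100
#' @param biphasicWeight weight of the stopped-flow biphasicness
#'   constraint (the saturating calcium-step rise must need two
#'   exponential components); 0 disables it
#' @return list with \code{sensor} (fitted, provenance in \code{meta}),
#'   \code{loss}, and \code{stats} (achieved statistics)
#' @export
calibrateSensor <- function(targets, cell, start, maxit = 600,
                            weights = NULL, rate = 1000, constrain = TRUE,
                            biphasicWeight = 0) {
  par0 <- c(.packSensor(start), log(start@Rf - 1))
  penalty <- function(s) {
    if (!constrain) return(0)
    konN <- lobeOnRate(s@lobeN, 0.5)
    konC <- lobeOnRate(s@lobeC, 0.5)
    pen <- 10 * max(0, log(konC / konN))^2 +
      max(0, log(s@Rf / 100))^2 +
      10 * max(0, log(0.1 / s@lobeN@hill))^2 +
      10 * max(0, log(0.1 / s@lobeC@hill))^2
    if (biphasicWeight > 0) {
      br <- tryCatch(.biphasicRatio(s), error = function(e) 1)
      pen <- pen + biphasicWeight * max(0, log(8 / br))^2
    }
    pen
  }
  obj <- function(p) {
    s <- tryCatch(.unpackSensor(p[1:10], Rf = 1 + exp(p[11]),
                                name = start@name),
                  error = function(e) NULL)
    if (is.null(s)) return(1e6)
    st <- tryCatch(sliceStats(s, cell, rate = rate, what = names(targets)),
                   error = function(e) NULL)
    if (is.null(st)) return(1e6)
    .sliceLoss(st, targets, weights) + penalty(s)
  }
  fit <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  sensor <- .unpackSensor(fit$par[1:10], Rf = 1 + exp(fit$par[11]),
                          name = start@name,
                          meta = list(loss = fit$value,
                                      calibration = "slice-statistics",
                                      targets = targets))
  list(sensor = sensor, loss = fit$value,
       stats = sliceStats(sensor, cell, rate = rate))
}
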