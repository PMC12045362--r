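#' @include AllClasses.R sensor-kinetics.R
NULL

.volRatio <- function(cell) {
  if (cell@slowFrac <= 0) 0 else cell@slowFrac / (1 - cell@slowFrac)
}

.mm <- function(vmax, km, ca) vmax * ca / (km + ca)

## Resting store level. When the store exchanges calcium both ways, the
## level that balances influx and efflux at basal calcium is used, so the
## whole system is at rest; otherwise the configured storeCaBasal stands.
.storeRest <- function(cell) {
  jIn <- .mm(cell@storeInVmax, cell@storeInKm, cell@caBasal)
  if (jIn > 0 && cell@storeOutVmax > jIn)
    jIn * cell@storeOutKm / (cell@storeOutVmax - jIn)
  else cell@storeCaBasal
}

## Constant leak influx making caBasal an exact fixed point of the main
## pool at the resting store level (the slow pool equilibrates by itself).
.leakRate <- function(cell) {
  .mm(cell@pumpVmax, cell@pumpKm, cell@caBasal) +
    .mm(cell@storeInVmax, cell@storeInKm, cell@caBasal) -
    .mm(cell@storeOutVmax, cell@storeOutKm, .storeRest(cell))
}

#' Resting state of the bouton model
#'
#' Free calcium at \code{caBasal}, slow pool equilibrated, buffer-bound
#' calcium at \code{kappaB * caBasal}, store at its resting level, and the
#' sensor at its steady state for basal calcium.
#'
#' @param cell a \linkS4class{CellParams}
#' @param sensor a \linkS4class{SensorModel}
#' @return a \linkS4class{CellState}
#' @export
restingState <- function(cell, sensor) {
  CellState(caFree = cell@caBasal, caSlow = cell@caBasal,
            bCa = cell@kappaB * cell@caBasal, caStore = .storeRest(cell),
            sensor = steadyState(sensor, cell@caBasal))
}

#' Apply an instantaneous spike-evoked calcium influx
#'
#' The total calcium added per action potential is split instantaneously
#' between the free pool and the fast endogenous buffer: the free pool
#' receives \code{aCa / (1 + kappaB)} and the buffer \code{aCa * kappaB /
#' (1 + kappaB)}. All other fields are unchanged.
#'
#' @param state a \linkS4class{CellState}
#' @param aCa total calcium added (uM, before buffering)
#' @param kappaB endogenous buffer capacity
#' @return the updated \linkS4class{CellState}
#' @export
applySpike <- function(state, aCa, kappaB) {
  if (aCa < 0) stop("aCa must be nonnegative")
  CellState(caFree = state@caFree + aCa / (1 + kappaB),
            caSlow = state@caSlow,
            bCa = state@bCa + aCa * kappaB / (1 + kappaB),
            caStore = state@caStore, sensor = state@sensor)
}

## Split the 9x9 generator into constant and per-lobe binding parts so the
## ODE right-hand side avoids rebuilding Kronecker products:
## Q(ca) = Q0 + konN(ca) QN + konC(ca) QC.
.generatorParts <- function(sensor) {
  gFixed <- function(l) matrix(c(0, l@koffCa, 0,
                                 0, -(l@koffCa + l@konPep), l@koffPep,
                                 0, l@konPep, -l@koffPep), 3, byrow = TRUE)
  gBind <- matrix(c(-1, 0, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  I3 <- diag(3)
  list(Q0 = kronecker(gFixed(sensor@lobeN), I3) +
            kronecker(I3, gFixed(sensor@lobeC)),
       QN = kronecker(gBind, I3),
       QC = kronecker(I3, gBind))
}

## Marginal apo/bound occupancies for each lobe from the joint 9-vector.
.lobeMarginals <- function(x) {
  list(nApo = sum(x[.N_OF_STATE == 1L]), nCa = sum(x[.N_OF_STATE == 2L]),
       cApo = sum(x[.C_OF_STATE == 1L]), cCa = sum(x[.C_OF_STATE == 2L]))
}

## Right-hand side shared by calciumDerivatives and the integrator.
## y = c(ca, caSlow, caStore, bCa, x1..x9); env carries a clip-warning flag.
.cellDeriv <- function(y, cell, sensor, parts, leak, env = NULL) {
  ca <- y[1]
  if (ca < 0) {
    if (!is.null(env) && !env$warned) {
      warning("free calcium went negative; clipped at 0", call. = FALSE)
      env$warned <- TRUE
    }
    ca <- 0
  }
  caSlow <- max(y[2], 0); caStore <- max(y[3], 0)
  x <- y[5:13]
  konN <- lobeOnRate(sensor@lobeN, ca)
  konC <- lobeOnRate(sensor@lobeC, ca)
  dx <- parts$Q0 %*% x + konN * (parts$QN %*% x) + konC * (parts$QC %*% x)
  m <- .lobeMarginals(x)
  jSensor <- cell@gTotal * sensor@nCaPerLobe *
    (konN * m$nApo - sensor@lobeN@koffCa * m$nCa +
     konC * m$cApo - sensor@lobeC@koffCa * m$cCa)
  jPump <- .mm(cell@pumpVmax, cell@pumpKm, ca)
  jIn <- .mm(cell@storeInVmax, cell@storeInKm, ca)
  jOut <- .mm(cell@storeOutVmax, cell@storeOutKm, caStore)
  vr <- .volRatio(cell)
  jSlow <- cell@slowK * vr * (caSlow - ca)
  jTotal <- leak - jPump + jOut - jIn + jSlow - jSensor
  dca <- jTotal / (1 + cell@kappaB)
  c(dca,
    if (vr > 0) cell@slowK * (ca - caSlow) else 0,
    jIn - jOut,
    cell@kappaB * dca,
    as.numeric(dx))
}

#' Time derivatives of the calcium-handling state
#'
#' Returns the instantaneous derivatives of all calcium pools and of the
#' sensor occupancy. Extrusion is Michaelis-Menten minus the constant
#' basal-balancing leak; store and slow-compartment fluxes are antisymmetric
#' (volume-ratio weighted for the slow pool); sensor binding removes free
#' calcium at rate \code{gTotal * nCaPerLobe *} (net lobe-binding flux).
#' The free-calcium derivative is divided by (1 + kappaB), the linearized
#' instantaneous-buffer-equilibration approximation.
#'
#' @param state a \linkS4class{CellState}
#' @param cell a \linkS4class{CellParams}
#' @param sensor a \linkS4class{SensorModel}
#' @return named numeric vector: caFree, caSlow, caStore, bCa and the nine
#'   sensor occupancy derivatives
#' @export
calciumDerivatives <- function(state, cell, sensor) {
  y <- c(state@caFree, state@caSlow, state@caStore, state@bCa,
         state@sensor@occupancy)
  d <- .cellDeriv(y, cell, sensor, .generatorParts(sensor), .leakRate(cell))
  names(d) <- c("caFree", "caSlow", "caStore", "bCa",
                names(stateNames(numeric(9))))
  d
}

#' Simulate a fluorescence transient from a spike train
#'
#' Integrates the coupled bouton-calcium and sensor master equations with a
#' stiff solver, applying the instantaneous buffered influx of
#' \code{\link{applySpike}} at each spike time, and reads out dF/F relative
#' to the basal steady state. Optional white Gaussian observation noise of
#' SD \code{sigma} (from \code{cell}) is added when a seed is supplied or
#' \code{sigma > 0}.
#'
#' @param cell a \linkS4class{CellParams}
#' @param sensor a \linkS4class{SensorModel}
#' @param spikes a \linkS4class{SpikeTrain} with times inside [0, duration]
#' @param duration trace length (s)
#' @param rate sampling rate (Hz)
#' @param noiseSeed optional integer seed for observation noise
#' @param returnLatents if TRUE, attach the latent state trajectory
#' @param rtol,atol solver tolerances
#' @return a \linkS4class{FluorescenceTrace}; with \code{returnLatents} a
#'   list with elements \code{trace}, \code{states} (13 x T matrix), and
#'   \code{time}
#' @export
simulateCell <- function(cell, sensor, spikes, duration, rate,
                         noiseSeed = NULL, returnLatents = FALSE,
                         rtol = 1e-8, atol = 1e-10) {
  if (duration <= 0) stop("duration must be > 0")
  st <- spikeTimes(spikes)
  if (length(st) && (any(st < 0) | any(st > duration)))
    stop("spike times must lie within [0, duration]")
  times <- seq(0, duration, by = 1 / rate)
  parts <- .generatorParts(sensor)
  leak <- .leakRate(cell)
  env <- new.env(); env$warned <- FALSE
  y0 <- {
    r <- restingState(cell, sensor)
    c(ca = r@caFree, caSlow = r@caSlow, caStore = r@caStore, bCa = r@bCa,
      setNames(r@sensor@occupancy, paste0("x", 1:9)))
  }
  rhs <- function(t, y, p) list(.cellDeriv(y, cell, sensor, parts, leak, env))
  events <- NULL
  if (length(st)) {
    dFree <- cell@aCa / (1 + cell@kappaB)
    dBuf <- cell@aCa * cell@kappaB / (1 + cell@kappaB)
    ev <- data.frame(
      var = rep(c("ca", "bCa"), each = length(st)),
      time = rep(st, 2),
      value = rep(c(dFree, dBuf), each = length(st)),
      method = "add")
    events <- list(data = ev[order(ev$time, ev$var), ])
  }
  sol <- withCallingHandlers(
    deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                   atol = atol, events = events, maxsteps = 50000),
    warning = function(w) {
      ## solver notes about event/output grid alignment are benign
      if (grepl("event", conditionMessage(w), ignore.case = TRUE))
        invokeRestart("muffleWarning")
    })
  ## solver may merge output rows with event times; re-grid if needed
  if (nrow(sol) != length(times)) {
    keep <- vapply(times, function(tt)
      which.min(abs(sol[, 1] - tt)), integer(1))
    sol <- sol[keep, , drop = FALSE]
  }
  x <- t(sol[, 6:14, drop = FALSE])
  fBasal <- fluorescence(steadyState(sensor, cell@caBasal), sensor, "cell")
  f <- fluorescence(x, sensor, "cell")
  dff <- as.numeric(dffValue(f, fBasal))
  if (cell@sigma > 0) {
    if (!is.null(noiseSeed)) {
      old <- .Random.seed.exists()
      on.exit(restoreSeed(old), add = TRUE)
      set.seed(noiseSeed)
    }
    dff <- dff + rnorm(length(dff), 0, cell@sigma)
  }
  trace <- FluorescenceTrace(dff = dff, rate = rate, time = times)
  if (!returnLatents) return(trace)
  list(trace = trace, states = t(sol[, -1, drop = FALSE]), time = times)
}

## RNG bookkeeping helpers: preserve the caller's stream around seeded draws.
.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restoreSeed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Transient summary statistics
#'
#' Event statistics of a fluorescence transient: peak amplitude relative to
#' the pre-event baseline, signal-to-noise ratio (peak over the robust SD,
#' MAD/0.6745, of the pre-stimulus baseline), 10-90\% rise time (linear
#' interpolation of the crossings of 10\% and 90\% of the peak relative to
#' baseline), and half-decay time (peak to 50\% crossing). Statistics whose
#' defining crossings fall outside the trace are reported as \code{NA}
#' rather than extrapolated.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param spikes a \linkS4class{SpikeTrain}; the first spike marks the event
#'   onset (an empty train treats t = 0 as onset)
#' @return list with elements \code{peak}, \code{snr}, \code{riseTime},
#'   \code{halfDecay}, \code{baseline} (times in seconds)
#' @export
summaryStats <- function(trace, spikes = SpikeTrain()) {
  t <- trace@time; y <- trace@dff
  st <- spikeTimes(spikes)
  onset <- if (length(st)) st[1] else 0
  pre <- y[t < onset]
  baseline <- if (length(pre)) median(pre) else 0
  noiseSd <- if (length(pre) > 1) mad(pre) else 0
  post <- which(t >= onset)
  if (!length(post)) stop("trace does not cover the event")
  ipk <- post[which.max(y[post])]
  peak <- y[ipk] - baseline
  snr <- if (noiseSd > 0) peak / noiseSd else Inf
  ## rise: last upward crossings of 10% / 90% before the peak
  lvl <- function(fr) baseline + fr * peak
  crossUp <- function(fr) {
    th <- lvl(fr)
    idx <- post[post <= ipk]
    below <- idx[y[idx] < th]
    if (!length(below)) return(NA_real_)
    i <- max(below)
    if (i >= ipk) return(NA_real_)
    t[i] + (th - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
  }
  t10 <- crossUp(0.10); t90 <- crossUp(0.90)
  riseTime <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10
  ## decay: first downward crossing of 50% after the peak
  th <- lvl(0.5)
  after <- which(t > t[ipk])
  belowIdx <- after[y[after] <= th]
  halfDecay <- if (!length(belowIdx)) NA_real_ else {
    i <- min(belowIdx)
    tc <- t[i - 1] + (y[i - 1] - th) / (y[i - 1] - y[i]) * (t[i] - t[i - 1])
    tc - t[ipk]
  }
  list(peak = peak, snr = snr, riseTime = riseTime, halfDecay = halfDecay,
       baseline = baseline, peakTime = t[ipk])
}

#' Paired-pulse amplitude ratio
#'
#' Second-response increment divided by the single-response amplitude:
#' (peak of the pair response - peak of the single response) / single peak.
#' A value of 1 indicates linear summation; larger values indicate
#' supralinear facilitation.
#'
#' @param pairTrace trace evoked by the two-spike protocol
#' @param singleTrace trace evoked by one spike
#' @return the dimensionless ratio
#' @export
pairedPulseRatio <- function(pairTrace, singleTrace) {
  pk2 <- max(pairTrace@dff); pk1 <- max(singleTrace@dff)
  if (pk1 <= 0) stop("single-spike response has non-positive peak")
  (pk2 - pk1) / pk1
}
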