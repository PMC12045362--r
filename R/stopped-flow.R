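#' @include AllClasses.R sensor-kinetics.R
NULL

#' Stopped-flow mixing protocol
#'
#' A calcium step from \code{caPre} to \code{caPost} at t = 0, observed from
#' \code{deadTime} (the unobservable mixing interval, typically 0.6-1.5 ms)
#' to \code{duration} at \code{rate} Hz. Free calcium is clamped by the
#' mixing buffer: the ~175 nM sensor does not deplete it.
#'
#' @slot caPre,caPost pre- and post-mix free calcium (uM)
#' @slot deadTime unobservable interval after mixing (s)
#' @slot duration observation window (s)
#' @slot rate sampling rate (Hz)
#' @exportClass StoppedFlowProtocol
setClass("StoppedFlowProtocol",
  representation(caPre = "numeric", caPost = "numeric", deadTime = "numeric",
                 duration = "numeric", rate = "numeric"))

setValidity("StoppedFlowProtocol", function(object) {
  if (object@caPre < 0 || object@caPost < 0)
    return("calcium concentrations must be nonnegative")
  if (object@deadTime < 0) return("deadTime must be >= 0")
  if (object@duration <= object@deadTime)
    return("duration must exceed deadTime")
  TRUE
})

#' Construct a stopped-flow protocol
#' @param caPre,caPost pre/post-mix free calcium (uM)
#' @param deadTime dead time (s), default 1 ms
#' @param duration observation window (s)
#' @param rate sampling rate (Hz)
#' @return a \linkS4class{StoppedFlowProtocol}
#' @export
StoppedFlowProtocol <- function(caPre, caPost, deadTime = 1e-3,
                                duration = 1, rate = 5000) {
  new("StoppedFlowProtocol", caPre = caPre, caPost = caPost,
      deadTime = deadTime, duration = duration, rate = rate)
}

## Analytic per-lobe occupancy at arbitrary times under constant calcium:
## eigendecomposition of the 3x3 generator. Returns 3 x length(t) matrix.
.lobeOccupancyAt <- function(lobe, ca, x0, t) {
  G <- .lobeGenerator(lobe, ca)
  e <- eigen(G)
  c0 <- solve(e$vectors, x0)
  out <- Re(e$vectors %*% (c0 * exp(outer(e$values, t))))
  pmax(out, 0)
}

#' Simulate a stopped-flow trace
#'
#' The sensor is equilibrated at \code{caPre}, calcium is stepped to
#' \code{caPost} at t = 0 and clamped; fluorescence is reported from
#' \code{deadTime} onward, normalized between 0 (zero-calcium steady state)
#' and 1 (saturating steady state). Because the lobes evolve independently
#' from a product initial state, the solution is computed analytically from
#' the per-lobe eigendecompositions.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param protocol a \linkS4class{StoppedFlowProtocol}
#' @return a normalized \linkS4class{FluorescenceTrace} whose first sample
#'   time is the first grid point at or after \code{deadTime}
#' @export
simulateStoppedFlow <- function(sensor, protocol) {
  tAll <- seq(0, protocol@duration, by = 1 / protocol@rate)
  t <- tAll[tAll >= protocol@deadTime]
  pN0 <- .lobeStationary(sensor@lobeN, protocol@caPre)
  pC0 <- .lobeStationary(sensor@lobeC, protocol@caPre)
  pN <- .lobeOccupancyAt(sensor@lobeN, protocol@caPost, pN0, t)
  pC <- .lobeOccupancyAt(sensor@lobeC, protocol@caPost, pC0, t)
  phi <- pN[3, ] + pC[3, ] - pN[3, ] * pC[3, ]
  pr <- .phiRange(sensor)
  f <- (phi - pr["phi0"]) / (pr["phiSat"] - pr["phi0"])
  FluorescenceTrace(dff = unname(f), rate = protocol@rate, time = t)
}

#' Half-rise time of a monotone-rising trace
#'
#' Time (from the first sample) at which the trace first crosses halfway
#' between its initial and final (last-sample) level, by linear
#' interpolation.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @return time in seconds, or NA if the trace never crosses
#' @export
halfRiseTime <- function(trace) {
  y <- trace@dff; t <- trace@time
  th <- y[1] + 0.5 * (y[length(y)] - y[1])
  i <- which(y >= th)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  t[i - 1] + (th - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1]) - t[1]
}

## Linear LS solve of amplitudes + offset for fixed taus; returns list with
## residual sum of squares. Design matrix: exp(-t/tau_k) columns plus 1.
.ampsForTaus <- function(t, y, taus) {
  X <- cbind(exp(-outer(t, taus, "/")), 1)
  fit <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  r <- y - X %*% fit
  list(amps = fit[seq_along(taus)], offset = fit[length(fit)],
       rss = sum(r^2))
}

#' Fit a sum of exponentials
#'
#' Least-squares fit of \code{y = offset + sum_k a_k exp(-t / tau_k)} with
#' t measured from the first sample. Deterministic multistart: time
#' constants are scanned over a log-spaced grid (amplitudes and offset
#' solved linearly for each candidate), and the best grid point is polished
#' by Levenberg-Marquardt. Rising traces are handled by the sign of the
#' fitted amplitudes; \code{direction} only checks the trend.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param nComponents 1, 2 or 3
#' @param direction "rise" or "decay" (consistency check only)
#' @return an \linkS4class{ExpFit} with taus ascending
#' @export
fitMultiExponential <- function(trace, nComponents = 2,
                                direction = c("decay", "rise")) {
  direction <- match.arg(direction)
  stopifnot(nComponents %in% 1:3)
  t <- trace@time - trace@time[1]
  y <- trace@dff
  span <- max(t)
  grid <- exp(seq(log(max(1 / trace@rate, span * 1e-4)), log(span * 2),
                  length.out = 14))
  combos <- utils::combn(length(grid), nComponents)
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    taus <- grid[combos[, j]]
    cand <- .ampsForTaus(t, y, taus)
    if (is.null(cand)) next
    if (is.null(best) || cand$rss < best$rss) {
      best <- cand; best$taus <- taus
    }
  }
  if (is.null(best)) stop("multi-exponential fit failed on the tau grid")
  ## LM polish on log-taus (amplitudes/offset re-solved inside)
  obj <- function(lt) {
    cand <- .ampsForTaus(t, y, exp(lt))
    if (is.null(cand)) return(rep(1e6, length(y)))
    X <- cbind(exp(-outer(t, exp(lt), "/")), 1)
    as.numeric(y - X %*% c(cand$amps, cand$offset))
  }
  pol <- tryCatch(
    minpack.lm::nls.lm(par = log(best$taus), fn = obj,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(pol)) {
    cand <- .ampsForTaus(t, y, exp(pol$par))
    if (!is.null(cand) && cand$rss <= best$rss) {
      best <- cand; best$taus <- exp(pol$par)
    }
  }
  o <- order(best$taus)
  new("ExpFit", amplitudes = as.numeric(best$amps[o]),
      taus = as.numeric(best$taus[o]), offset = as.numeric(best$offset),
      residualRms = sqrt(best$rss / length(y)))
}

#' Evaluate a multi-exponential fit
#' @param fit an \linkS4class{ExpFit}
#' @param t times (s) measured from the fit origin
#' @return fitted values
#' @export
predictExpFit <- function(fit, t) {
  as.numeric(exp(-outer(t, fit@taus, "/")) %*% fit@amplitudes + fit@offset)
}

#' Fit the Hill equation to steady-state responses
#'
#' Least-squares fit of
#' \code{f = fMin + (fMax - fMin) ca^h / (kd^h + ca^h)}.
#'
#' @param ca calcium concentrations (uM), at least 4 distinct values
#' @param f steady-state responses
#' @return a \linkS4class{HillFit}
#' @export
fitHill <- function(ca, f) {
  if (length(unique(ca)) < 4) stop("need at least 4 distinct concentrations")
  if (diff(range(f)) < 1e-12 * max(abs(f), 1))
    stop("flat response data: Hill fit is not identifiable")
  ## starts from the data
  fMin0 <- min(f); fMax0 <- max(f)
  mid <- fMin0 + 0.5 * (fMax0 - fMin0)
  kd0 <- approx(f, ca, xout = mid, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(ca[ca > 0])
  obj <- function(p) {
    kd <- exp(p[1]); h <- exp(p[2])
    pred <- p[3] + (p[4] - p[3]) * ca^h / (kd^h + ca^h)
    f - pred
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(kd0), log(1), fMin0, fMax0), fn = obj,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  new("HillFit", kd = exp(p[1]), hill = exp(p[2]), fMin = p[3], fMax = p[4])
}

#' Evaluate a Hill fit
#' @param fit a \linkS4class{HillFit}
#' @param ca calcium concentrations (uM)
#' @return fitted response
#' @export
predictHillFit <- function(fit, ca) {
  fit@fMin + (fit@fMax - fit@fMin) * ca^fit@hill /
    (fit@kd^fit@hill + ca^fit@hill)
}

## Parameter packing for the 10 kinetic parameters (both lobes), log scale.
.sensorParNames <- c("N.koffCa", "N.Ka", "N.hill", "N.konPep", "N.koffPep",
                     "C.koffCa", "C.Ka", "C.hill", "C.konPep", "C.koffPep")

.packSensor <- function(sensor) {
  log(c(sensor@lobeN@koffCa, sensor@lobeN@Ka, sensor@lobeN@hill,
        sensor@lobeN@konPep, sensor@lobeN@koffPep,
        sensor@lobeC@koffCa, sensor@lobeC@Ka, sensor@lobeC@hill,
        sensor@lobeC@konPep, sensor@lobeC@koffPep))
}

.unpackSensor <- function(logPar, Rf = 10, name = "fit",
                          nCaPerLobe = 2L, meta = list()) {
  p <- exp(logPar)
  p[c(3, 8)] <- pmin(p[c(3, 8)], 4)  # Hill cap
  SensorModel(
    lobeN = LobeKinetics(p[1], p[2], p[3], p[4], p[5]),
    lobeC = LobeKinetics(p[6], p[7], p[8], p[9], p[10]),
    Rf = Rf, nCaPerLobe = nCaPerLobe, name = name, meta = meta)
}

## Default log-bounds for the kinetic parameters.
.sensorLogBounds <- function() {
  lower <- log(c(0.5, 0.01, 0.5, 0.5, 0.05, 0.5, 0.01, 0.5, 0.5, 0.05))
  upper <- log(c(5e3, 10, 4, 5e3, 5e2, 5e3, 10, 4, 5e3, 5e2))
  cbind(lower = lower, upper = upper)
}

#' Multistart global fit of sensor kinetics to stopped-flow traces
#'
#' Mean-squared-error fit (traces weighted equally) of the ten lobe kinetic
#' parameters to a set of stopped-flow recordings. Initial points are drawn
#' from a maximin Latin hypercube over log-scaled parameter bounds (a
#' low-discrepancy design); each start is refined by Nelder-Mead and the
#' best final loss wins. Deterministic given \code{seed}.
#'
#' @param traces list of \code{list(protocol = StoppedFlowProtocol, trace =
#'   FluorescenceTrace)} pairs; at least 3 distinct calcium steps including
#'   one step-down are recommended
#' @param nStarts number of multistart points (default 64; the full
#'   characterization-scale run uses many more)
#' @param seed integer seed
#' @param extraStarts optional list of \linkS4class{SensorModel} objects
#'   whose parameters are added to the start set
#' @param maxit Nelder-Mead iteration cap per start
#' @return list with elements \code{sensor} (best \linkS4class{SensorModel}),
#'   \code{loss}, and \code{diagnostics} (per-start losses)
#' @export
globalFitSensor <- function(traces, nStarts = 64, seed = 1,
                            extraStarts = list(), maxit = 400) {
  stopifnot(length(traces) >= 1)
  bounds <- .sensorLogBounds()
  loss <- function(logPar) {
    if (any(logPar < bounds[, 1] - 20) || any(logPar > bounds[, 2] + 20))
      return(1e6)
    s <- tryCatch(.unpackSensor(logPar), error = function(e) NULL)
    if (is.null(s)) return(1e6)
    tot <- 0
    for (tr in traces) {
      sim <- tryCatch(simulateStoppedFlow(s, tr$protocol),
                      error = function(e) NULL)
      if (is.null(sim)) return(1e6)
      n <- min(length(sim@dff), length(tr$trace@dff))
      tot <- tot + mean((sim@dff[seq_len(n)] - tr$trace@dff[seq_len(n)])^2)
    }
    tot / length(traces)
  }
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  d <- nrow(bounds)
  u <- lhs::maximinLHS(max(nStarts, 2), d)
  starts <- lapply(seq_len(nrow(u)), function(i)
    bounds[, 1] + u[i, ] * (bounds[, 2] - bounds[, 1]))
  starts <- c(starts, lapply(extraStarts, .packSensor))
  results <- lapply(starts, function(p0) {
    fit <- tryCatch(
      optim(p0, loss, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) list(par = p0, value = 1e6))
    list(par = fit$par, value = fit$value)
  })
  losses <- vapply(results, `[[`, numeric(1), "value")
  if (all(losses >= 1e6))
    stop("all multistart fits failed; per-start losses: ",
         paste(signif(losses, 3), collapse = ", "))
  best <- results[[which.min(losses)]]
  sensor <- .unpackSensor(best$par, meta = list(
    loss = best$value, seed = seed, nStarts = length(starts)))
  list(sensor = sensor, loss = best$value, diagnostics = losses)
}

#' Fit cell parameters to recordings with a fixed sensor
#'
#' With the sensor kinetics held fixed, optimizes cell-specific parameters
#' (by default calcium influx per spike \code{aCa}, sensor concentration
#' \code{gTotal}, and extrusion \code{pumpVmax}) per recording by
#' Nelder-Mead on log scale, minimizing the mean squared error between the
#' simulated and recorded dF/F. Deterministic given \code{seed}.
#'
#' @param recordings list of \code{list(trace = FluorescenceTrace, spikes =
#'   SpikeTrain)} pairs
#' @param sensor a fixed \linkS4class{SensorModel}
#' @param cell0 starting \linkS4class{CellParams}
#' @param whichPars names of CellParams slots to optimize
#' @param seed integer seed (start jitter)
#' @param nStarts number of jittered starts per recording
#' @return list (one per recording) of \code{list(cell, loss, trajectory)}
#' @export
fitCellParams <- function(recordings, sensor, cell0 = CellParams(),
                          whichPars = c("aCa", "gTotal", "pumpVmax"),
                          seed = 1, nStarts = 4) {
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  lapply(recordings, function(rec) {
    trace <- rec$trace; spikes <- rec$spikes
    duration <- (length(trace@dff) - 1) / trace@rate
    lossHist <- numeric(0)
    loss <- function(logPar) {
      cell <- cell0
      for (i in seq_along(whichPars))
        slot(cell, whichPars[i]) <- unname(exp(logPar[i]))
      cell@sigma <- 0
      sim <- tryCatch(
        simulateCell(cell, sensor, spikes, duration, trace@rate),
        error = function(e) NULL)
      if (is.null(sim)) return(1e6)
      v <- mean((sim@dff - trace@dff)^2)
      lossHist <<- c(lossHist, v)
      v
    }
    p0 <- log(vapply(whichPars, function(nm) slot(cell0, nm), numeric(1)))
    starts <- c(list(p0), lapply(seq_len(max(nStarts - 1, 0)), function(i)
      p0 + rnorm(length(p0), 0, 0.5)))
    fits <- lapply(starts, function(s) {
      if (length(s) == 1L)
        optim(s, loss, method = "Brent", lower = s - 8, upper = s + 8)
      else
        optim(s, loss, method = "Nelder-Mead",
              control = list(maxit = 300, reltol = 1e-10))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    cell <- cell0
    for (i in seq_along(whichPars))
      slot(cell, whichPars[i]) <- unname(exp(best$par[i]))
    list(cell = cell, loss = best$value,
         trajectory = cummin(lossHist))
  })
}

#' Accessible-slowing surrogate
#'
#' A documented surrogate (not a published formula) for the tendency of a
#' sensor to become trapped in slow fluorescent states after large calcium
#' transients: the ratio of (slow-state entry rate x slow-state dwell time)
#' to the fast-state counterpart, evaluated at a reference calcium level.
#' Entry rates are the C- and N-lobe peptide on-rates weighted by the
#' calcium-bound lobe fraction at \code{ca}; dwell times are the inverse
#' peptide off-rates.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param ca reference calcium (uM), default 1
#' @return dimensionless slowing index
#' @export
accessibleSlowing <- function(sensor, ca = 1) {
  pN <- .lobeStationary(sensor@lobeN, ca)
  pC <- .lobeStationary(sensor@lobeC, ca)
  slow <- (pC[2] * sensor@lobeC@konPep) / sensor@lobeC@koffPep
  fast <- (pN[2] * sensor@lobeN@konPep) / sensor@lobeN@koffPep
  unname(slow / fast)
}
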