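#' @include AllClasses.R spike-metrics.R
NULL

#' Supervised spike-density regressor
#'
#' A windowed gradient-boosted tree regressor mapping a local window of
#' dF/F samples to the Gaussian-smoothed spike density at the window
#' centre, trained on the synthetic corpus. The embedded manifest records
#' everything needed to retrain to equivalent performance.
#'
#' @slot booster serialized xgboost model (raw bytes)
#' @slot manifest training manifest: corpus manifest, seeds, window and
#'   smoothing settings, loss curve, held-out loss
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(booster = "raw", manifest = "list"))

## Window design matrix: rows = bins, cols = trace samples at lags
## -w..w (zero-padded at the edges).
.windowFeatures <- function(y, w) {
  n <- length(y)
  yp <- c(rep(0, w), y, rep(0, w))
  lags <- -w:w
  X <- matrix(0, n, length(lags))
  for (j in seq_along(lags)) X[, j] <- yp[(1 + w + lags[j]):(n + w + lags[j])]
  X
}

## Smoothed spike-density target (counts smoothed with a unit-mass kernel).
.densityTarget <- function(spikes, n, rate, smoothSd) {
  .gaussSmooth(binSpikes(spikes, n, rate), smoothSd * rate)
}

#' Train the supervised spike-density model
#'
#' Builds windowed features and Gaussian-smoothed spike-density targets
#' from a synthetic corpus and fits a gradient-boosted tree regressor
#' (squared-error objective, single thread, fixed seed: deterministic).
#' One boosting round plays the role of one training epoch; the per-round
#' training RMSE curve is stored in the manifest. A held-out subset of
#' traces provides the reported held-out loss and correlation.
#'
#' @param corpus output of \code{\link{generateCorpus}} (or a list with
#'   \code{traces})
#' @param config list of settings: \code{windowHalf} (s, default 0.064),
#'   \code{smoothSd} (s, default 0.010), \code{nrounds} (default 150),
#'   \code{eta}, \code{maxDepth}, \code{heldOut} (number of held-out
#'   traces, default 1), \code{nSilent} (resting-condition augmentation
#'   rows with zero target, teaching the quiescent baseline; default 2000)
#' @param seed integer seed
#' @return a \linkS4class{TrainedModel}
#' @export
trainSupervised <- function(corpus, config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(windowHalf = 0.064, smoothSd = 0.010, nrounds = 150, eta = 0.1,
         maxDepth = 4, heldOut = 1, nSilent = 2000), config)
  traces <- corpus$traces
  if (is.null(traces)) traces <- corpus
  nSpikes <- sum(vapply(traces, function(tr)
    length(spikeTimes(tr$spikes)), numeric(1)))
  if (nSpikes < 10)
    stop("degenerate corpus: needs at least 10 spikes, has ", nSpikes)
  rate <- traces[[1]]$trace@rate
  w <- round(cfg$windowHalf * rate)
  build <- function(tr) {
    y <- tr$trace@dff
    list(X = .windowFeatures(y, w),
         z = .densityTarget(tr$spikes, length(y), rate, cfg$smoothSd))
  }
  nHeld <- min(cfg$heldOut, length(traces) - 1)
  idxHeld <- if (nHeld > 0) tail(seq_along(traces), nHeld) else integer(0)
  trn <- lapply(traces[setdiff(seq_along(traces), idxHeld)], build)
  X <- do.call(rbind, lapply(trn, `[[`, "X"))
  z <- unlist(lapply(trn, `[[`, "z"))
  if (cfg$nSilent > 0) {
    ## resting-condition augmentation: silent windows map to zero density
    X <- rbind(X, matrix(0, cfg$nSilent, ncol(X)))
    z <- c(z, numeric(cfg$nSilent))
  }
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = z)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = cfg$eta,
                  max_depth = cfg$maxDepth, nthread = 1, seed = seed,
                  base_score = 0),
    data = dtrain, nrounds = cfg$nrounds,
    evals = list(train = dtrain), verbose = 0)
  lossCurve <- attributes(booster)$evaluation_log$train_rmse
  heldLoss <- NA_real_; heldCor <- NA_real_
  if (length(idxHeld)) {
    hld <- lapply(traces[idxHeld], build)
    Xh <- do.call(rbind, lapply(hld, `[[`, "X"))
    zh <- unlist(lapply(hld, `[[`, "z"))
    ph <- pmax(predict(booster, xgboost::xgb.DMatrix(Xh)), 0)
    heldLoss <- sqrt(mean((ph - zh)^2))
    heldCor <- if (sd(ph) > 0 && sd(zh) > 0) cor(ph, zh) else NA_real_
  }
  manifest <- list(
    rate = rate, windowHalf = cfg$windowHalf, windowBins = w,
    smoothSd = cfg$smoothSd, nrounds = cfg$nrounds, eta = cfg$eta,
    maxDepth = cfg$maxDepth, nSilent = cfg$nSilent, seed = seed,
    heldOutTraces = idxHeld,
    lossCurve = lossCurve, heldOutLoss = heldLoss, heldOutCor = heldCor,
    corpusManifest = corpus$manifest)
  new("TrainedModel", booster = xgboost::xgb.save.raw(booster),
      manifest = manifest)
}

#' Predict per-bin spike density
#'
#' @param model a \linkS4class{TrainedModel}
#' @param trace a \linkS4class{FluorescenceTrace}; its rate must match the
#'   training rate unless \code{resample = TRUE}
#' @param resample linearly resample the trace to the training rate
#' @return nonnegative numeric spike-density vector, one value per bin
#' @export
predictDensity <- function(model, trace, resample = FALSE) {
  rate <- model@manifest$rate
  if (abs(trace@rate - rate) > 1e-6 * rate) {
    if (!resample)
      stop("trace rate ", trace@rate, " Hz differs from training rate ",
           rate, " Hz; pass resample = TRUE to resample")
    tNew <- seq(trace@time[1], tail(trace@time, 1), by = 1 / rate)
    y <- approx(trace@time, trace@dff, tNew)$y
    trace <- FluorescenceTrace(dff = y, rate = rate, time = tNew)
  }
  booster <- xgboost::xgb.load.raw(model@booster)
  X <- .windowFeatures(trace@dff, model@manifest$windowBins)
  pmax(predict(booster, xgboost::xgb.DMatrix(X)), 0)
}

#' Discretize a spike-density trace into spike times
#'
#' Greedy matching pursuit: repeatedly place a unit-mass Gaussian kernel
#' (SD \code{kernelWidth}) at the maximum of the residual density, while
#' the residual mass is at least half a kernel's mass. Placed centres are
#' returned as spike times.
#'
#' @param density nonnegative per-bin spike density
#' @param kernelWidth Gaussian SD (s); defaults to the model smoothing
#' @param rate bin rate (Hz)
#' @param maxSpikes safety cap on the number of placed kernels
#' @return a \linkS4class{SpikeTrain}
#' @export
discretizeDensity <- function(density, kernelWidth, rate,
                              maxSpikes = length(density)) {
  if (any(density < -1e-9)) stop("density must be nonnegative")
  r <- pmax(as.numeric(density), 0)
  n <- length(r)
  sdBins <- kernelWidth * rate
  half <- max(1L, ceiling(5 * sdBins))
  kern <- dnorm(seq(-half, half), sd = sdBins)
  kern <- kern / sum(kern)
  centers <- ((seq_len(n) - 1) + 0.5) / rate
  times <- numeric(0)
  while (sum(r) >= 0.5 && length(times) < maxSpikes) {
    i <- which.max(r)
    if (r[i] <= 0.25 * max(kern)) break
    times <- c(times, centers[i])
    lo <- max(1L, i - half); hi <- min(n, i + half)
    r[lo:hi] <- r[lo:hi] - kern[(lo - i + half + 1):(hi - i + half + 1)]
    r <- pmax(r, 0)
  }
  SpikeTrain(sort(unique(times)))
}

#' Retrain a model from its manifest
#'
#' Regenerates the training corpus from the embedded corpus manifest and
#' reruns training with the stored settings and seed.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param presets,sensor,cell the generator arguments used originally
#' @return a new \linkS4class{TrainedModel}
#' @export
retrainFromManifest <- function(model, presets, sensor,
                                cell = CellParams()) {
  m <- model@manifest
  traces <- regenerateCorpus(m$corpusManifest, presets, sensor, cell)
  trainSupervised(list(traces = traces, manifest = m$corpusManifest),
                  config = list(windowHalf = m$windowHalf,
                                smoothSd = m$smoothSd, nrounds = m$nrounds,
                                eta = m$eta, maxDepth = m$maxDepth,
                                nSilent = m$nSilent,
                                heldOut = length(m$heldOutTraces)),
                  seed = m$seed)
}
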