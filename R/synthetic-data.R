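#' @include AllClasses.R cell-model.R
NULL

#' Construct a trace preset
#'
#' The \code{"excitatory"} preset emulates a 10 Hz Poisson-spiking cell at
#' single-spike SNR of roughly 5; the \code{"inhibitory"} preset a 30 Hz
#' Poisson-spiking cell whose calcium influx per spike is halved and whose
#' dynamic range above 1 (Rf - 1) is halved, giving smaller, noisier
#' responses. \code{"custom"} leaves all scaling untouched.
#'
#' @param name "excitatory", "inhibitory" or "custom"
#' @param rate Poisson rate (Hz)
#' @param duration trace duration (s)
#' @param sampleRate sampling rate (Hz)
#' @param sigma white observation noise SD (dF/F)
#' @param driftAmp baseline drift stationary SD (dF/F)
#' @param driftTau baseline drift timescale (s)
#' @param refractory absolute refractory period (s)
#' @param cellOverrides named list of CellParams slot overrides
#' @return a \linkS4class{TracePreset}
#' @export
tracePreset <- function(name = c("excitatory", "inhibitory", "custom"),
                        rate = NULL, duration = 60, sampleRate = 500,
                        sigma = 0.12, driftAmp = 0.02, driftTau = 5,
                        refractory = 0.003, cellOverrides = list()) {
  name <- match.arg(name)
  if (is.null(rate)) rate <- switch(name, excitatory = 10, inhibitory = 30,
                                    custom = 10)
  new("TracePreset", name = name, rate = rate, duration = duration,
      sampleRate = sampleRate, sigma = sigma, driftAmp = driftAmp,
      driftTau = driftTau, refractory = refractory,
      cellOverrides = cellOverrides)
}

## Derive a bounded, distinct sub-seed from a base seed and a stream label.
.subSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + stream * 7919L
}

#' Sample a Poisson spike train with absolute refractoriness
#'
#' Homogeneous Poisson process thinned so that every inter-spike interval
#' is at least \code{refractory}. Deterministic given \code{seed}.
#'
#' @param rate spike rate (Hz), >= 0
#' @param duration window length (s)
#' @param refractory absolute refractory period (s)
#' @param seed integer seed
#' @return a \linkS4class{SpikeTrain}
#' @export
sampleSpikeTrain <- function(rate, duration, refractory = 0, seed = 1) {
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(SpikeTrain())
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  n <- rpois(1, rate * duration * 1.5) + 50
  gaps <- rexp(n, rate)
  t <- cumsum(gaps)
  while (max(t) < duration) t <- c(t, max(t) + cumsum(rexp(n, rate)))
  t <- t[t < duration]
  keep <- numeric(0); last <- -Inf
  for (ti in t) {
    if (ti - last >= refractory) { keep <- c(keep, ti); last <- ti }
  }
  SpikeTrain(keep)
}

## Ornstein-Uhlenbeck baseline drift sampled exactly on the grid.
.ouDrift <- function(n, dt, amp, tau, seed) {
  if (amp <= 0) return(numeric(n))
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  rho <- exp(-dt / tau)
  innov <- rnorm(n, 0, amp * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, amp)
  for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i]
  x
}

## Apply preset scalings/overrides to cell and sensor.
.presetApply <- function(preset, sensor, cell) {
  for (nm in names(preset@cellOverrides))
    slot(cell, nm) <- preset@cellOverrides[[nm]]
  if (preset@name == "inhibitory") {
    cell@aCa <- cell@aCa / 2
    sensor@Rf <- 1 + (sensor@Rf - 1) / 2
  }
  list(sensor = sensor, cell = cell)
}

#' Generate a ground-truth-paired synthetic fluorescence trace
#'
#' Simulates the bouton model driven by a Poisson spike train and adds
#' Ornstein-Uhlenbeck baseline drift and white Gaussian noise. The seed is
#' split deterministically into independent spike, drift, and noise
#' streams, so the triple (trace, spikes, latents) is fully reproducible.
#'
#' @param preset a \linkS4class{TracePreset}
#' @param sensor a \linkS4class{SensorModel}
#' @param cell a \linkS4class{CellParams} (preset overrides applied on top)
#' @param seed integer seed
#' @return list with \code{trace} (\linkS4class{FluorescenceTrace}),
#'   \code{spikes} (\linkS4class{SpikeTrain}), and \code{latents} (list with
#'   the noiseless dF/F and the drift component)
#' @export
generateTrace <- function(preset, sensor, cell = CellParams(), seed = 1) {
  pa <- .presetApply(preset, sensor, cell)
  spikes <- sampleSpikeTrain(preset@rate, preset@duration,
                             preset@refractory, .subSeed(seed, 1L))
  pa$cell@sigma <- 0
  clean <- simulateCell(pa$cell, pa$sensor, spikes, preset@duration,
                        preset@sampleRate)
  n <- length(clean@dff)
  drift <- .ouDrift(n, 1 / preset@sampleRate, preset@driftAmp,
                    preset@driftTau, .subSeed(seed, 2L))
  noise <- if (preset@sigma > 0) {
    old <- .Random.seed.exists()
    set.seed(.subSeed(seed, 3L))
    z <- rnorm(n, 0, preset@sigma)
    restoreSeed(old)
    z
  } else numeric(n)
  trace <- FluorescenceTrace(dff = clean@dff + drift + noise,
                             rate = preset@sampleRate, time = clean@time)
  list(trace = trace, spikes = spikes,
       latents = list(clean = clean@dff, drift = drift))
}

#' Generate a corpus of paired synthetic traces
#'
#' Draws per-trace cell parameters from log-normal jitter around the given
#' cell model (emulating across-cell variability), generates each trace
#' with its own deterministic sub-seed, and records every draw in a
#' manifest from which the corpus can be regenerated bit-identically.
#'
#' @param nTraces number of traces (>= 1)
#' @param presets list of \linkS4class{TracePreset}s cycled over traces
#' @param sensor a \linkS4class{SensorModel}
#' @param cell base \linkS4class{CellParams}
#' @param seed integer master seed
#' @param jitterSd SD of the log-normal jitter applied to aCa and gTotal
#' @return list with \code{traces} (list of generateTrace outputs) and
#'   \code{manifest} (data.frame of sub-seeds and parameter draws)
#' @export
generateCorpus <- function(nTraces, presets, sensor, cell = CellParams(),
                           seed = 1, jitterSd = 0.15) {
  stopifnot(nTraces >= 1)
  if (is(presets, "TracePreset")) presets <- list(presets)
  old <- .Random.seed.exists(); on.exit(restoreSeed(old), add = TRUE)
  set.seed(.subSeed(seed, 0L))
  jit <- matrix(rnorm(2 * nTraces, 0, jitterSd), ncol = 2)
  manifest <- data.frame(
    id = seq_len(nTraces),
    preset = vapply(seq_len(nTraces), function(i)
      presets[[(i - 1) %% length(presets) + 1]]@name, character(1)),
    subSeed = vapply(seq_len(nTraces), function(i)
      .subSeed(seed, 10L + i), numeric(1)),
    aCa = cell@aCa * exp(jit[, 1]),
    gTotal = cell@gTotal * exp(jit[, 2]))
  traces <- lapply(seq_len(nTraces), function(i) {
    ci <- cell
    ci@aCa <- manifest$aCa[i]
    ci@gTotal <- manifest$gTotal[i]
    p <- presets[[(i - 1) %% length(presets) + 1]]
    generateTrace(p, sensor, ci, manifest$subSeed[i])
  })
  list(traces = traces, manifest = manifest)
}

#' Regenerate a corpus from its manifest
#'
#' @param manifest a manifest data.frame from \code{\link{generateCorpus}}
#' @param presets the same preset list used originally
#' @param sensor,cell the same sensor and base cell parameters
#' @return list of generateTrace outputs, bit-identical to the original
#' @export
regenerateCorpus <- function(manifest, presets, sensor,
                             cell = CellParams()) {
  if (is(presets, "TracePreset")) presets <- list(presets)
  lapply(seq_len(nrow(manifest)), function(i) {
    ci <- cell
    ci@aCa <- manifest$aCa[i]
    ci@gTotal <- manifest$gTotal[i]
    p <- presets[[(i - 1) %% length(presets) + 1]]
    generateTrace(p, sensor, ci, manifest$subSeed[i])
  })
}
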