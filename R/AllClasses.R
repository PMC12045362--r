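#' @import methods
#' @importFrom stats dnorm rnorm runif rbinom rexp median mad sd quantile
#'   optim nlminb approx convolve cor complete.cases setNames ks.test uniroot
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib biospike, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Per-lobe state coding used throughout: 1 = apo, 2 = Ca-bound,
## 3 = Ca + peptide bound (fluorescence-competent configuration of that lobe).
## Joint 9-state index: s = (n - 1) * 3 + c, N-lobe major.
.LOBE_STATES <- c("apo", "ca", "pep")

#' Kinetic parameters of one calmodulin lobe
#'
#' Holds the rate constants governing calcium binding and subsequent target
#' peptide binding at one lobe (N or C) of the sensor's calmodulin domain.
#' The calcium on-rate is not stored: it is derived from the off-rate,
#' the apparent dissociation constant and the Hill coefficient via
#' \code{\link{lobeOnRate}}.
#'
#' @slot koffCa calcium unbinding rate (1/s)
#' @slot Ka apparent dissociation constant (uM)
#' @slot hill Hill coefficient for cooperative calcium binding (dimensionless)
#' @slot konPep peptide-binding rate from the calcium-bound lobe state (1/s)
#' @slot koffPep peptide-unbinding rate (1/s)
#' @exportClass LobeKinetics
setClass("LobeKinetics",
  representation(koffCa = "numeric", Ka = "numeric", hill = "numeric",
                 konPep = "numeric", koffPep = "numeric"))

setValidity("LobeKinetics", function(object) {
  v <- c(koffCa = object@koffCa, Ka = object@Ka, hill = object@hill,
         konPep = object@konPep, koffPep = object@koffPep)
  if (length(v) != 5L || any(!is.finite(v)))
    return("all five rate parameters must be finite scalars")
  if (any(v <= 0)) return("all rates and K_a must be strictly positive")
  if (object@hill > 4) return("Hill coefficient must be in (0, 4]")
  TRUE
})

#' Construct lobe kinetics
#'
#' @param koffCa calcium off-rate (1/s)
#' @param Ka apparent dissociation constant (uM)
#' @param hill Hill coefficient (0 < H <= 4)
#' @param konPep peptide on-rate from the calcium-bound state (1/s)
#' @param koffPep peptide off-rate (1/s)
#' @return a \linkS4class{LobeKinetics} object
#' @export
LobeKinetics <- function(koffCa, Ka, hill, konPep, koffPep) {
  new("LobeKinetics", koffCa = as.numeric(koffCa), Ka = as.numeric(Ka),
      hill = as.numeric(hill), konPep = as.numeric(konPep),
      koffPep = as.numeric(koffPep))
}

#' Multistate kinetic model of a GCaMP variant
#'
#' Two semi-independent calmodulin lobes (the fast-binding N-lobe and the
#' slow-binding C-lobe), each cycling apo -> Ca-bound -> Ca+peptide-bound,
#' tracked jointly over the 9 combined configurations. Fluorescence arises
#' from configurations where at least one lobe has bound the target peptide.
#'
#' @slot lobeN kinetics of the fast (N) lobe
#' @slot lobeC kinetics of the slow (C) lobe
#' @slot Rf dynamic range: fluorescence at saturating calcium relative to
#'   zero calcium (>= 1)
#' @slot nCaPerLobe calcium ions sequestered per lobe-binding event (used for
#'   mass balance in the cell model; two EF-hands per lobe by default)
#' @slot name variant label, e.g. "jGCaMP8f"
#' @slot meta provenance metadata (fit loss, seed, data version)
#' @exportClass SensorModel
setClass("SensorModel",
  representation(lobeN = "LobeKinetics", lobeC = "LobeKinetics",
                 Rf = "numeric", nCaPerLobe = "integer",
                 name = "character", meta = "list"))

setValidity("SensorModel", function(object) {
  if (!is.finite(object@Rf) || object@Rf < 1)
    return("Rf (dynamic range) must be >= 1")
  if (object@nCaPerLobe < 1L)
    return("nCaPerLobe must be a positive integer")
  TRUE
})

#' Construct a sensor model
#'
#' @param lobeN,lobeC \linkS4class{LobeKinetics} for the N (fast) and C
#'   (slow) lobes
#' @param Rf dynamic range (>= 1)
#' @param nCaPerLobe calcium ions per lobe-binding event (default 2)
#' @param name variant label
#' @param meta provenance list
#' @return a \linkS4class{SensorModel}
#' @export
SensorModel <- function(lobeN, lobeC, Rf, nCaPerLobe = 2L,
                        name = "custom", meta = list()) {
  new("SensorModel", lobeN = lobeN, lobeC = lobeC, Rf = as.numeric(Rf),
      nCaPerLobe = as.integer(nCaPerLobe), name = name, meta = meta)
}

#' Occupancy over the 9 joint sensor configurations
#'
#' A probability vector over the joint (N-lobe, C-lobe) configuration space,
#' N-lobe major: index s = (n-1)*3 + c with per-lobe states apo, ca, pep.
#'
#' @slot occupancy numeric 9-vector, nonnegative, summing to 1
#' @exportClass SensorState
setClass("SensorState", representation(occupancy = "numeric"))

setValidity("SensorState", function(object) {
  p <- object@occupancy
  if (length(p) != 9L) return("occupancy must have length 9")
  if (any(!is.finite(p))) return("occupancy must be finite")
  if (any(p < -1e-9)) return("occupancy entries must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) return("occupancy must sum to 1 (within 1e-9)")
  TRUE
})

#' Construct a sensor state
#' @param occupancy numeric 9-vector over joint lobe configurations
#' @return a \linkS4class{SensorState}
#' @export
SensorState <- function(occupancy) {
  occupancy <- pmax(as.numeric(occupancy), 0)
  occupancy <- occupancy / sum(occupancy)
  new("SensorState", occupancy = stateNames(occupancy))
}

stateNames <- function(x) {
  names(x) <- paste(rep(.LOBE_STATES, each = 3), rep(.LOBE_STATES, 3),
                    sep = ".")
  x
}

#' Calcium-handling parameters of a bouton compartment
#'
#' Parameters of the single-bouton cell model: spike-evoked calcium influx,
#' linearized endogenous buffering with capacity kappaB, Michaelis-Menten
#' plasma-membrane extrusion and store exchange, and a slow second
#' compartment. Resting free calcium is an exact fixed point: a constant
#' leak influx balancing the basal pump and store fluxes is computed at
#' construction time.
#'
#' @slot gTotal total sensor concentration (uM)
#' @slot aCa total calcium added per action potential before buffering (uM)
#' @slot kappaB endogenous buffer capacity (dimensionless, ~40 for a
#'   cerebellar granule cell)
#' @slot pumpVmax,pumpKm extrusion Michaelis-Menten constants (uM/s, uM)
#' @slot storeInVmax,storeInKm,storeOutVmax,storeOutKm store exchange
#'   Michaelis-Menten constants (uM/s, uM)
#' @slot storeCaBasal resting store calcium (uM, cytosol-volume units)
#' @slot slowFrac slow-compartment volume fraction (0 <= f < 1)
#' @slot slowK main-slow exchange rate (1/s)
#' @slot caBasal resting free calcium (uM)
#' @slot f0 absolute baseline fluorescence (arbitrary units)
#' @slot sigma observation noise SD (dF/F units)
#' @exportClass CellParams
setClass("CellParams",
  representation(gTotal = "numeric", aCa = "numeric", kappaB = "numeric",
                 pumpVmax = "numeric", pumpKm = "numeric",
                 storeInVmax = "numeric", storeInKm = "numeric",
                 storeOutVmax = "numeric", storeOutKm = "numeric",
                 storeCaBasal = "numeric",
                 slowFrac = "numeric", slowK = "numeric",
                 caBasal = "numeric", f0 = "numeric", sigma = "numeric"))

setValidity("CellParams", function(object) {
  v <- c(object@gTotal, object@aCa, object@kappaB, object@pumpVmax,
         object@pumpKm, object@storeInVmax, object@storeInKm,
         object@storeOutVmax, object@storeOutKm, object@storeCaBasal,
         object@slowFrac, object@slowK, object@caBasal, object@f0,
         object@sigma)
  if (any(!is.finite(v)) || any(v < 0))
    return("all cell parameters must be finite and nonnegative")
  if (object@slowFrac >= 1) return("slowFrac must be in [0, 1)")
  if (object@caBasal <= 0) return("caBasal must be > 0")
  TRUE
})

#' Construct cell parameters
#'
#' @param gTotal sensor concentration (uM); @param aCa calcium per spike
#'   before buffering (uM); @param kappaB buffer capacity; @param pumpVmax
#'   extrusion Vmax (uM/s); @param pumpKm extrusion Km (uM);
#'   @param storeInVmax,storeInKm,storeOutVmax,storeOutKm store exchange
#'   constants; @param storeCaBasal resting store calcium (uM);
#'   @param slowFrac slow-compartment volume fraction; @param slowK exchange
#'   rate (1/s); @param caBasal resting free calcium (uM); @param f0 baseline
#'   fluorescence; @param sigma observation noise SD (dF/F)
#' @return a \linkS4class{CellParams}
#' @export
CellParams <- function(gTotal = 20, aCa = 20, kappaB = 40,
                       pumpVmax = 1500, pumpKm = 0.5,
                       storeInVmax = 0, storeInKm = 0.5,
                       storeOutVmax = 0, storeOutKm = 50,
                       storeCaBasal = 50,
                       slowFrac = 0.1, slowK = 2,
                       caBasal = 0.05, f0 = 1, sigma = 0) {
  new("CellParams", gTotal = gTotal, aCa = aCa, kappaB = kappaB,
      pumpVmax = pumpVmax, pumpKm = pumpKm,
      storeInVmax = storeInVmax, storeInKm = storeInKm,
      storeOutVmax = storeOutVmax, storeOutKm = storeOutKm,
      storeCaBasal = storeCaBasal, slowFrac = slowFrac, slowK = slowK,
      caBasal = caBasal, f0 = f0, sigma = sigma)
}

#' Instantaneous state of the bouton compartment model
#'
#' @slot caFree free calcium in the main compartment (uM)
#' @slot caSlow free calcium in the slow compartment (uM)
#' @slot bCa endogenous-buffer-bound calcium (uM)
#' @slot caStore store calcium (uM, cytosol-volume units)
#' @slot sensor joint sensor occupancy
#' @exportClass CellState
setClass("CellState",
  representation(caFree = "numeric", caSlow = "numeric", bCa = "numeric",
                 caStore = "numeric", sensor = "SensorState"))

setValidity("CellState", function(object) {
  v <- c(object@caFree, object@caSlow, object@bCa, object@caStore)
  if (any(!is.finite(v)) || any(v < 0))
    return("calcium pools must be finite and nonnegative")
  TRUE
})

#' Construct a cell state
#' @param caFree,caSlow,bCa,caStore calcium pools (uM)
#' @param sensor a \linkS4class{SensorState}
#' @return a \linkS4class{CellState}
#' @export
CellState <- function(caFree, caSlow, bCa, caStore, sensor) {
  new("CellState", caFree = caFree, caSlow = caSlow, bCa = bCa,
      caStore = caStore, sensor = sensor)
}

#' A sorted train of spike times
#'
#' @slot times strictly increasing, nonnegative spike times (s)
#' @exportClass SpikeTrain
setClass("SpikeTrain", representation(times = "numeric"))

setValidity("SpikeTrain", function(object) {
  t <- object@times
  if (length(t) == 0L) return(TRUE)
  if (any(!is.finite(t))) return("spike times must be finite")
  if (any(t < 0)) return("spike times must be nonnegative")
  if (is.unsorted(t, strictly = TRUE))
    return("spike times must be strictly increasing")
  TRUE
})

#' Construct a spike train
#' @param times numeric vector of spike times in seconds
#' @return a \linkS4class{SpikeTrain}
#' @export
SpikeTrain <- function(times = numeric(0)) {
  new("SpikeTrain", times = as.numeric(times))
}

#' A uniformly sampled fluorescence time series
#'
#' @slot time sample times (s), uniform grid
#' @slot dff dF/F (or normalized fluorescence) values
#' @slot rate sampling rate (Hz)
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
  representation(time = "numeric", dff = "numeric", rate = "numeric"))

setValidity("FluorescenceTrace", function(object) {
  if (length(object@time) != length(object@dff))
    return("time and dff must have equal length")
  if (object@rate <= 0) return("rate must be > 0")
  if (length(object@time) > 1L) {
    dt <- diff(object@time)
    if (any(abs(dt - 1 / object@rate) > 1e-6 * max(1 / object@rate, 1)))
      return("sampling must be uniform at the declared rate")
  }
  TRUE
})

#' Construct a fluorescence trace
#' @param time sample times (s); if missing, built from \code{rate}
#' @param dff dF/F values
#' @param rate sampling rate (Hz)
#' @return a \linkS4class{FluorescenceTrace}
#' @export
FluorescenceTrace <- function(dff, rate, time = NULL) {
  if (is.null(time)) time <- (seq_along(dff) - 1) / rate
  new("FluorescenceTrace", time = as.numeric(time), dff = as.numeric(dff),
      rate = as.numeric(rate))
}

#' Configuration of the sequential Monte Carlo sampler
#'
#' @slot nParticles number of particles (>= 2)
#' @slot nIterations number of particle-Gibbs iterations
#' @slot binDt bin width (s); NA means the trace's sample interval
#' @slot priors named list of prior specifications
#' @slot proposalScales named list of Metropolis proposal scales
#' @slot seed integer RNG seed
#' @slot generativeModel "biophysical" or "linear_ar"
#' @exportClass InferenceConfig
setClass("InferenceConfig",
  representation(nParticles = "integer", nIterations = "integer",
                 binDt = "numeric", priors = "list",
                 proposalScales = "list", seed = "integer",
                 generativeModel = "character"))

setValidity("InferenceConfig", function(object) {
  if (object@nParticles < 2L) return("nParticles must be >= 2")
  if (object@nIterations < 1L) return("nIterations must be >= 1")
  if (!object@generativeModel %in% c("biophysical", "linear_ar"))
    return("generativeModel must be 'biophysical' or 'linear_ar'")
  TRUE
})

#' Posterior summary from the particle Gibbs sampler
#'
#' @slot spikeProb per-bin posterior spike probability
#' @slot mapSpikes MAP spike train
#' @slot paramSamples per-iteration parameter draws (data.frame)
#' @slot logPost per-iteration joint log-density
#' @slot config configuration echo (list)
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
  representation(spikeProb = "numeric", mapSpikes = "SpikeTrain",
                 paramSamples = "data.frame", logPost = "numeric",
                 config = "list"))

setValidity("PosteriorSummary", function(object) {
  p <- object@spikeProb
  if (length(p) && (any(p < -1e-12) || any(p > 1 + 1e-12)))
    return("spikeProb must lie in [0, 1]")
  TRUE
})

#' Synthetic-trace preset
#'
#' Presets emulate the simulated ground-truth regimes: an excitatory cell
#' (10 Hz Poisson spiking) and an inhibitory cell (30 Hz Poisson, calcium
#' influx per spike halved, dynamic range Rf - 1 halved).
#'
#' @slot name preset label
#' @slot rate Poisson spike rate (Hz)
#' @slot duration trace duration (s)
#' @slot sampleRate sampling rate (Hz)
#' @slot sigma white observation noise SD (dF/F)
#' @slot driftAmp baseline drift SD (dF/F)
#' @slot driftTau baseline drift timescale (s)
#' @slot refractory absolute refractory period (s)
#' @slot cellOverrides named list of CellParams overrides
#' @exportClass TracePreset
setClass("TracePreset",
  representation(name = "character", rate = "numeric", duration = "numeric",
                 sampleRate = "numeric", sigma = "numeric",
                 driftAmp = "numeric", driftTau = "numeric",
                 refractory = "numeric", cellOverrides = "list"))

setValidity("TracePreset", function(object) {
  if (object@rate < 0) return("rate must be >= 0")
  if (object@duration <= 0 || object@sampleRate <= 0)
    return("duration and sampleRate must be > 0")
  TRUE
})

#' Multi-exponential fit result
#'
#' @slot amplitudes component amplitudes
#' @slot taus time constants (s), ascending
#' @slot offset additive offset
#' @slot residualRms root-mean-square residual
#' @exportClass ExpFit
setClass("ExpFit",
  representation(amplitudes = "numeric", taus = "numeric",
                 offset = "numeric", residualRms = "numeric"))

setValidity("ExpFit", function(object) {
  if (any(object@taus <= 0)) return("taus must be strictly positive")
  if (is.unsorted(object@taus)) return("taus must be ascending")
  if (length(object@amplitudes) != length(object@taus))
    return("amplitudes and taus must have equal length")
  TRUE
})

#' Hill-equation fit result
#'
#' @slot kd half-saturation (uM)
#' @slot hill Hill coefficient
#' @slot fMin,fMax fitted response bounds
#' @exportClass HillFit
setClass("HillFit",
  representation(kd = "numeric", hill = "numeric",
                 fMin = "numeric", fMax = "numeric"))

setValidity("HillFit", function(object) {
  if (object@kd <= 0 || object@hill <= 0)
    return("kd and hill must be > 0")
  TRUE
})

#' Result of assignment-based spike matching
#'
#' @slot pairs data.frame with columns imputed, truth, offset (s)
#' @slot nTp,nFp,nFn true-positive, false-positive, false-negative counts
#' @slot maxDt matching window (s)
#' @exportClass MatchResult
setClass("MatchResult",
  representation(pairs = "data.frame", nTp = "integer", nFp = "integer",
                 nFn = "integer", maxDt = "numeric"))

setValidity("MatchResult", function(object) {
  if (object@nTp != nrow(object@pairs))
    return("nTp must equal the number of matched pairs")
  if (nrow(object@pairs) &&
      any(abs(object@pairs$offset) > object@maxDt + 1e-12))
    return("all matched offsets must lie within maxDt")
  TRUE
})
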