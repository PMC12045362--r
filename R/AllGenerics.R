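#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#' @param object an S4 object from this package
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setMethod("occupancy", "SensorState", function(object) object@occupancy)
#' @rdname accessors
#' @export
setMethod("occupancy", "CellState", function(object) object@sensor@occupancy)

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("spikeTimes", "PosteriorSummary",
          function(object) object@mapSpikes@times)

#' @rdname accessors
#' @export
setGeneric("dffValues", function(object) standardGeneric("dffValues"))
#' @rdname accessors
#' @export
setMethod("dffValues", "FluorescenceTrace", function(object) object@dff)

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setMethod("sampleTimes", "FluorescenceTrace", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "FluorescenceTrace", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("spikeProb", function(object) standardGeneric("spikeProb"))
#' @rdname accessors
#' @export
setMethod("spikeProb", "PosteriorSummary", function(object) object@spikeProb)

#' @rdname accessors
#' @export
setGeneric("paramSamples", function(object) standardGeneric("paramSamples"))
#' @rdname accessors
#' @export
setMethod("paramSamples", "PosteriorSummary",
          function(object) object@paramSamples)

#' @rdname accessors
#' @export
setGeneric("dynamicRange", function(object) standardGeneric("dynamicRange"))
#' @rdname accessors
#' @export
setMethod("dynamicRange", "SensorModel", function(object) object@Rf)

setMethod("show", "SensorModel", function(object) {
  cat("SensorModel:", object@name, "\n")
  cat(sprintf("  Rf = %.3g, nCaPerLobe = %d\n", object@Rf, object@nCaPerLobe))
  for (lab in c("N", "C")) {
    l <- slot(object, paste0("lobe", lab))
    cat(sprintf(
      "  %s-lobe: koffCa %.4g /s, Ka %.4g uM, H %.3g, konPep %.4g /s, koffPep %.4g /s\n",
      lab, l@koffCa, l@Ka, l@hill, l@konPep, l@koffPep))
  }
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "SensorState", function(object) {
  cat("SensorState (9 joint lobe configurations)\n")
  print(round(object@occupancy, 6))
})

setMethod("show", "CellParams", function(object) {
  cat("CellParams (bouton compartment)\n")
  cat(sprintf("  gTotal %.3g uM, aCa %.3g uM/AP, kappaB %.3g, caBasal %.3g uM\n",
              object@gTotal, object@aCa, object@kappaB, object@caBasal))
  cat(sprintf("  pump Vmax %.3g uM/s Km %.3g uM; slowFrac %.3g slowK %.3g /s; sigma %.3g\n",
              object@pumpVmax, object@pumpKm, object@slowFrac, object@slowK,
              object@sigma))
})

setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("FluorescenceTrace: %d samples at %.6g Hz (%.4g s)\n",
              length(object@dff), object@rate,
              length(object@dff) / object@rate))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes", length(object@times)))
  if (length(object@times))
    cat(sprintf(" in [%.4g, %.4g] s", min(object@times), max(object@times)))
  cat("\n")
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf(
    "PosteriorSummary: %d bins, %d MAP spikes, %d parameter samples\n",
    length(object@spikeProb), length(object@mapSpikes@times),
    nrow(object@paramSamples)))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d, FP %d, FN %d (window %.3g ms)\n",
              object@nTp, object@nFp, object@nFn, 1000 * object@maxDt))
})
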