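#' @include AllClasses.R
NULL

#' Read a fluorescence trace from CSV
#'
#' Expects a header with columns \code{time_s} and \code{dff} (or
#' \code{f_norm}). Sampling must be uniform within a relative jitter of
#' 1e-6 of the sample interval.
#'
#' @param path CSV file path
#' @return a \linkS4class{FluorescenceTrace}
#' @export
readTrace <- function(path) {
  d <- tryCatch(read.csv(path), error = function(e)
    stop("could not parse trace file '", path, "': ", conditionMessage(e)))
  if (!nrow(d)) stop("trace file '", path, "' contains no samples")
  valCol <- intersect(c("dff", "f_norm"), names(d))
  if (!"time_s" %in% names(d) || !length(valCol))
    stop("trace file must have header columns time_s and dff (or f_norm)")
  t <- d$time_s; y <- d[[valCol[1]]]
  if (length(t) > 1) {
    dt <- diff(t)
    bad <- which(abs(dt - dt[1]) > 1e-6 * abs(dt[1]))
    if (length(bad))
      stop("non-uniform sampling at row ", bad[1] + 1,
           " (interval ", signif(dt[bad[1]], 6), " vs ",
           signif(dt[1], 6), ")")
    if (dt[1] <= 0) stop("time column must be strictly increasing")
  }
  rate <- if (length(t) > 1) 1 / mean(diff(t)) else 1
  FluorescenceTrace(dff = y, rate = rate, time = t)
}

#' Write a fluorescence trace to CSV
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param path output CSV path
#' @param valueName value column name ("dff" or "f_norm")
#' @return invisibly, the path
#' @export
writeTrace <- function(trace, path, valueName = "dff") {
  d <- data.frame(time_s = formatC(trace@time, digits = 17, format = "g"),
                  value = formatC(trace@dff, digits = 17, format = "g"))
  names(d)[2] <- valueName
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike times from a text file
#'
#' One time (seconds) per line, or a single-column CSV (optionally headed
#' \code{time_s}). Unsorted input is sorted with a warning; duplicate or
#' negative times are rejected.
#'
#' @param path file path
#' @return a \linkS4class{SpikeTrain}
#' @export
readSpikes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1]))))
    lines <- lines[-1]  # header
  if (!length(lines)) return(SpikeTrain())
  t <- suppressWarnings(as.numeric(lines))
  if (any(is.na(t))) stop("non-numeric spike time in '", path, "'")
  if (any(t < 0)) stop("negative spike times in '", path, "'")
  if (anyDuplicated(t)) stop("duplicate spike times in '", path, "'")
  if (is.unsorted(t)) {
    warning("spike times were unsorted; sorting", call. = FALSE)
    t <- sort(t)
  }
  SpikeTrain(t)
}

#' Write spike times to a text file
#'
#' @param spikes a \linkS4class{SpikeTrain}
#' @param path output path (one time in seconds per line, with header)
#' @return invisibly, the path
#' @export
writeSpikes <- function(spikes, path) {
  writeLines(c("time_s",
               formatC(spikeTimes(spikes), digits = 17, format = "g")),
             path)
  invisible(path)
}

#' Serialize a sensor model to JSON
#'
#' Units are recorded explicitly; provenance metadata from the sensor's
#' \code{meta} slot is embedded.
#'
#' @param sensor a \linkS4class{SensorModel}
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeSensorJSON <- function(sensor, path) {
  l <- list(
    name = sensor@name,
    units = list(rates = "1/s", Ka = "uM"),
    Rf = sensor@Rf,
    nCaPerLobe = sensor@nCaPerLobe,
    lobeN = list(koffCa = sensor@lobeN@koffCa, Ka = sensor@lobeN@Ka,
                 hill = sensor@lobeN@hill, konPep = sensor@lobeN@konPep,
                 koffPep = sensor@lobeN@koffPep),
    lobeC = list(koffCa = sensor@lobeC@koffCa, Ka = sensor@lobeC@Ka,
                 hill = sensor@lobeC@hill, konPep = sensor@lobeC@konPep,
                 koffPep = sensor@lobeC@koffPep),
    meta = sensor@meta)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sensor model from JSON
#'
#' @param path JSON path written by \code{\link{writeSensorJSON}}
#' @return a \linkS4class{SensorModel}
#' @export
readSensorJSON <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  SensorModel(
    lobeN = do.call(LobeKinetics, l$lobeN),
    lobeC = do.call(LobeKinetics, l$lobeC),
    Rf = l$Rf, nCaPerLobe = as.integer(l$nCaPerLobe),
    name = l$name, meta = as.list(l$meta))
}

#' Load a shipped default sensor parameter set
#'
#' Parameter sets for GCaMP6f, jGCaMP7f and jGCaMP8f produced by the
#' package's calibration pipeline are installed under
#' \code{extdata/sensors}; each JSON carries provenance metadata (fit loss,
#' seed).
#'
#' @param name "jGCaMP8f", "GCaMP6f" or "jGCaMP7f" (case-insensitive)
#' @return a \linkS4class{SensorModel}
#' @export
defaultSensor <- function(name = c("jGCaMP8f", "GCaMP6f", "jGCaMP7f")) {
  name <- match.arg(name)
  path <- system.file("extdata", "sensors",
                      paste0(tolower(name), ".json"), package = "biospike")
  if (!nzchar(path)) stop("no shipped parameter set for '", name, "'")
  readSensorJSON(path)
}

#' Default granule-cell bouton parameters
#'
#' The standard bouton calcium-handling parameter set used with the shipped
#' sensors (buffer capacity ~40, resting calcium 50 nM), as produced by the
#' calibration pipeline.
#'
#' @return a \linkS4class{CellParams}
#' @export
defaultCellParams <- function() {
  path <- system.file("extdata", "sensors", "bouton.json",
                      package = "biospike")
  if (!nzchar(path)) return(CellParams())
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(CellParams, l$params)
}

#' Write cell parameters to JSON
#' @param cell a \linkS4class{CellParams}
#' @param path output path
#' @param meta provenance list
#' @return invisibly, the path
#' @export
writeCellJSON <- function(cell, path, meta = list()) {
  nm <- slotNames("CellParams")
  params <- lapply(setNames(nm, nm), function(s) slot(cell, s))
  jsonlite::write_json(list(params = params, meta = meta), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Adapter for external ground-truth benchmark epochs (optional)
#'
#' Reads paired fluorescence/spike epochs from a directory laid out as
#' \code{<dir>/<epoch>.trace.csv} + \code{<dir>/<epoch>.spikes.csv} (the
#' formats of \code{\link{readTrace}} and \code{\link{readSpikes}}). The
#' external jGCaMP8f ground-truth benchmark can be converted to this layout
#' for evaluation; the package does not depend on or ship those data.
#'
#' @param dir directory containing paired epoch files
#' @return list of \code{list(trace, spikes, name)} per epoch
#' @export
readGroundTruthEpochs <- function(dir) {
  if (!dir.exists(dir))
    stop("ground-truth directory '", dir, "' does not exist; ",
         "this adapter requires an externally obtained benchmark dataset ",
         "converted to <epoch>.trace.csv / <epoch>.spikes.csv pairs")
  tfiles <- list.files(dir, pattern = "\\.trace\\.csv$", full.names = TRUE)
  if (!length(tfiles))
    stop("no *.trace.csv epochs found under '", dir, "'")
  lapply(tfiles, function(tf) {
    sf <- sub("\\.trace\\.csv$", ".spikes.csv", tf)
    if (!file.exists(sf)) stop("missing spike file for epoch '", tf, "'")
    list(trace = readTrace(tf), spikes = readSpikes(sf),
         name = sub("\\.trace\\.csv$", "", basename(tf)))
  })
}
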