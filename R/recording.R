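#' Construct an MEA recording
#'
#' @param voltage numeric matrix, electrodes x samples, microvolts
#' @param grid [ElectrodeGrid-class]
#' @param samplingRate Hz
#' @param meta optional metadata list
#' @return an [MEARecording-class]
#' @export
meaRecording <- function(voltage, grid, samplingRate, meta = list()) {
  new("MEARecording", grid = grid, samplingRate = samplingRate,
      voltage = voltage, meta = meta)
}

#' @describeIn voltage recording method
#' @export
setMethod("voltage", "MEARecording", function(x) x@voltage)

#' @describeIn samplingRate recording method
#' @export
setMethod("samplingRate", "MEARecording", function(x) x@samplingRate)

#' @describeIn electrodeGrid recording method
#' @export
setMethod("electrodeGrid", "MEARecording", function(x) x@grid)

#' @describeIn duration recording method
#' @export
setMethod("duration", "MEARecording",
          function(x) ncol(x@voltage) / x@samplingRate)

#' @describeIn nElectrodes recording method
#' @export
setMethod("nElectrodes", "MEARecording", function(x) nrow(x@voltage))

#' @describeIn electrodePositions recording method
#' @export
setMethod("electrodePositions", "MEARecording",
          function(x) electrodePositions(x@grid))

setMethod("show", "MEARecording", function(object) {
  cat(sprintf(
    "MEARecording: %d electrodes x %d samples (%.4g s at %g Hz)\n",
    nrow(object@voltage), ncol(object@voltage),
    duration(object), object@samplingRate))
  show(object@grid)
})

# Container schema: a serialized named list with fields
#   voltage (numeric matrix), grid (nRows, nCols, pitch, electrodeSide),
#   meta (sampling_rate, duration_s, extra...)
# The reader validates the schema and names any missing field.

recordingToBundle <- function(rec) {
  g <- rec@grid
  list(
    voltage = rec@voltage,
    grid = list(nRows = g@nRows, nCols = g@nCols, pitch = g@pitch,
                electrodeSide = g@electrodeSide),
    meta = c(list(sampling_rate = rec@samplingRate,
                  duration_s = duration(rec)), rec@meta)
  )
}

bundleToRecording <- function(b, path = "<bundle>") {
  need <- function(x, field, where) {
    if (is.null(x))
      stop(sprintf("malformed recording container '%s': missing field '%s'",
                   path, where))
    x
  }
  v <- need(b$voltage, , "voltage")
  g <- need(b$grid, , "grid")
  m <- need(b$meta, , "meta")
  rate <- need(m$sampling_rate, , "meta/sampling_rate")
  grid <- makeGrid(need(g$nRows, , "grid/nRows"),
                   need(g$nCols, , "grid/nCols"),
                   need(g$pitch, , "grid/pitch"),
                   need(g$electrodeSide, , "grid/electrodeSide"))
  extra <- m[setdiff(names(m), c("sampling_rate", "duration_s"))]
  meaRecording(v, grid, rate, meta = extra)
}

#' Write / read a recording container
#'
#' One self-describing binary file per recording holding the voltage
#' matrix, grid descriptor and metadata. The round trip preserves voltages
#' bit-exactly. `readRecording()` also accepts a plain named list with the
#' same `voltage`/`grid`/`meta` fields, so bundles produced by other tools
#' can be adapted without rewriting files. A malformed container raises a
#' format error naming the missing field.
#'
#' @param rec an [MEARecording-class]
#' @param path file path
#' @return `readRecording`: an [MEARecording-class]
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "MEARecording"))
  saveRDS(recordingToBundle(rec), path, compress = "gzip")
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  b <- if (is.list(path)) path else readRDS(path)
  if (!is.list(b))
    stop(sprintf("malformed recording container '%s': not a field bundle",
                 if (is.character(path)) path else "<bundle>"))
  bundleToRecording(b, if (is.character(path)) path else "<bundle>")
}

#' Export spike trains as CSV
#'
#' Two-column CSV (id, time_s), one row per spike, times in seconds.
#'
#' @param trains named list of numeric spike-time vectors
#' @param path output file
#' @export
writeSpikesCsv <- function(trains, path) {
  ids <- rep(names(trains), lengths(trains))
  df <- data.frame(id = ids, time_s = unlist(trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpikesCsv
#' @export
readSpikesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df$time_s, factor(df$id, levels = unique(df$id)))
}

#' Export / import region masks as JSON
#' @param masks list of [RegionMask-class]
#' @param path file path
#' @export
writeMasksJson <- function(masks, path) {
  x <- lapply(masks, function(m) list(label = m@label,
                                      electrodes = m@electrodes))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMasksJson
#' @export
readMasksJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(x)), function(i)
    regionMask(x$label[i], unlist(x$electrodes[i])))
}
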