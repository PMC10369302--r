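#' Detect LFP propagation events in a region
#'
#' Activity is assessed on the rectified amplitude envelope (centered
#' running maximum of |v| over `envelopeMs`, bridging the zero crossings
#' of oscillatory events): an event spans contiguous sample frames in
#' which at least `minElectrodes` region electrodes have an envelope at
#' or above `ampThreshold`; events are separated by at least one quiet
#' frame. The default threshold is 5 x the per-electrode quiet-period SD,
#' estimated from the `quietWindow` seconds of the trace.
#'
#' @param rec an [MEARecording-class], LFP-band (detrended, optionally
#'   band-filtered)
#' @param region a [RegionMask-class] or integer electrode indices
#' @param ampThreshold amplitude threshold, uV; NULL (default) uses
#'   5 x quiet-period SD per electrode
#' @param minElectrodes minimum simultaneously active electrodes
#'   (default 3)
#' @param quietWindow c(start, end) s used for the automatic threshold
#' @param envelopeMs envelope half-window, ms (default 10; 0 disables)
#' @return data.frame (start, end, nFrames, nElectrodes, areaMm2,
#'   velocityMm2S); one row per event, empty when quiet. `nElectrodes`
#'   counts distinct electrodes active at any point of the event.
#' @export
detectLfpEvents <- function(rec, region, ampThreshold = NULL,
                            minElectrodes = 3L, quietWindow = NULL,
                            envelopeMs = 10) {
  electrodes <- if (is(region, "RegionMask")) region@electrodes
                else as.integer(region)
  v <- voltage(rec)[electrodes, , drop = FALSE]
  fs <- samplingRate(rec)
  if (is.null(ampThreshold)) {
    qw <- if (is.null(quietWindow)) c(0, min(0.5, ncol(v) / fs))
          else quietWindow
    j <- max(1L, floor(qw[1] * fs) + 1L):min(ncol(v), ceiling(qw[2] * fs))
    ampThreshold <- 5 * apply(v[, j, drop = FALSE], 1L, stats::sd)
  }
  env <- abs(v)
  h <- as.integer(round(envelopeMs / 1000 * fs))
  if (h > 0) {
    shifted <- lapply(-h:h, function(s) {
      m <- env
      if (s > 0) m[, (1 + s):ncol(m) - s] <- env[, (1 + s):ncol(m)]
      if (s < 0) m[, (1 - s):ncol(m)] <- env[, (1 - s):ncol(m) + s]
      m
    })
    env <- Reduce(pmax, shifted)
  }
  act <- env >= ampThreshold             # recycles per-electrode thresholds
  nAct <- colSums(act)
  on <- nAct >= minElectrodes
  empty <- data.frame(start = numeric(), end = numeric(),
                      nFrames = integer(), nElectrodes = integer(),
                      areaMm2 = numeric(), velocityMm2S = numeric())
  if (!any(on)) return(empty)
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  grid <- electrodeGrid(rec)
  rows <- lapply(which(r$values), function(k) {
    j <- starts[k]:ends[k]
    nd <- sum(rowSums(act[, j, drop = FALSE]) > 0L)
    durS <- length(j) / fs
    area <- propagationArea(nd, grid)
    data.frame(start = (starts[k] - 1L) / fs, end = ends[k] / fs,
               nFrames = length(j), nElectrodes = nd, areaMm2 = area,
               velocityMm2S = if (durS > 0) area / durS else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Propagated area of an electrode footprint
#'
#' Area swept by an event: the number of distinct active electrodes times
#' the lattice cell area (pitch squared), in mm^2. Setting
#' `metalArea = TRUE` uses the bare electrode metal area instead.
#'
#' @param nElectrodes distinct active electrode count
#' @param grid [ElectrodeGrid-class]
#' @param metalArea use electrode metal area instead of cell area
#' @return area, mm^2
#' @export
propagationArea <- function(nElectrodes, grid, metalArea = FALSE) {
  side <- if (metalArea) grid@electrodeSide else grid@pitch
  nElectrodes * (side * 1e-3)^2
}

#' Area and areal velocity of one event
#'
#' @param event one row of the [detectLfpEvents()] output
#' @param grid [ElectrodeGrid-class]
#' @return c(areaMm2, velocityMm2S); velocity NA (flagged) for
#'   zero-duration events
#' @export
propagationAreaVelocity <- function(event, grid) {
  area <- propagationArea(event$nElectrodes, grid)
  durS <- event$end - event$start
  c(areaMm2 = area,
    velocityMm2S = if (durS > 0) area / durS else NA_real_)
}

#' Inter-region event synchrony
#'
#' Counts event pairs across two regions whose onsets differ by at most
#' `windowMs`, for every region pair.
#'
#' @param eventsByRegion named list of event data.frames (as returned by
#'   [detectLfpEvents()]), one per region
#' @param windowMs onset coincidence window, ms (default 50)
#' @return data.frame (regionA, regionB, nPairs)
#' @export
regionSynchrony <- function(eventsByRegion, windowMs = 50) {
  regions <- names(eventsByRegion)
  out <- list()
  w <- windowMs / 1000
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (j <= i) next
      a <- eventsByRegion[[i]]$start
      b <- eventsByRegion[[j]]$start
      n <- if (length(a) && length(b))
        sum(vapply(a, function(t0) any(abs(b - t0) <= w), TRUE))
        else 0L
      out[[length(out) + 1L]] <-
        data.frame(regionA = regions[i], regionB = regions[j],
                   nPairs = as.integer(n))
    }
  }
  do.call(rbind, out)
}

#' Export LFP events as CSV
#' @param eventsByRegion named list of event data.frames
#' @param path output CSV
#' @export
writeLfpEventsCsv <- function(eventsByRegion, path) {
  rows <- lapply(names(eventsByRegion), function(r) {
    ev <- eventsByRegion[[r]]
    if (!nrow(ev)) return(NULL)
    cbind(region = r, ev)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
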