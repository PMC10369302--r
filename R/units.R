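#' Threshold spike detection
#'
#' Detects one spike per threshold excursion of a preprocessed (detrended,
#' spike-band) trace: wherever |v| crosses the threshold, the spike is
#' timestamped at the extremum of the excursion's leading lobe (the lobe
#' carrying the first crossing — for a biphasic extracellular spike, the
#' sink), so the timestamp does not jump to the rebound lobe when filter
#' overshoot makes it the larger one; crossings within `deadTimeMs` of
#' the previous spike are suppressed.
#'
#' @param x numeric filtered voltage series (uV)
#' @param rate sampling rate, Hz
#' @param threshold detection threshold, uV (> 0; applied as +/-)
#' @param deadTimeMs dead time, ms (default 1)
#' @return numeric vector of spike times, s (possibly empty)
#' @export
detectSpikes <- function(x, rate, threshold, deadTimeMs = 1) {
  if (threshold <= 0) stop("threshold must be positive")
  over <- which(abs(x) >= threshold)
  if (!length(over)) return(numeric())
  gap <- max(1L, as.integer(round(deadTimeMs / 1000 * rate)))
  grp <- cumsum(c(1L, as.integer(diff(over) > gap)))
  peaks <- vapply(split(over, grp), function(ix) {
    s0 <- sign(x[ix[1L]])
    flip <- which(sign(x[ix]) == -s0)
    lobe <- if (length(flip)) ix[seq_len(flip[1L] - 1L)] else ix
    lobe[which.max(abs(x[lobe]))]
  }, integer(1))
  times <- (unname(peaks) - 1L) / rate
  # enforce dead time between consecutive accepted spikes
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= deadTimeMs / 1000 - 1e-12) {
      keep[i] <- TRUE; last <- times[i]
    }
  }
  times[keep]
}

#' Cosine similarity between two vectors
#'
#' u . v / (||u|| ||v||); by convention 0 when either vector is all zero,
#' so silent electrodes never merge.
#'
#' @param u,v numeric vectors of equal length
#' @return value in [-1, 1]
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Sparse 1 ms firing histograms: per electrode, bin ids and counts.
binSparse <- function(train, binS) {
  if (!length(train)) return(list(bins = integer(), counts = integer()))
  b <- as.integer(floor(train / binS)) + 1L
  tb <- table(b)
  list(bins = as.integer(names(tb)), counts = as.integer(tb))
}

sparseCosine <- function(a, b) {
  na <- sqrt(sum(a$counts^2)); nb <- sqrt(sum(b$counts^2))
  if (na == 0 || nb == 0) return(0)
  m <- match(a$bins, b$bins)
  hit <- !is.na(m)
  if (!any(hit)) return(0)
  sum(a$counts[hit] * b$counts[m[hit]]) / (na * nb)
}

#' Merge electrodes into single-neuron units
#'
#' Computes the 1 ms-bin firing histogram of every electrode, links
#' adjacent electrodes (8-neighborhood) whose histogram cosine similarity
#' is at least `simThreshold`, and takes connected components of the
#' resulting graph as neurons. The unit spike train is the union of member
#' spike times deduplicated within the histogram bin; the centroid is the
#' mean of member electrode positions. Electrodes without spikes form no
#' units.
#'
#' @param trains list of spike-time vectors (s), one per electrode, in
#'   electrode-index order
#' @param grid [ElectrodeGrid-class]
#' @param duration recording duration, s
#' @param binMs histogram bin, ms (default 1)
#' @param simThreshold similarity threshold (default 0.3)
#' @return a [NeuronUnitSet-class]
#' @export
mergeSomata <- function(trains, grid, duration, binMs = 1,
                        simThreshold = 0.3) {
  nE <- nElectrodes(grid)
  stopifnot(length(trains) == nE)
  binS <- binMs / 1000
  hists <- lapply(trains, binSparse, binS = binS)
  active <- which(vapply(trains, length, 0L) > 0L)
  edges <- list()
  for (e in active) {
    nb <- gridNeighbors(grid, e)
    nb <- nb[nb > e]            # undirected, each pair once
    for (f in nb) {
      if (!length(trains[[f]])) next
      if (sparseCosine(hists[[e]], hists[[f]]) >= simThreshold)
        edges[[length(edges) + 1L]] <- c(e, f)
    }
  }
  g <- igraph::make_empty_graph(n = nE, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.integer(t(do.call(rbind, edges))))
  comp <- igraph::components(g)$membership
  units <- list()
  pos <- electrodePositions(grid)
  for (cid in unique(comp[active])) {
    memb <- sort(which(comp == cid))
    allSpk <- sort(unlist(trains[memb], use.names = FALSE))
    spk <- dedupeWithin(allSpk, binS)
    if (!length(spk)) next
    units[[length(units) + 1L]] <- list(
      id = sprintf("unit%03d", length(units) + 1L),
      electrodes = memb,
      centroid = colMeans(pos[memb, , drop = FALSE]),
      spikes = spk,
      rate = length(spk) / duration)
  }
  new("NeuronUnitSet", units = units, duration = duration, grid = grid)
}

# collapse spikes closer than win (s) to the first of each run
dedupeWithin <- function(x, win) {
  if (length(x) <= 1L) return(x)
  keep <- c(TRUE, diff(x) > win)
  out <- numeric(0)
  last <- -Inf
  for (t in x) {
    if (t - last > win) { out <- c(out, t); last <- t }
  }
  out
}

#' Build a unit set directly from known memberships and trains
#'
#' Convenience constructor used when ground-truth or externally sorted
#' units are available.
#'
#' @param trains named list of spike trains (s)
#' @param memberships named list of member-electrode index vectors
#' @param grid [ElectrodeGrid-class]
#' @param duration s
#' @return a [NeuronUnitSet-class]
#' @export
unitSetFromTrains <- function(trains, memberships, grid, duration) {
  pos <- electrodePositions(grid)
  units <- lapply(names(trains), function(id) {
    memb <- memberships[[id]]
    list(id = id, electrodes = as.integer(memb),
         centroid = colMeans(pos[memb, , drop = FALSE]),
         spikes = sort(trains[[id]]),
         rate = length(trains[[id]]) / duration)
  })
  new("NeuronUnitSet", units = units, duration = duration, grid = grid)
}

#' @describeIn nUnits unit-set method
#' @export
setMethod("nUnits", "NeuronUnitSet", function(x) length(x@units))

#' @describeIn spikeTrains unit-set method
#' @export
setMethod("spikeTrains", "NeuronUnitSet", function(x) {
  out <- lapply(x@units, `[[`, "spikes")
  names(out) <- vapply(x@units, `[[`, "", "id")
  out
})

#' @describeIn centroids unit-set method
#' @export
setMethod("centroids", "NeuronUnitSet", function(x) {
  m <- do.call(rbind, lapply(x@units, `[[`, "centroid"))
  rownames(m) <- vapply(x@units, `[[`, "", "id")
  m
})

#' @describeIn duration unit-set method
#' @export
setMethod("duration", "NeuronUnitSet", function(x) x@duration)

setMethod("show", "NeuronUnitSet", function(object) {
  cat(sprintf("NeuronUnitSet: %d units over %.4g s on a %d x %d grid\n",
              nUnits(object), object@duration,
              object@grid@nRows, object@grid@nCols))
})

#' Neighborhood waveform-similarity map (soma detection)
#'
#' For every interior electrode, the mean cosine similarity between its
#' full-trace waveform and those of its eight neighbors; border electrodes
#' are undefined (NA). Somata spanning several electrodes show up as local
#' maxima because neighboring electrodes see the same action potentials.
#'
#' @param rec an [MEARecording-class] (or plain electrodes x samples matrix
#'   with `grid` supplied)
#' @param grid optional [ElectrodeGrid-class] when `rec` is a matrix
#' @return numeric vector, one value per electrode (NA on borders)
#' @export
somaSimilarityMap <- function(rec, grid = NULL) {
  if (is(rec, "MEARecording")) {
    v <- voltage(rec); grid <- electrodeGrid(rec)
  } else v <- rec
  if (grid@nRows < 3L || grid@nCols < 3L) {
    warning("grid smaller than 3 x 3: no interior electrodes")
    return(rep(NA_real_, nElectrodes(grid)))
  }
  out <- rep(NA_real_, nElectrodes(grid))
  rc <- cbind((seq_len(nElectrodes(grid)) - 1L) %/% grid@nCols + 1L,
              (seq_len(nElectrodes(grid)) - 1L) %% grid@nCols + 1L)
  interior <- which(rc[, 1] > 1L & rc[, 1] < grid@nRows &
                    rc[, 2] > 1L & rc[, 2] < grid@nCols)
  norms <- sqrt(rowSums(v^2))
  for (e in interior) {
    nb <- gridNeighbors(grid, e)
    sims <- vapply(nb, function(f) {
      if (norms[e] == 0 || norms[f] == 0) return(0)
      sum(v[e, ] * v[f, ]) / (norms[e] * norms[f])
    }, 0)
    out[e] <- mean(sims)
  }
  out
}

#' Call soma electrode groups from a similarity map
#'
#' Electrodes above mean + `k` SD of the (defined) map, grouped by grid
#' connectivity.
#'
#' @param simMap output of [somaSimilarityMap()]
#' @param grid [ElectrodeGrid-class]
#' @param k SD multiplier (default 2)
#' @return list of integer electrode groups
#' @export
callSomataFromMap <- function(simMap, grid, k = 2) {
  vals <- simMap[!is.na(simMap)]
  if (!length(vals)) return(list())
  thr <- mean(vals) + k * stats::sd(vals)
  sel <- which(!is.na(simMap) & simMap >= thr)
  if (!length(sel)) return(list())
  connectedGroups(sel, grid)
}

connectedGroups <- function(electrodes, grid) {
  sub <- igraph::make_empty_graph(n = length(electrodes), directed = FALSE)
  idxOf <- stats::setNames(seq_along(electrodes), electrodes)
  edges <- integer(0)
  for (i in seq_along(electrodes)) {
    nb <- gridNeighbors(grid, electrodes[i])
    nb <- nb[nb %in% electrodes & nb > electrodes[i]]
    for (f in nb) edges <- c(edges, i, idxOf[[as.character(f)]])
  }
  if (length(edges)) sub <- igraph::add_edges(sub, edges)
  comp <- igraph::components(sub)$membership
  lapply(unique(comp), function(cid) sort(electrodes[comp == cid]))
}

#' Firing-frequency band table per unit
#'
#' Per-unit firing rate, frequency-band label over the bands
#' {0, (0,0.1), [0.1,0.5), [0.5,1), [1,2), [2,5), [5,10), >=10 Hz},
#' electrodes-per-soma count, plus aggregate band percentages and the
#' electrodes-per-soma histogram (1-electrode bins).
#'
#' @param units a [NeuronUnitSet-class]
#' @return list with `perUnit` data.frame (id, rate, band, nElectrodes),
#'   `bandTable` data.frame (band, n, percent), `electrodeHist` table
#' @export
unitFiringStats <- function(units) {
  rates <- vapply(units@units, `[[`, 0, "rate")
  nel <- vapply(units@units, function(u) length(u$electrodes), 0L)
  ids <- vapply(units@units, `[[`, "", "id")
  band <- firingBand(rates)
  perUnit <- data.frame(id = ids, rate = rates, band = band,
                        nElectrodes = nel)
  lv <- firingBandLevels()
  n <- as.integer(table(factor(band, levels = lv)))
  bandTable <- data.frame(band = lv, n = n,
                          percent = 100 * n / max(1L, length(rates)))
  list(perUnit = perUnit, bandTable = bandTable,
       electrodeHist = table(nel))
}

firingBandLevels <- function() {
  c("0", "(0,0.1)", "[0.1,0.5)", "[0.5,1)", "[1,2)", "[2,5)", "[5,10)",
    ">=10")
}

#' @rdname unitFiringStats
#' @param rates numeric firing rates, Hz
#' @export
firingBand <- function(rates) {
  lv <- firingBandLevels()
  out <- character(length(rates))
  out[rates == 0] <- lv[1]
  out[rates > 0 & rates < 0.1] <- lv[2]
  out[rates >= 0.1 & rates < 0.5] <- lv[3]
  out[rates >= 0.5 & rates < 1] <- lv[4]
  out[rates >= 1 & rates < 2] <- lv[5]
  out[rates >= 2 & rates < 5] <- lv[6]
  out[rates >= 5 & rates < 10] <- lv[7]
  out[rates >= 10] <- lv[8]
  out
}

#' Band percentages from counts
#'
#' The percentage formula used by the band table: 100 * n / total.
#'
#' @param n count in a band
#' @param total total number of units
#' @return percentage
#' @export
bandPercent <- function(n, total) 100 * n / total

#' Electrode-level activity summary
#'
#' Totals over per-electrode spike trains restricted to a contact mask:
#' total spikes, active-electrode count (>= 1 spike), active fraction of
#' the mask (%), mean rate per active electrode (Hz), and the per-bin
#' firing-electrode-count histogram (number of distinct electrodes firing
#' in each time bin; 5 ms bins for synchrony profiles, 100 ms for
#' rasters).
#'
#' @param trains list of spike trains (s), one per electrode
#' @param contactMask integer electrode indices in contact (default: all)
#' @param duration s
#' @param binMs histogram bin, ms (default 5)
#' @return list with `totalSpikes`, `activeElectrodes`, `maskSize`,
#'   `activePercent`, `meanRateActive`, `electrodesPerBin` (integer
#'   vector), `binMs`
#' @export
activitySummary <- function(trains, contactMask = seq_along(trains),
                            duration, binMs = 5) {
  sub <- trains[contactMask]
  counts <- vapply(sub, length, 0L)
  total <- sum(counts)
  active <- sum(counts > 0L)
  nBins <- max(1L, as.integer(ceiling(duration * 1000 / binMs)))
  perBin <- integer(nBins)
  binS <- binMs / 1000
  for (tr in sub) {
    if (!length(tr)) next
    b <- unique(pmin(nBins, as.integer(floor(tr / binS)) + 1L))
    perBin[b] <- perBin[b] + 1L
  }
  list(totalSpikes = total,
       activeElectrodes = active,
       maskSize = length(sub),
       activePercent = 100 * active / max(1L, length(sub)),
       meanRateActive = if (active) total / active / duration else 0,
       electrodesPerBin = perBin,
       binMs = binMs)
}

#' Active-electrode percentage from printed counts
#' @param nActive,nTotal electrode counts
#' @return percentage
#' @export
activePercent <- function(nActive, nTotal) 100 * nActive / nTotal

#' Export units as JSON + spike CSV
#' @param units a [NeuronUnitSet-class]
#' @param jsonPath,csvPath output paths
#' @export
writeUnitsJson <- function(units, jsonPath, csvPath = NULL) {
  x <- lapply(units@units, function(u)
    list(id = u$id, electrodes = u$electrodes,
         centroid_um = unname(u$centroid), rate_hz = u$rate))
  jsonlite::write_json(x, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath)) writeSpikesCsv(spikeTrains(units), csvPath)
  invisible(jsonPath)
}
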