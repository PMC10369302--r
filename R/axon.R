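#' Synchronous-firing counts per electrode
#'
#' Conduction-path electrode selection: the recording is cut into
#' `windowS` windows; in each window, every electrode's maximum-|v| time
#' is located, and an electrode scores one synchronous firing when at
#' least `minNeighbors` of its 8 lattice neighbors have their maximum
#' within `dtMs` of its own. Counts accumulate over all windows; axonal
#' electrodes (repeatedly co-active with their neighbors) accumulate high
#' counts while noise electrodes rarely coincide.
#'
#' @param rec an [MEARecording-class], spike-band filtered
#' @param windowS analysis window, s (default 0.05)
#' @param dtMs coincidence tolerance, ms (default 1)
#' @param minNeighbors required coincident neighbors (default 4)
#' @return integer vector of counts per electrode
#' @export
countSynchronousFirings <- function(rec, windowS = 0.05, dtMs = 1,
                                    minNeighbors = 4L) {
  v <- voltage(rec); fs <- samplingRate(rec)
  grid <- electrodeGrid(rec)
  nE <- nrow(v); nS <- ncol(v)
  win <- max(1L, as.integer(round(windowS * fs)))
  nW <- nS %/% win
  counts <- integer(nE)
  adj <- gridAdjacency(grid)
  dt <- dtMs / 1000
  for (w in seq_len(nW)) {
    j <- ((w - 1L) * win + 1L):(w * win)
    tmax <- (j[1] - 1L + max.col(abs(v[, j, drop = FALSE]),
                                 ties.method = "first") - 1L) / fs
    for (e in seq_len(nE)) {
      nb <- adj[[e]]
      if (sum(abs(tmax[nb] - tmax[e]) < dt) >= minNeighbors)
        counts[e] <- counts[e] + 1L
    }
  }
  counts
}

#' Identify the soma locus from an amplitude map
#'
#' Over a selected electrode set (e.g. electrodes with many synchronous
#' firings), takes the largest connected component whose maximum |v|
#' reaches `ampThreshold`, computes its center of gravity, and detects the
#' soma spike train on the component's peak electrode at the soma
#' detection threshold with 1 ms dead time.
#'
#' @param rec an [MEARecording-class]
#' @param selected integer electrode indices to consider (default: all)
#' @param ampThreshold soma amplitude threshold, uV (default 200)
#' @param spikeThreshold detection threshold for the soma train, uV
#'   (default 200)
#' @return list with `electrodes`, `centroid` (um), `peakElectrode`,
#'   `peakAmplitude` (uV), `train` (s), and `secondary` (other
#'   above-threshold components, possibly empty)
#' @export
identifySoma <- function(rec, selected = seq_len(nElectrodes(rec)),
                         ampThreshold = 200, spikeThreshold = 200) {
  v <- voltage(rec); grid <- electrodeGrid(rec)
  maxAmp <- apply(abs(v[selected, , drop = FALSE]), 1L, max)
  hot <- selected[maxAmp >= ampThreshold]
  if (!length(hot))
    stop("soma not found: no electrode reaches the amplitude threshold")
  groups <- connectedGroups(hot, grid)
  sizes <- lengths(groups)
  main <- groups[[which.max(sizes)]]
  secondary <- groups[order(sizes, decreasing = TRUE)][-1]
  pos <- electrodePositions(grid)
  peakE <- main[which.max(apply(abs(v[main, , drop = FALSE]), 1L, max))]
  train <- detectSpikes(v[peakE, ], samplingRate(rec), spikeThreshold)
  list(electrodes = main,
       centroid = colMeans(pos[main, , drop = FALSE]),
       peakElectrode = peakE,
       peakAmplitude = max(abs(v[peakE, ])),
       train = train,
       secondary = secondary)
}

#' Spike-triggered average voltage map
#'
#' Mean voltage in [-halfWindowMs, +halfWindowMs] around each trigger,
#' per electrode. Triggers clipped by the recording edges are skipped and
#' counted.
#'
#' @param rec an [MEARecording-class]
#' @param train trigger times, s
#' @param halfWindowMs half window, ms (default 3)
#' @return list with `avg` (electrodes x samples matrix), `times` (ms,
#'   relative to trigger), `nTriggers` used, `nSkipped`
#' @export
spikeTriggeredAverage <- function(rec, train, halfWindowMs = 3) {
  v <- voltage(rec); fs <- samplingRate(rec)
  w <- as.integer(round(halfWindowMs / 1000 * fs))
  idx <- as.integer(round(train * fs)) + 1L
  ok <- idx - w >= 1L & idx + w <= ncol(v)
  if (!any(ok)) stop("no trigger fully inside the recording")
  acc <- matrix(0, nrow(v), 2L * w + 1L)
  for (i in idx[ok]) acc <- acc + v[, (i - w):(i + w)]
  list(avg = acc / sum(ok),
       times = ((-w):w) / fs * 1000,
       nTriggers = sum(ok), nSkipped = sum(!ok))
}

# first time (ms) each electrode's trace crosses below -k * sigma, or NA;
# sigma estimated robustly per electrode from the map itself
electrodeFireTimes <- function(avg, timesMs, k = 5, sigma = NULL,
                               side = c("forward", "backward")) {
  side <- match.arg(side)
  if (is.null(sigma)) {
    sigma <- apply(avg, 1L, stats::mad)
    sigma[sigma <= 0] <- stats::mad(avg)
  }
  sel <- if (side == "forward") timesMs > 0 else timesMs < 0
  tt <- timesMs[sel]
  sub <- avg[, sel, drop = FALSE]
  out <- rep(NA_real_, nrow(avg))
  for (e in seq_len(nrow(avg))) {
    hit <- which(sub[e, ] < -k * sigma[e])
    if (length(hit)) out[e] <- tt[hit[1L]]
  }
  out
}

#' Track the propagation front of an averaged map
#'
#' Starting at the soma center of gravity, advances in `stepMs` frames:
#' in each frame (forward: t > 0; backward: t < 0, scanned away from the
#' soma spike) the firing electrode farthest from the soma centroid is
#' selected, and the cumulative straight-line distance between
#' consecutive selected electrodes is accumulated as the conduction
#' distance. An electrode "fires" at its first crossing below -k x its
#' noise level on the averaged map; frames with no firing electrode are
#' skipped. Soma-component electrodes are excluded from the front.
#'
#' @param sta output of [spikeTriggeredAverage()]
#' @param grid [ElectrodeGrid-class]
#' @param somaCentroid (x, y) um
#' @param stepMs frame step, ms (default 0.1)
#' @param k noise multiplier of the fire criterion (default 5)
#' @param exclude electrode indices excluded from the front (the soma
#'   locus), default none
#' @return list with `forward` and `backward` [ConductionPath-class]
#' @export
trackPropagationFront <- function(sta, grid, somaCentroid, stepMs = 0.1,
                                  k = 5, exclude = integer()) {
  pos <- electrodePositions(grid)
  dSoma <- sqrt((pos[, 1] - somaCentroid[1])^2 +
                (pos[, 2] - somaCentroid[2])^2)
  build <- function(side) {
    ft <- electrodeFireTimes(sta$avg, sta$times, k = k, side = side)
    ft[exclude] <- NA_real_
    cand <- which(!is.na(ft))
    if (!length(cand))
      return(emptyPath(side))
    tAbs <- abs(ft[cand])
    frame <- floor(tAbs / stepMs + 1e-9)
    sel <- integer(0); selT <- numeric(0)
    for (fr in sort(unique(frame))) {
      inFr <- cand[frame == fr]
      far <- inFr[which.max(dSoma[inFr])]
      sel <- c(sel, far)
      selT <- c(selT, (fr + 0.5) * stepMs)
    }
    seg <- sqrt(diff(c(somaCentroid[1], pos[sel, 1]))^2 +
                diff(c(somaCentroid[2], pos[sel, 2]))^2)
    cum <- unname(cummax(cumsum(seg))) * 1e-3   # mm, non-decreasing
    fit <- if (length(sel) >= 3L) fitVelocity(selT, cum)
           else list(velocity = NA_real_, r2 = NA_real_)
    ep <- if (length(sel) >= 2L)
      (cum[length(cum)] - cum[1]) / (selT[length(selT)] - selT[1])
      else NA_real_
    new("ConductionPath", direction = side,
        times = if (side == "forward") selT else -selT,
        electrodes = sel, cumDist = cum,
        velocity = fit$velocity, r2 = fit$r2,
        endpointVelocity = ep)
  }
  list(forward = build("forward"), backward = build("backward"))
}

emptyPath <- function(side) {
  new("ConductionPath", direction = side, times = numeric(),
      electrodes = integer(), cumDist = numeric(),
      velocity = NA_real_, r2 = NA_real_, endpointVelocity = NA_real_)
}

fitVelocity <- function(tMs, dMm) {
  if (stats::sd(tMs) == 0) stop("degenerate time spread: cannot fit")
  fit <- stats::lm(dMm ~ tMs)
  res <- stats::residuals(fit)
  sst <- sum((dMm - mean(dMm))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(velocity = unname(stats::coef(fit)[2L]),  # mm/ms = m/s
       r2 = r2)
}

#' Least-squares conduction velocity of a path
#'
#' Ordinary least squares of cumulative distance (mm) against |time|
#' (ms); the slope is the conduction velocity in m/s. Also reports the
#' endpoint ratio total distance / total time, the arithmetic the printed
#' distance/time figures correspond to.
#'
#' @param path a [ConductionPath-class], or a list/data.frame with
#'   elements `times` (ms) and `cumDist` (mm)
#' @return list with `velocity` (m/s), `r2`, `endpointVelocity`,
#'   `totalDistanceMm`, `totalTimeMs`
#' @export
fitConductionVelocity <- function(path) {
  if (is(path, "ConductionPath")) {
    tMs <- abs(path@times); dMm <- path@cumDist
  } else {
    tMs <- abs(path$times); dMm <- path$cumDist
  }
  if (length(tMs) < 3L) stop("need at least 3 points to fit")
  fit <- fitVelocity(tMs, dMm)
  totD <- dMm[length(dMm)]       # cumulative distance from the soma
  totT <- tMs[length(tMs)]
  list(velocity = fit$velocity, r2 = fit$r2,
       endpointVelocity = endpointVelocity(totD, totT),
       totalDistanceMm = totD, totalTimeMs = totT)
}

#' Endpoint conduction velocity from printed distance/time
#'
#' distance (mm) / time (ms) = velocity in m/s; e.g. 2.44 mm over 2.1 ms
#' gives 1.16 m/s.
#'
#' @param distanceMm conduction distance, mm
#' @param timeMs conduction time, ms
#' @return velocity, m/s
#' @export
endpointVelocity <- function(distanceMm, timeMs) {
  if (timeMs <= 0) stop("conduction time must be positive")
  distanceMm / timeMs
}

#' Backpropagation statistics over individual firings
#'
#' A trigger counts as backpropagating when at least `minElectrodes` of
#' the path electrodes fire (trace below -k x noise SD) in the pre-soma
#' window [-windowMs, 0) in distal-to-proximal order (fire time
#' decreasing with distance from the soma, Pearson r < 0). The
#' probability is 100 x nBackprop / nTriggers. Ordering is assessed by
#' the Spearman rank correlation between fire time and distance, which
#' must be at most `orderRho` (near-monotone distal-to-proximal).
#'
#' @param rec an [MEARecording-class]
#' @param train soma spike times, s
#' @param pathElectrodes path electrode indices (distal ordering taken
#'   from distance to `somaCentroid`)
#' @param somaCentroid (x, y) um
#' @param windowMs pre-soma window, ms (default 3)
#' @param k noise multiplier (default 4)
#' @param minElectrodes required firing path electrodes (default 5)
#' @param orderRho Spearman correlation ceiling for distal-to-proximal
#'   ordering (default -0.9)
#' @return list with `nBackprop`, `nTriggers`, `probabilityPercent`
#' @export
backpropagationStats <- function(rec, train, pathElectrodes, somaCentroid,
                                 windowMs = 3, k = 4, minElectrodes = 5L,
                                 orderRho = -0.9) {
  v <- voltage(rec); fs <- samplingRate(rec)
  grid <- electrodeGrid(rec)
  pos <- electrodePositions(grid)
  d <- sqrt((pos[pathElectrodes, 1] - somaCentroid[1])^2 +
            (pos[pathElectrodes, 2] - somaCentroid[2])^2)
  w <- as.integer(round(windowMs / 1000 * fs))
  sigma <- apply(v[pathElectrodes, , drop = FALSE], 1L, stats::mad)
  sigma[sigma <= 0] <- max(sigma, 1e-6)
  idx <- as.integer(round(train * fs)) + 1L
  idx <- idx[idx - w >= 1L & idx <= ncol(v)]
  nBp <- 0L
  for (i in idx) {
    j <- (i - w):(i - 1L)
    tMs <- (j - i) / fs * 1000
    fired <- rep(NA_real_, length(pathElectrodes))
    snip <- v[pathElectrodes, j, drop = FALSE]
    for (e in seq_along(pathElectrodes)) {
      hit <- which(snip[e, ] < -k * sigma[e])
      if (length(hit)) fired[e] <- tMs[hit[1L]]
    }
    ok <- !is.na(fired)
    if (sum(ok) >= minElectrodes &&
        stats::sd(fired[ok]) > 0 && stats::sd(d[ok]) > 0 &&
        suppressWarnings(stats::cor(fired[ok], d[ok],
                                    method = "spearman")) <= orderRho)
      nBp <- nBp + 1L
  }
  list(nBackprop = nBp, nTriggers = length(idx),
       probabilityPercent = backpropProbability(nBp, length(idx)))
}

#' Backpropagation probability from counts
#' @param nBackprop,nTriggers counts
#' @return percentage
#' @export
backpropProbability <- function(nBackprop, nTriggers) {
  100 * nBackprop / nTriggers
}

#' Velocity change report, vehicle-normalized
#'
#' 100 x velocity / baseline per timepoint, averaged across wells with
#' SEM.
#'
#' @param velocities numeric matrix wells x timepoints (column 1 =
#'   baseline) or a vector for a single well
#' @return data.frame (timepoint, meanPercent, semPercent)
#' @export
velocityChangeReport <- function(velocities) {
  if (is.null(dim(velocities))) velocities <- matrix(velocities, nrow = 1)
  if (any(velocities[, 1] <= 0)) stop("baseline velocity must be positive")
  pct <- 100 * velocities / velocities[, 1]
  tp <- colnames(velocities)
  if (is.null(tp)) tp <- paste0("t", seq_len(ncol(velocities)))
  data.frame(
    timepoint = tp,
    meanPercent = colMeans(pct),
    semPercent = apply(pct, 2L, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0))
}

setMethod("show", "ConductionPath", function(object) {
  cat(sprintf(
    "ConductionPath (%s): %d frames, %.3g mm, velocity %.3g m/s (R2 %.3g)\n",
    object@direction, length(object@times),
    if (length(object@cumDist)) max(object@cumDist) else 0,
    object@velocity, object@r2))
})

#' Export a conduction path as CSV
#' @param path a [ConductionPath-class]
#' @param grid [ElectrodeGrid-class]
#' @param file output path
#' @export
writePathCsv <- function(path, grid, file) {
  pos <- electrodePositions(grid)
  df <- data.frame(frame_time_ms = path@times,
                   electrode = path@electrodes,
                   x_um = pos[path@electrodes, 1],
                   y_um = pos[path@electrodes, 2],
                   cumdist_mm = path@cumDist)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
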