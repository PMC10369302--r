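#' Network-burst detection (four-step ISI method)
#'
#' Step 1: pool and sort spikes across units. Step 2: group maximal runs
#' of consecutive spikes whose inter-spike interval is <= `isiThMs`.
#' Step 3: merge groups whose separation is strictly less than `ibiThMs`.
#' Step 4: keep groups with at least `minSpikes` spikes from at least
#' `minUnits` distinct units.
#'
#' @param trains named list of unit spike trains (s)
#' @param isiThMs within-burst ISI threshold, ms (default 100)
#' @param ibiThMs inter-burst merge threshold, ms (default 300)
#' @param minSpikes minimum spikes per burst (default 5)
#' @param minUnits minimum participating units (default 2)
#' @return data.frame (start, end, nSpikes, nUnits), one row per network
#'   burst, empty when none
#' @export
detectNetworkBursts <- function(trains, isiThMs = 100, ibiThMs = 300,
                                minSpikes = 5L, minUnits = 2L) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      nSpikes = integer(), nUnits = integer())
  times <- unlist(trains, use.names = FALSE)
  if (!length(times)) return(empty)
  src <- rep(seq_along(trains), lengths(trains))
  o <- order(times)
  times <- times[o]; src <- src[o]
  isiTh <- isiThMs / 1000; ibiTh <- ibiThMs / 1000
  grp <- cumsum(c(1L, as.integer(diff(times) > isiTh)))
  bounds <- do.call(rbind, lapply(split(seq_along(times), grp), range))
  # merge groups separated by < ibiTh (strict)
  merged <- list(bounds[1, ])
  if (nrow(bounds) > 1) {
    for (i in 2:nrow(bounds)) {
      prev <- merged[[length(merged)]]
      if (times[bounds[i, 1]] - times[prev[2]] < ibiTh)
        merged[[length(merged)]] <- c(prev[1], bounds[i, 2])
      else merged[[length(merged) + 1L]] <- bounds[i, ]
    }
  }
  rows <- lapply(merged, function(b) {
    ix <- b[1]:b[2]
    data.frame(start = times[b[1]], end = times[b[2]],
               nSpikes = length(ix), nUnits = length(unique(src[ix])))
  })
  out <- do.call(rbind, rows)
  out <- out[out$nSpikes >= minSpikes & out$nUnits >= minUnits, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Poisson-Surprise statistic
#'
#' S = -ln P(N >= n) for N ~ Poisson(r T): the surprise of observing at
#' least `n` spikes in a window of length `T` from a unit firing at mean
#' rate `r`. Natural log; evaluated through the numerically stable
#' upper-tail log probability.
#'
#' @param n observed spike count (>= 1)
#' @param T window length, s
#' @param r mean firing rate, Hz
#' @return surprise value S (vectorized over `n`)
#' @export
poissonSurprise <- function(n, T, r) {
  if (any(n < 1)) stop("n must be >= 1")
  if (T <= 0 || r <= 0) stop("T and r must be positive")
  -stats::ppois(n - 1, lambda = r * T, lower.tail = FALSE, log.p = TRUE)
}

#' Poisson-Surprise single-neuron burst detection
#'
#' Splits the train into candidate groups: maximal runs of spikes whose
#' ISIs are strictly below the train's mean ISI. Within each group, the
#' contiguous sub-window maximizing the surprise S (at the unit's overall
#' mean rate) is retained if S >= `sThreshold` and it holds at least
#' `minSpikes` spikes.
#'
#' @param train sorted spike times, s
#' @param duration recording duration, s (for the mean rate)
#' @param sThreshold surprise threshold (natural log units, default 10)
#' @param minSpikes minimum spikes per burst (default 3)
#' @return data.frame (start, end, nSpikes, surprise); empty when the
#'   train has fewer than 3 spikes or nothing passes
#' @export
detectPsBursts <- function(train, duration, sThreshold = 10,
                           minSpikes = 3L) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      nSpikes = integer(), surprise = numeric())
  if (length(train) < 3L) return(empty)
  r <- length(train) / duration
  isi <- diff(train)
  meanIsi <- mean(isi)
  short <- isi < meanIsi
  if (!any(short)) return(empty)
  # maximal runs of consecutive short ISIs -> spike index ranges
  rl <- rle(short)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  out <- list()
  for (k in which(rl$values)) {
    i1 <- starts[k]; i2 <- ends[k] + 1L     # spikes i1..i2
    best <- maxSurpriseWindow(train[i1:i2], r, minSpikes)
    if (!is.null(best) && best$surprise >= sThreshold)
      out[[length(out) + 1L]] <- best
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, lapply(out, as.data.frame))
  rownames(res) <- NULL
  res
}

# exhaustive contiguous sub-window search (groups are short in practice)
maxSurpriseWindow <- function(spk, r, minSpikes) {
  m <- length(spk)
  if (m < minSpikes) return(NULL)
  best <- NULL
  for (i in 1:(m - minSpikes + 1L)) {
    for (j in (i + minSpikes - 1L):m) {
      Tw <- spk[j] - spk[i]
      if (Tw <= 0) next
      s <- poissonSurprise(j - i + 1L, Tw, r)
      if (is.null(best) || s > best$surprise)
        best <- list(start = spk[i], end = spk[j],
                     nSpikes = j - i + 1L, surprise = s)
    }
  }
  best
}

#' Burst parameter table (12 parameters)
#'
#' Computes, for one condition, the network-analysis parameter set (or its
#' single-neuron twin when fed single-neuron bursts): total spikes (TS),
#' number of bursts, inter-burst interval (mean), burst duration (mean),
#' spikes per burst (mean), max frequency in a burst (MF: the peak bin
#' count of the intra-burst firing histogram at `mfBinMs`, expressed in
#' Hz), inter-MF interval (IMFI: interval between the MF-bin centers of
#' consecutive bursts), and the coefficients of variation (SD/mean) of
#' interval, duration, spikes, MF and IMFI. Entries that need bursts are
#' NA when there are none; CVs are NA with fewer than 2 bursts.
#'
#' @param bursts data.frame with columns start, end (s) as returned by
#'   [detectNetworkBursts()] or [detectPsBursts()]
#' @param trains list (or single vector) of spike trains contributing to
#'   the condition; pooled for TS and the intra-burst histograms
#' @param duration s
#' @param mfBinMs intra-burst histogram bin, ms (default 10)
#' @return named numeric vector of the 12 parameters (NA where
#'   incomputable)
#' @export
burstParameterTable <- function(bursts, trains, duration, mfBinMs = 10) {
  if (!is.list(trains)) trains <- list(trains)
  pooled <- sort(unlist(trains, use.names = FALSE))
  nb <- nrow(bursts)
  cv <- function(x) if (length(x) >= 2) stats::sd(x) / mean(x) else NA_real_
  na <- NA_real_
  if (nb == 0L) {
    return(c(TS = length(pooled), nBursts = 0, IBI = na, duration = na,
             spikesPerBurst = na, MF = na, IMFI = na,
             cvIBI = na, cvDuration = na, cvSpikes = na, cvMF = na,
             cvIMFI = na))
  }
  binS <- mfBinMs / 1000
  mf <- numeric(nb); mfTime <- numeric(nb); spb <- numeric(nb)
  for (i in seq_len(nb)) {
    inB <- pooled[pooled >= bursts$start[i] & pooled <= bursts$end[i]]
    spb[i] <- length(inB)
    edges <- seq(bursts$start[i], bursts$end[i] + binS, by = binS)
    h <- graphics::hist(inB, breaks = edges, plot = FALSE)
    top <- which.max(h$counts)
    mf[i] <- max(h$counts) / binS          # peak bin count as a rate, Hz
    mfTime[i] <- h$mids[top]
  }
  ibi <- if (nb >= 2) diff(bursts$start) else numeric()
  imfi <- if (nb >= 2) diff(mfTime) else numeric()
  dur <- bursts$end - bursts$start
  c(TS = length(pooled),
    nBursts = nb,
    IBI = if (length(ibi)) mean(ibi) else na,
    duration = mean(dur),
    spikesPerBurst = mean(spb),
    MF = mean(mf),
    IMFI = if (length(imfi)) mean(imfi) else na,
    cvIBI = cv(ibi),
    cvDuration = cv(dur),
    cvSpikes = cv(spb),
    cvMF = cv(mf),
    cvIMFI = cv(imfi))
}

#' Vehicle normalization of a parameter table
#'
#' 100 x condition / vehicle per parameter; NA where the vehicle value is
#' zero or either entry is NA (flagged incomputable).
#'
#' @param tableCondition,tableVehicle named numeric vectors with matching
#'   names (from [burstParameterTable()])
#' @return named numeric vector of percentages
#' @export
normalizeToVehicle <- function(tableCondition, tableVehicle) {
  if (!identical(names(tableCondition), names(tableVehicle)))
    stop("parameter sets do not match")
  out <- 100 * tableCondition / tableVehicle
  out[!is.finite(out)] <- NA_real_
  out[tableVehicle == 0] <- NA_real_
  out
}

#' Tidy export of burst parameter tables
#' @param tables named list of named numeric vectors (one per condition)
#' @param vehicle name of the vehicle condition in `tables`
#' @param path output CSV path
#' @return the tidy data.frame, invisibly written to `path`
#' @export
writeBurstTableCsv <- function(tables, vehicle, path) {
  veh <- tables[[vehicle]]
  rows <- lapply(names(tables), function(cond) {
    tab <- tables[[cond]]
    norm <- normalizeToVehicle(tab, veh)
    data.frame(condition = cond, parameter = names(tab),
               value = unname(tab), normalized_pct = unname(norm),
               na_flag = is.na(tab) | is.na(norm))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
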