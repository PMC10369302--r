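#' Count synchronized spikes
#'
#' Directional coincidence count: the number of target spikes in the
#' half-open window (t, t + window] summed over every reference spike t.
#' Simultaneous spikes are not counted (deduplication happens upstream in
#' unit merging).
#'
#' @param ref,target sorted spike-time vectors, s
#' @param window coincidence window, s (default 0.1)
#' @return integer count
#' @export
countSynchronizedSpikes <- function(ref, target, window = 0.1) {
  if (!length(ref) || !length(target)) return(0L)
  hi <- findInterval(ref + window, target)
  lo <- findInterval(ref, target)        # strictly-after via half-open (t, t+w]
  as.integer(sum(hi - lo))
}

#' ISI-shuffle surrogate spike trains
#'
#' Each surrogate keeps the first spike time and randomly permutes the
#' multiset of inter-spike intervals, preserving the spike count, the ISI
#' distribution, and the span (last spike time) exactly.
#'
#' @param train sorted spike times, s
#' @param n number of surrogates (default 100)
#' @return list of `n` sorted spike-time vectors
#' @export
makeIsiSurrogates <- function(train, n = 100L) {
  if (length(train) < 2L) {
    warning("fewer than 2 spikes: surrogates identical to input")
    return(replicate(n, train, simplify = FALSE))
  }
  isi <- diff(train)
  lapply(seq_len(n), function(i)
    cumsum(c(train[1L], sample(isi))))
}

#' Surrogate Z-score for one directed pair
#'
#' Z = (real - mean(surrogate)) / sd(surrogate) where the surrogate
#' synchronized-spike counts come from ISI-shuffled target trains (the
#' reference train stays fixed; set `shuffleBoth` to shuffle both sides).
#' When the surrogate SD is zero, Z is 0 if the real count equals the
#' surrogate value and NA (undefined, never infinite) otherwise.
#'
#' @param ref,target sorted spike trains, s
#' @param nSurrogates number of surrogates (default 100)
#' @param window coincidence window, s (default 0.1)
#' @param shuffleBoth also shuffle the reference train (default FALSE)
#' @return list with `z`, `real`, `surrogateMean`, `surrogateSD`
#' @export
connectionZScore <- function(ref, target, nSurrogates = 100L,
                             window = 0.1, shuffleBoth = FALSE) {
  real <- countSynchronizedSpikes(ref, target, window)
  tgtS <- makeIsiSurrogates(target, nSurrogates)
  refS <- if (shuffleBoth) makeIsiSurrogates(ref, nSurrogates)
          else replicate(nSurrogates, ref, simplify = FALSE)
  counts <- vapply(seq_len(nSurrogates), function(i)
    countSynchronizedSpikes(refS[[i]], tgtS[[i]], window), 0L)
  mu <- mean(counts); sdv <- stats::sd(counts)
  z <- if (sdv > 0) (real - mu) / sdv
       else if (real == mu) 0 else NA_real_
  list(z = z, real = real, surrogateMean = mu, surrogateSD = sdv)
}

#' Full surrogate connectivity analysis
#'
#' Computes the directed synchronized-spike count, surrogate mean/SD and
#' Z score for every ordered unit pair, and classifies each pair as
#' excitatory (Z >= 3), inhibitory (Z <= -3) or none. The diagonal is
#' left NA. The RNG seed is recorded for reproducibility.
#'
#' @param units a [NeuronUnitSet-class] or named list of spike trains
#' @param nSurrogates surrogates per pair (default 100)
#' @param window coincidence window, s (default 0.1)
#' @param zThreshold classification threshold (default 3)
#' @param strict use strict inequality (> / <) instead of >= / <=
#' @param seed integer RNG seed (default 1)
#' @return a [ConnectivityResult-class]
#' @export
connectivityAnalysis <- function(units, nSurrogates = 100L, window = 0.1,
                                 zThreshold = 3, strict = FALSE,
                                 seed = 1L) {
  trains <- if (is(units, "NeuronUnitSet")) spikeTrains(units) else units
  n <- length(trains)
  if (n < 2L) stop("need at least 2 units")
  ids <- names(trains)
  set.seed(seed)
  real <- mu <- sdv <- z <- matrix(NA_real_, n, n,
                                   dimnames = list(ids, ids))
  for (j in seq_len(n)) {              # shuffle each target once per pair set
    for (i in seq_len(n)) {
      if (i == j) next
      res <- connectionZScore(trains[[i]], trains[[j]], nSurrogates, window)
      real[i, j] <- res$real; mu[i, j] <- res$surrogateMean
      sdv[i, j] <- res$surrogateSD; z[i, j] <- res$z
    }
  }
  cls <- classifyZ(z, zThreshold, strict)
  new("ConnectivityResult", unitIds = ids, real = real,
      surrogateMean = mu, surrogateSD = sdv, z = z, classification = cls,
      nSurrogates = as.integer(nSurrogates), window = window,
      seed = as.integer(seed))
}

classifyZ <- function(z, zThreshold = 3, strict = FALSE) {
  cls <- matrix("none", nrow(z), ncol(z), dimnames = dimnames(z))
  exc <- if (strict) z > zThreshold else z >= zThreshold
  inh <- if (strict) z < -zThreshold else z <= -zThreshold
  cls[which(exc)] <- "excitatory"
  cls[which(inh)] <- "inhibitory"
  cls[is.na(z)] <- NA_character_
  diag(cls) <- NA_character_
  cls
}

#' @describeIn zMatrix connectivity method
#' @export
setMethod("zMatrix", "ConnectivityResult", function(x) x@z)

setMethod("show", "ConnectivityResult", function(object) {
  s <- classifySummary(object@z)
  cat(sprintf(
    "ConnectivityResult: %d units, %d surrogates, window %g ms\n  excitatory %.1f%%, inhibitory %.1f%% of ordered pairs\n",
    length(object@unitIds), object@nSurrogates, 1000 * object@window,
    s["excitatoryPercent"], s["inhibitoryPercent"]))
})

#' Classify a Z matrix and summarize network percentages
#'
#' Network-level percentage of ordered unit pairs with Z >= threshold
#' (excitatory) and Z <= -threshold (inhibitory); the diagonal is
#' excluded. Optionally reports deltas against a vehicle summary in
#' percentage points.
#'
#' @param z numeric Z matrix (diagonal ignored)
#' @param zThreshold threshold (default 3)
#' @param strict strict inequality flag
#' @param vehicle optional summary from a vehicle condition for deltas
#' @return named vector: excitatoryPercent, inhibitoryPercent and, with
#'   `vehicle`, deltaExcitatory / deltaInhibitory (percentage points)
#' @export
classifySummary <- function(z, zThreshold = 3, strict = FALSE,
                            vehicle = NULL) {
  off <- z[row(z) != col(z)]
  off <- off[!is.na(off)]
  nPairs <- length(off)
  exc <- if (strict) sum(off > zThreshold) else sum(off >= zThreshold)
  inh <- if (strict) sum(off < -zThreshold) else sum(off <= -zThreshold)
  out <- c(excitatoryPercent = 100 * exc / max(1L, nPairs),
           inhibitoryPercent = 100 * inh / max(1L, nPairs))
  if (!is.null(vehicle)) {
    out <- c(out,
             deltaExcitatory = unname(out["excitatoryPercent"] -
                                      vehicle["excitatoryPercent"]),
             deltaInhibitory = unname(out["inhibitoryPercent"] -
                                      vehicle["inhibitoryPercent"]))
  }
  out
}

#' Excitability connection rate (ECR)
#'
#' Per-unit percentage of possible partners with Z >= threshold:
#' 100 * |{j != i : Z_ij >= 3}| / (n - 1).
#'
#' @param zRow Z scores from one unit to all others (its own entry NA or
#'   excluded)
#' @param nUnits total number of units (>= 2)
#' @param zThreshold threshold (default 3)
#' @return percentage in [0, 100]
#' @export
ecr <- function(zRow, nUnits, zThreshold = 3) {
  if (nUnits < 2L) stop("ECR needs at least 2 units")
  100 * sum(zRow >= zThreshold, na.rm = TRUE) / (nUnits - 1L)
}

#' Per-unit ECR table for a connectivity result
#' @param result a [ConnectivityResult-class]
#' @param zThreshold threshold (default 3)
#' @return data.frame (id, ecr)
#' @export
ecrTable <- function(result, zThreshold = 3) {
  n <- length(result@unitIds)
  data.frame(id = result@unitIds,
             ecr = vapply(seq_len(n), function(i)
               ecr(result@z[i, -i], n, zThreshold), 0))
}

#' Export a connectivity result
#'
#' Z matrix and classification as CSV, the per-unit ECR table as CSV, and
#' the provenance (seed, surrogate count, window) as a JSON sidecar.
#'
#' @param result a [ConnectivityResult-class]
#' @param dir output directory (created if needed)
#' @export
writeConnectivity <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result@z, file.path(dir, "z_matrix.csv"))
  utils::write.csv(result@classification,
                   file.path(dir, "classification.csv"))
  utils::write.csv(ecrTable(result), file.path(dir, "ecr.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = result@seed, n_surrogates = result@nSurrogates,
         window_s = result@window),
    file.path(dir, "connectivity_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
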