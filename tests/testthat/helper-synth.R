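# shared fixtures and small utilities for the suite; everything is
# generated in code at test time

quietBandpass <- function(x, rate, ...) {
  suppressWarnings(spikeBandpass(x, rate, ...))
}

# one simulated axon recording per (seed, velocity), cached across tests
.fixtures <- new.env(parent = emptyenv())

axonFixture <- function(seed = 5, velocity = 1.155, backpropProb = 0.4) {
  key <- sprintf("axon_%d_%g_%g", seed, velocity, backpropProb)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateRecording(
      synthPreset("axon", seed = seed, velocity = velocity,
                  backpropProb = backpropProb))
  .fixtures[[key]]
}

# fraction of responses correctly labelled under the best one-to-one
# matching of clusters to true templates (exhaustive over permutations)
matchedAccuracy <- function(labels, truth) {
  ks <- sort(unique(truth))
  tab <- table(factor(labels, levels = seq_along(ks)),
               factor(truth, levels = ks))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_along(ks))) {
    s <- sum(vapply(seq_along(ks), function(k) tab[k, p[k]], 0))
    best <- max(best, s)
  }
  best / length(labels)
}

# spike trains per electrode for a grid of well-separated planted units:
# each member electrode records the unit's (deduplicated) train
plantedElectrodeTrains <- function(grid, nUnits, duration, seed,
                                   radiusRange = c(1, 3)) {
  set.seed(seed)
  pos <- electrodePositions(grid)
  nSide <- ceiling(sqrt(nUnits))
  margin <- radiusRange[2] + 1
  rows <- round(seq(margin, grid@nRows - margin, length.out = nSide))
  cols <- round(seq(margin, grid@nCols - margin, length.out = nSide))
  ctrIdx <- as.vector(outer(rows, cols, function(r, c)
    electrodeIndex(grid, r, c)))[seq_len(nUnits)]
  units <- lapply(seq_len(nUnits), function(i)
    unitSpec(paste0("u", i), pos[ctrIdx[i], ],
             footprintRadius = stats::runif(1, radiusRange[1],
                                            radiusRange[2]),
             firing = list(model = "poisson",
                           rate = stats::runif(1, 0.5, 3))))
  trains <- simulateSpikeTrains(units, list(), duration)
  memberships <- lapply(units, function(u)
    hdmea:::footprintElectrodes(grid, u$centroid, u$footprintRadius))
  names(memberships) <- names(trains)
  perElectrode <- rep(list(numeric()), nElectrodes(grid))
  for (i in seq_along(trains)) {
    for (e in memberships[[i]])
      perElectrode[[e]] <- sort(c(perElectrode[[e]], trains[[i]]))
  }
  list(trains = trains, memberships = memberships,
       perElectrode = perElectrode)
}

# membership Jaccard between a detected unit set and true memberships,
# matched greedily by best overlap
membershipJaccards <- function(unitSet, memberships) {
  det <- lapply(unitSet@units, `[[`, "electrodes")
  vapply(memberships, function(m) {
    best <- 0
    for (d in det) {
      j <- length(intersect(d, m)) / length(union(d, m))
      best <- max(best, j)
    }
    best
  }, 0)
}
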