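test_that("threshold detection finds planted spikes and honors dead time", {
  fs <- 5000
  expect_length(detectSpikes(rep(0, 1000), fs, 80), 0L)
  # single biphasic template above threshold: one spike at the trough
  g <- makeGrid(2, 2)
  u <- unitSpec("a", electrodePositions(g)[1, ], 0.1, 150,
                firing = list(model = "times", times = 0.1))
  v <- voltage(simulateRecording(
    synthConfig(g, 0.3, fs, noiseRms = 0, units = list(u),
                seed = 1L))$recording)
  expect_equal(detectSpikes(v[1, ], fs, 100), 0.1, tolerance = 1e-9)
  expect_error(detectSpikes(v[1, ], fs, -5), "threshold")
  # two crossings inside the dead time collapse to one spike
  x <- numeric(1000)
  x[100] <- -120; x[103] <- -90
  expect_length(detectSpikes(x, fs, 80, deadTimeMs = 1), 1L)
  x2 <- numeric(1000); x2[100] <- -120; x2[200] <- -90
  expect_length(detectSpikes(x2, fs, 80, deadTimeMs = 1), 2L)
})

test_that("detection on noisy synthetic units has high recall and 1-sample timing", {
  fs <- 5000
  g <- makeGrid(3, 3)
  set.seed(2)
  # spikes on a 20 ms lattice so no pair falls inside the dead time
  spikes <- sort(sample(seq(0.06, 9.94, by = 0.02), 40))
  u <- unitSpec("a", electrodePositions(g)[5, ], 0.1, 200,
                firing = list(model = "times", times = spikes))
  sim <- simulateRecording(synthConfig(g, 10, fs, noiseRms = 9.43,
                                       units = list(u), seed = 3L))
  x <- quietBandpass(detrendBlocks(voltage(sim$recording)[5, ]), fs)
  det <- detectSpikes(x, fs, 80)
  truth <- sim$truth@spikeTrains$a
  hits <- vapply(truth, function(t0) any(abs(det - t0) <= 0.001), TRUE)
  expect_gte(mean(hits), 0.99)
  # after removing the causal filter cascade's constant group delay,
  # timing error is within one sample
  near <- vapply(truth[hits], function(t0) det[which.min(abs(det - t0))], 0)
  lag <- stats::median(near - truth[hits])
  expect_lte(max(abs(near - truth[hits] - lag)), 1.5 / fs)
})

test_that("cosine similarity: identity, orthogonality, hand value, conventions", {
  expect_equal(cosineSimilarity(c(2, 1, 3), c(2, 1, 3)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosineSimilarity(numeric(3), c(1, 2, 3)), 0)
  expect_error(cosineSimilarity(1:3, 1:4), "length")
})

test_that("soma merging joins identical adjacent trains and separates distant units", {
  g <- makeGrid(5, 5)
  dur <- 10
  set.seed(6)
  # 10 ms lattice: no two spikes within the 1 ms dedup window
  tr <- sort(sample(seq(0.05, 9.95, by = 0.01), 30))
  trains <- rep(list(numeric()), 25)
  trains[[7]] <- tr; trains[[8]] <- tr          # adjacent, identical
  trains[[19]] <- sort(runif(25, 0, dur))       # distant, independent
  us <- mergeSomata(trains, g, dur)
  expect_equal(nUnits(us), 2L)
  sizes <- sort(vapply(us@units, function(u) length(u$electrodes), 0L))
  expect_equal(sizes, c(1L, 2L))
  two <- us@units[[which(vapply(us@units, function(u)
    length(u$electrodes), 0L) == 2L)]]
  expect_setequal(two$electrodes, c(7L, 8L))
  # unit train deduplicates the union within 1 ms
  expect_equal(two$spikes, tr, tolerance = 1e-9)
  expect_equal(two$rate, length(tr) / dur)
  # centroid is the mean member position
  expect_equal(unname(two$centroid),
               unname(colMeans(electrodePositions(g)[c(7, 8), ])))
})

test_that("merging matches a brute-force transitive closure and is threshold-monotone", {
  dur <- 20
  g9 <- makeGrid(9, 9)
  planted <- plantedElectrodeTrains(g9, 4, dur, seed = 13)
  trains <- planted$perElectrode
  us <- mergeSomata(trains, g9, dur)
  # brute force: similarity of all adjacent active pairs, transitive
  # closure via repeated label propagation
  binS <- 1e-3
  hists <- lapply(trains, hdmea:::binSparse, binS = binS)
  nE <- nElectrodes(g9)
  adj <- matrix(FALSE, nE, nE)
  active <- which(lengths(trains) > 0)
  for (e in active) for (f in gridNeighbors(g9, e)) {
    if (f <= e || !length(trains[[f]])) next
    if (hdmea:::sparseCosine(hists[[e]], hists[[f]]) >= 0.3)
      adj[e, f] <- adj[f, e] <- TRUE
  }
  lab <- seq_len(nE)
  repeat {
    old <- lab
    for (e in active) {
      nb <- which(adj[e, ])
      if (length(nb)) lab[c(e, nb)] <- min(lab[c(e, nb)])
    }
    if (identical(old, lab)) break
  }
  bruteSizes <- sort(as.integer(table(lab[active])))
  detSizes <- sort(vapply(us@units, function(u) length(u$electrodes), 0L))
  expect_equal(detSizes, bruteSizes)
  # raising the similarity threshold never merges more
  n1 <- nUnits(mergeSomata(trains, g9, dur, simThreshold = 0.1))
  n2 <- nUnits(mergeSomata(trains, g9, dur, simThreshold = 0.5))
  n3 <- nUnits(mergeSomata(trains, g9, dur, simThreshold = 0.9))
  expect_true(n1 <= n2 && n2 <= n3)
  # unit spike count never exceeds the summed member counts
  us <- mergeSomata(trains, g9, dur)
  for (u in us@units)
    expect_lte(length(u$spikes), sum(lengths(trains[u$electrodes])))
})

test_that("neighborhood waveform-similarity map localizes somata", {
  g <- makeGrid(5, 5)
  # identical waveform everywhere: interior map is exactly 1
  v <- matrix(rep(sin(seq(0, 20, length.out = 500)), each = 25), 25, 500)
  m <- somaSimilarityMap(v, g)
  interior <- which(!is.na(m))
  expect_length(interior, 9L)
  expect_true(all(abs(m[interior] - 1) < 1e-12))
  # independent noise: values concentrate near 0
  set.seed(7)
  vn <- matrix(rnorm(25 * 4000), 25, 4000)
  mn <- somaSimilarityMap(vn, g)
  expect_lt(max(abs(mn[!is.na(mn)])), 0.1)
  # planted soma footprint: local maximum at the soma center
  g7 <- makeGrid(7, 7)
  u <- unitSpec("s", electrodePositions(g7)[25, ], 1.2, 250,
                firing = list(model = "poisson", rate = 5))
  sim <- simulateRecording(synthConfig(g7, 10, 5000, units = list(u),
                                       seed = 3L))
  ms <- somaSimilarityMap(sim$recording)
  expect_equal(which.max(ms), 25L)
  expect_equal(callSomataFromMap(ms, g7)[[1]], 25L)
  expect_warning(somaSimilarityMap(matrix(0, 4, 10), makeGrid(2, 2)),
                 "3 x 3")
})

test_that("firing-band table implements the band rule and percentage formula", {
  g <- makeGrid(6, 6)
  rates <- c(0, 0.05, 0.3, 0.7, 1, 3, 7, 12)
  trains <- lapply(rates, function(r)
    if (r == 0) numeric() else seq(0, 59.9, length.out = r * 60))
  names(trains) <- paste0("u", seq_along(rates))
  memb <- as.list(seq_along(rates)); names(memb) <- names(trains)
  us <- unitSetFromTrains(trains, memb, g, 60)
  st <- unitFiringStats(us)
  expect_equal(st$perUnit$band,
               c("0", "(0,0.1)", "[0.1,0.5)", "[0.5,1)", "[1,2)",
                 "[2,5)", "[5,10)", ">=10"))
  expect_equal(sum(st$bandTable$percent), 100)
  # printed-count arithmetic
  expect_equal(bandPercent(354, 993), 35.65, tolerance = 1e-3)
  expect_equal(bandPercent(238, 993), 23.97, tolerance = 1e-3)
  # a 60-spike unit over 60 s sits in [1,2)
  expect_equal(st$perUnit$rate[5], 1)
  expect_equal(st$perUnit$band[5], "[1,2)")
})

test_that("activity summary counts spikes, active electrodes and per-bin firing electrodes", {
  trains <- list(c(0.001, 0.052), numeric(), c(0.003), c(0.300))
  s <- activitySummary(trains, duration = 1, binMs = 5)
  expect_equal(s$totalSpikes, 4L)
  expect_equal(s$activeElectrodes, 3L)
  expect_equal(s$activePercent, 75)
  expect_equal(s$meanRateActive, 4 / 3)
  expect_equal(s$electrodesPerBin[1], 2L)   # electrodes 1 and 3 in bin 1
  expect_equal(s$electrodesPerBin[11], 1L)  # spike at 52 ms
  expect_equal(s$electrodesPerBin[61], 1L)  # spike at 300 ms
  expect_equal(sum(s$electrodesPerBin), 4L)
  z <- activitySummary(list(numeric(), numeric()), duration = 1)
  expect_equal(z$totalSpikes, 0L)
  expect_equal(z$activePercent, 0)
  expect_equal(z$meanRateActive, 0)
  # printed-count arithmetic
  expect_equal(activePercent(4605, 14612), 31.5, tolerance = 1e-2)
  expect_equal(activePercent(7260, 14612), 49.7, tolerance = 1e-2)
})
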