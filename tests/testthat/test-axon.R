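# the shared fixture: one soma driving a 2.4 mm straight axon at
# 1.155 m/s with 40% backpropagation under 9.43 uV rms noise (cached)

test_that("synchronous-firing counts single out the conduction path", {
  sim <- axonFixture(seed = 5)
  cnt <- countSynchronousFirings(sim$recording)
  truth <- sim$truth@axon[[1]]
  signal <- c(truth$electrodes, truth$haloElectrodes,
              unlist(sim$truth@memberships))
  # a planted sweep scores repeatedly; background electrodes never pass
  expect_equal(max(cnt[-signal]), 0L)
  expect_gt(min(cnt[truth$electrodes]), 0L)
  # selection retains a connected superset of the true path
  sel <- which(cnt >= 5)
  expect_true(all(truth$electrodes %in% sel))
  groups <- hdmea:::connectedGroups(sel, electrodeGrid(sim$recording))
  expect_equal(length(groups), 1L)
  # independent noise alone stays below the planted counts
  noise <- simulateRecording(synthConfig(makeGrid(6, 6), 2, 20000,
                                         seed = 31L))$recording
  expect_lt(max(countSynchronousFirings(noise)), 5)
})

test_that("soma identification finds the planted footprint and its train", {
  sim <- axonFixture(seed = 5)
  soma <- identifySoma(sim$recording, ampThreshold = 200)
  trueMemb <- sim$truth@memberships$soma
  expect_true(all(soma$electrodes %in% trueMemb))
  expect_gte(soma$peakAmplitude, 500)
  expect_gt(length(soma$train), 30)
  # uniform low map: not found
  flat <- meaRecording(matrix(rnorm(16 * 2000, 0, 5), 16, 2000),
                       makeGrid(4, 4), 20000)
  expect_error(identifySoma(flat, ampThreshold = 200), "not found")
  # two disjoint hotspots: larger component wins, other is secondary
  g <- makeGrid(5, 5)
  v <- matrix(0, 25, 2000)
  v[c(1, 2), 100] <- -300          # 2-electrode hotspot
  v[25, 100] <- -300               # single corner hotspot
  two <- identifySoma(meaRecording(v, g, 20000), ampThreshold = 200)
  expect_setequal(two$electrodes, c(1L, 2L))
  expect_equal(two$secondary[[1]], 25L)
})

test_that("spike-triggered averaging is exact for one trigger and averages noise down", {
  g <- makeGrid(2, 2)
  fs <- 10000
  set.seed(8)
  v <- matrix(rnorm(4 * fs, 0, 9.43), 4, fs)
  rec <- meaRecording(v, g, fs)
  sta1 <- spikeTriggeredAverage(rec, 0.5, halfWindowMs = 3)
  i <- round(0.5 * fs) + 1
  w <- round(0.003 * fs)
  expect_equal(sta1$avg, v[, (i - w):(i + w)])
  expect_equal(sta1$nTriggers, 1L)
  # averaging law: n triggers shrink noise like 1/sqrt(n)
  trig <- seq(0.05, 0.95, length.out = 60)
  sta <- spikeTriggeredAverage(rec, trig)
  expect_equal(stats::sd(sta$avg), 9.43 / sqrt(60), tolerance = 0.15)
  expect_error(spikeTriggeredAverage(rec, 2.0), "trigger")
  # triggers locked to a sine phase average to the sine snippet
  t <- (seq_len(fs) - 1) / fs
  vs <- matrix(rep(50 * sin(2 * pi * 100 * t), each = 4), 4, fs)
  stas <- spikeTriggeredAverage(meaRecording(vs, g, fs),
                                seq(0.1, 0.9, by = 0.01))
  expect_equal(stas$avg[1, ], 50 * sin(2 * pi * 100 *
                                       (0.1 + stas$times / 1000)),
               tolerance = 1e-6)
})

test_that("front tracking recovers the planted conduction path and velocity", {
  sim <- axonFixture(seed = 5)
  soma <- identifySoma(sim$recording, ampThreshold = 200)
  sta <- spikeTriggeredAverage(sim$recording, soma$train)
  paths <- trackPropagationFront(sta, electrodeGrid(sim$recording),
                                 soma$centroid,
                                 exclude = soma$electrodes)
  fw <- paths$forward
  truth <- sim$truth@axon[[1]]
  # the front advances monotonically and stays on the axonal footprint
  expect_true(all(diff(fw@cumDist) >= 0))
  expect_true(all(fw@electrodes %in%
                  c(truth$electrodes, truth$haloElectrodes)))
  # distance gained between +1 and +2 ms matches the planted velocity
  i1 <- which.min(abs(fw@times - 1)); i2 <- which.min(abs(fw@times - 2))
  expect_equal(fw@cumDist[i2] - fw@cumDist[i1],
               1.155 * (fw@times[i2] - fw@times[i1]), tolerance = 0.08)
  expect_equal(fw@velocity, 1.155, tolerance = 0.05)
  expect_gte(fw@r2, 0.99)
  # backward path retraces the forward route at matching speed
  bw <- paths$backward
  expect_gte(length(intersect(bw@electrodes,
                              c(truth$electrodes, truth$haloElectrodes))),
             0.9 * length(bw@electrodes))
  expect_equal(abs(bw@velocity), fw@velocity, tolerance = 0.03)
  # soma-only map yields empty paths
  g <- makeGrid(3, 3)
  quiet <- list(avg = matrix(0, 9, 121),
                times = seq(-3, 3, length.out = 121),
                nTriggers = 10, nSkipped = 0)
  ep <- trackPropagationFront(quiet, g, c(11.47, 11.47))
  expect_length(ep$forward@times, 0L)
  expect_true(is.na(ep$forward@velocity))
})

test_that("velocity fitting: collinear points, endpoint arithmetic, degenerate errors", {
  tMs <- seq(0.05, 2.05, by = 0.1)
  path <- list(times = tMs, cumDist = 1.2 * tMs)
  fit <- fitConductionVelocity(path)
  expect_equal(fit$velocity, 1.2, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  # the printed distance/time pairs
  expect_equal(endpointVelocity(2.44, 2.1), 1.16, tolerance = 0.005)
  expect_equal(endpointVelocity(2.05, 1.5), 1.37, tolerance = 0.005)
  expect_equal(endpointVelocity(1.70, 2.0), 0.85, tolerance = 1e-12)
  expect_error(endpointVelocity(1, 0), "positive")
  expect_error(fitConductionVelocity(list(times = c(1, 2),
                                          cumDist = c(1, 2))), "3 points")
  expect_error(hdmea:::fitVelocity(rep(1, 5), 1:5), "degenerate")
})

test_that("backpropagation statistics recover the generator probability", {
  sim <- axonFixture(seed = 5)
  soma <- identifySoma(sim$recording, ampThreshold = 200)
  truth <- sim$truth@axon[[1]]
  bp <- backpropagationStats(sim$recording, soma$train,
                             truth$electrodes, soma$centroid)
  pTrue <- length(truth$backpropSpikes) /
    length(sim$truth@spikeTrains$soma)
  # within the 95% binomial CI of the generator probability
  ci <- stats::binom.test(bp$nBackprop, bp$nTriggers)$conf.int
  expect_true(pTrue >= ci[1] && pTrue <= ci[2])
  expect_equal(bp$probabilityPercent,
               100 * bp$nBackprop / bp$nTriggers)
  # probability-zero generator: no backprop calls
  sim0 <- axonFixture(seed = 21, velocity = 1.0, backpropProb = 0)
  soma0 <- identifySoma(sim0$recording, ampThreshold = 200)
  bp0 <- backpropagationStats(sim0$recording, soma0$train,
                              sim0$truth@axon[[1]]$electrodes,
                              soma0$centroid)
  expect_equal(bp0$nBackprop, 0L)
  # printed-count arithmetic
  expect_equal(backpropProbability(486, 1167), 41.6, tolerance = 0.05)
})

test_that("velocity change report normalizes to the baseline with SEM", {
  one <- velocityChangeReport(c(before = 1.16, h2 = 1.16, h24 = 1.16))
  expect_equal(one$meanPercent, c(100, 100, 100))
  m <- rbind(c(1.16, 1.37, 0.85), c(1.10, 1.30, 0.90))
  colnames(m) <- c("before", "h2", "h24")
  rep <- velocityChangeReport(m)
  expect_equal(rep$meanPercent[1], 100)
  expect_equal(rep$meanPercent[2],
               mean(100 * m[, 2] / m[, 1]))
  expect_gt(rep$semPercent[2], 0)
  # the printed 24 h endpoint pair lands at 73.3% of baseline
  expect_equal(100 * endpointVelocity(1.70, 2.0) /
                 endpointVelocity(2.44, 2.1), 73.3, tolerance = 0.15)
  expect_error(velocityChangeReport(c(0, 1)), "baseline")
})
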