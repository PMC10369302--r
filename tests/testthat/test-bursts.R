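test_that("network-burst detection: empty input, planted bursts, strict merge boundary", {
  expect_equal(nrow(detectNetworkBursts(list(numeric(), numeric()))), 0L)

  set.seed(1)
  onsets <- seq(2, 38, by = 4)
  trains <- lapply(1:5, function(u) {
    sort(c(runif(4, 0, 40),
           unlist(lapply(onsets, function(t0)
             t0 + sort(runif(10, 0, 0.3))))))
  })
  names(trains) <- paste0("u", 1:5)
  nb <- detectNetworkBursts(trains)
  expect_equal(nrow(nb), length(onsets))
  # boundaries within the ISI threshold of the planted burst edges
  expect_true(all(abs(nb$start - onsets) <= 0.1 + 0.05))
  expect_true(all(nb$nUnits >= 2))

  # two groups whose gap equals the inter-burst threshold stay split
  a <- c(0, 0.01, 0.02, 0.03, 0.04)
  b <- a + 0.34                  # gap from last spike = 300 ms exactly
  two <- detectNetworkBursts(list(x = a, y = a, x2 = b, y2 = b),
                             minSpikes = 5, minUnits = 2)
  expect_equal(nrow(two), 2L)
  # a hair under the threshold merges
  b2 <- a + 0.339
  one <- detectNetworkBursts(list(x = a, y = a, x2 = b2, y2 = b2),
                             minSpikes = 5, minUnits = 2)
  expect_equal(nrow(one), 1L)
  # adding a silent unit changes nothing
  nb2 <- detectNetworkBursts(c(trains, list(silent = numeric())))
  expect_equal(nb, nb2)
})

test_that("Poisson-Surprise closed forms, tail oracle and monotonicity", {
  # n = 1 closed form
  for (rT in c(0.2, 1, 5))
    expect_equal(poissonSurprise(1, 1, rT), -log(1 - exp(-rT)),
                 tolerance = 1e-12)
  # n = 10, rT = 1 against direct tail summation
  direct <- -log(sum(exp(-1) / factorial(10:170)))
  expect_equal(poissonSurprise(10, 1, 1), direct, tolerance = 1e-10)
  # increasing in n at fixed rT
  s <- poissonSurprise(1:30, 2, 1)
  expect_true(all(diff(s) > 0))
  expect_error(poissonSurprise(0, 1, 1), "n")
  expect_error(poissonSurprise(2, 0, 1))
})

test_that("surprise agrees with a high-precision tail sum over the (n, rT) grid", {
  tailOracle <- function(n, lambda) {
    i <- n:(n + 400)
    # sum from the largest term for accuracy
    terms <- exp(-lambda + i * log(lambda) - lgamma(i + 1))
    -log(sum(sort(terms)))
  }
  for (lambda in c(0.1, 0.5, 1, 2, 5, 10, 20)) {
    n <- 1:50
    s <- poissonSurprise(n, 1, lambda)
    o <- vapply(n, tailOracle, 0, lambda = lambda)
    ok <- is.finite(o)   # oracle underflows for extreme surprise only
    # relative agreement, absolute where S itself underflows double rounding
    expect_true(all(abs(s[ok] - o[ok]) / o[ok] < 1e-8 |
                    abs(s[ok] - o[ok]) < 1e-12))
  }
})

test_that("single-neuron burst detection: periodic silence, planted burst, Poisson null", {
  # perfectly periodic train has no ISI below the mean
  per <- seq(0, 99, by = 1)
  expect_equal(nrow(detectPsBursts(per, 100)), 0L)
  expect_equal(nrow(detectPsBursts(c(1, 2), 100)), 0L)

  set.seed(2)
  planted <- 50 + sort(runif(20, 0, 0.4))     # 50 Hz burst
  tr <- sort(c(runif(50, 0, 100), planted))   # on 0.5 Hz background
  ps <- detectPsBursts(tr, 100)
  expect_gte(nrow(ps), 1L)
  main <- ps[which.max(ps$surprise), ]
  covered <- sum(planted >= main$start & planted <= main$end)
  expect_gte(covered / length(planted), 0.9)
  expect_gte(main$surprise, 10)

  # false-positive control: homogeneous Poisson, 100 seeds
  fp <- vapply(1:100, function(s) {
    set.seed(s + 300)
    nrow(detectPsBursts(sort(runif(50, 0, 100)), 100))
  }, 0L)
  expect_lt(mean(fp), 1)
})

test_that("burst parameter table matches hand arithmetic on a 3-burst toy", {
  # three bursts of 5 spikes at 100 Hz starting at 1, 3, 6 s; background
  # spikes at 9 and 9.5 s
  bspk <- function(t0) t0 + (0:4) * 0.01
  pooled <- c(bspk(1), bspk(3), bspk(6), 9, 9.5)
  bursts <- data.frame(start = c(1, 3, 6), end = c(1.045, 3.045, 6.045))
  tab <- burstParameterTable(bursts, pooled, duration = 10, mfBinMs = 10)
  expect_equal(unname(tab["TS"]), 17)
  expect_equal(unname(tab["nBursts"]), 3)
  expect_equal(unname(tab["IBI"]), mean(c(2, 3)))
  expect_equal(unname(tab["duration"]), 0.045)
  expect_equal(unname(tab["spikesPerBurst"]), 5)
  # 10 ms bins over [start, end]: 2 spikes in the fullest bin -> 200 Hz
  expect_equal(unname(tab["MF"]), 200)
  expect_equal(unname(tab["cvDuration"]), 0)
  expect_equal(unname(tab["cvSpikes"]), 0)
  expect_equal(unname(tab["cvMF"]), 0)
  expect_equal(unname(tab["cvIBI"]),
               stats::sd(c(2, 3)) / mean(c(2, 3)))
  # identical bursts: every CV zero
  two <- burstParameterTable(
    data.frame(start = c(1, 3), end = c(1.045, 3.045)),
    c(bspk(1), bspk(3)), 10)
  expect_equal(unname(two[c("cvDuration", "cvSpikes", "cvMF")]),
               c(0, 0, 0))
  # no bursts: burst-dependent entries flagged
  none <- burstParameterTable(bursts[0, ], pooled, 10)
  expect_equal(unname(none["TS"]), 17)
  expect_equal(unname(none["nBursts"]), 0)
  expect_true(is.na(none["IBI"]))
  expect_true(is.na(none["MF"]))
  # spikes inside bursts never exceed TS
  expect_lte(tab["spikesPerBurst"] * tab["nBursts"], tab["TS"])
})

test_that("vehicle normalization returns percentages with N/A on zero vehicle", {
  veh <- c(TS = 200, nBursts = 10, IBI = 2, duration = 0)
  cond <- c(TS = 300, nBursts = 10, IBI = 1, duration = 0.5)
  out <- normalizeToVehicle(cond, veh)
  expect_equal(unname(out["TS"]), 150)
  expect_equal(unname(out["nBursts"]), 100)
  expect_equal(unname(out["IBI"]), 50)
  expect_true(is.na(out["duration"]))           # vehicle zero
  expect_equal(unname(normalizeToVehicle(veh, veh)[1:3]),
               c(100, 100, 100))
  expect_error(normalizeToVehicle(cond, veh[1:3]), "match")
  # tidy export carries the na flag
  f <- tempfile(fileext = ".csv")
  df <- writeBurstTableCsv(list(vehicle = veh, drug = cond),
                           "vehicle", f)
  expect_true(file.exists(f))
  expect_true(any(df$na_flag))
})
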