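test_that("synchronized-spike counting matches enumeration and brute force", {
  expect_equal(countSynchronizedSpikes(numeric(), c(1, 2)), 0L)
  expect_equal(countSynchronizedSpikes(c(1, 2), numeric()), 0L)
  # worked enumeration: ref {0, 0.200}, target {0.050, 0.250, 0.260}
  expect_equal(countSynchronizedSpikes(c(0, 0.2), c(0.05, 0.25, 0.26)), 3L)
  # target = ref + 50 ms with wide ISIs: one hit per reference spike
  ref <- seq(0, 10, by = 0.2)
  expect_equal(countSynchronizedSpikes(ref, ref + 0.05),
               length(ref))
  # window is half-open: a simultaneous spike does not count,
  # one exactly at the window edge does
  expect_equal(countSynchronizedSpikes(1, 1), 0L)
  expect_equal(countSynchronizedSpikes(1, 1.1, window = 0.1), 1L)
  # brute-force double loop on random trains
  set.seed(10)
  for (i in 1:20) {
    a <- sort(runif(60, 0, 30)); b <- sort(runif(80, 0, 30))
    brute <- sum(vapply(a, function(t0)
      sum(b > t0 & b <= t0 + 0.1), 0))
    expect_equal(countSynchronizedSpikes(a, b), as.integer(brute))
  }
})

test_that("ISI surrogates preserve count, span and the ISI multiset", {
  set.seed(11)
  tr <- sort(runif(40, 0, 60))
  sur <- makeIsiSurrogates(tr, n = 50)
  for (s in sur) {
    expect_length(s, length(tr))
    expect_equal(s[1], tr[1])
    expect_equal(s[length(s)], tr[length(tr)], tolerance = 1e-9)
    expect_equal(sort(diff(s)), sort(diff(tr)), tolerance = 1e-12)
  }
  # a 2-ISI train has 2 orderings, each drawn about half the time
  tr3 <- c(0, 0.1, 0.4)
  set.seed(12)
  draws <- vapply(makeIsiSurrogates(tr3, n = 10000),
                  function(s) s[2], 0)
  p <- mean(abs(draws - 0.1) < 1e-12)
  expect_gt(p, 0.47); expect_lt(p, 0.53)
  expect_warning(makeIsiSurrogates(c(1), n = 3), "fewer than 2")
})

test_that("Z score arithmetic, zero-SD handling and time-shift invariance", {
  set.seed(13)
  a <- sort(runif(200, 0, 200)); b <- sort(runif(200, 0, 200))
  set.seed(99); r1 <- connectionZScore(a, b)
  expect_equal(r1$z, (r1$real - r1$surrogateMean) / r1$surrogateSD)
  # global time shift leaves Z unchanged (same surrogate draws)
  set.seed(99); r2 <- connectionZScore(a + 5, b + 5)
  expect_equal(r1$z, r2$z, tolerance = 1e-12)
  # degenerate target: zero surrogate SD, real equals surrogate -> 0
  set.seed(1)
  d <- connectionZScore(c(1, 2, 3), c(10, 20, 30), nSurrogates = 20)
  expect_true(d$surrogateSD == 0 || is.finite(d$z))
  one <- suppressWarnings(connectionZScore(c(1, 2), c(5), nSurrogates = 10))
  expect_true(one$z == 0 || is.na(one$z))   # never infinite
})

test_that("planted couplings are detected and classified excitatory", {
  hits <- 0L
  for (i in 1:10) {
    set.seed(i + 40)
    tr <- simulateSpikeTrains(
      list(unitSpec("s", c(0, 0),
                    firing = list(model = "poisson", rate = 1)),
           unitSpec("t", c(0, 0),
                    firing = list(model = "poisson", rate = 1))),
      list(couplingSpec("s", "t", p = 0.5)), 150)
    z <- connectionZScore(tr$s, tr$t)$z
    hits <- hits + (z >= 3)
  }
  expect_gte(hits, 9L)
})

test_that("classification matrix, network percentages and ECR formulas", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(z) <- NA
  s0 <- classifySummary(z)
  expect_equal(unname(s0["excitatoryPercent"]), 0)
  expect_equal(unname(s0["inhibitoryPercent"]), 0)
  z["a", "b"] <- 3; z["a", "c"] <- 5; z["b", "a"] <- -3; z["c", "d"] <- 2.9
  cls <- hdmea:::classifyZ(z)
  expect_equal(cls["a", "b"], "excitatory")    # inclusive >= 3
  expect_equal(cls["b", "a"], "inhibitory")
  expect_equal(cls["c", "d"], "none")
  expect_equal(hdmea:::classifyZ(z, strict = TRUE)["a", "b"], "none")
  s <- classifySummary(z)
  expect_equal(unname(s["excitatoryPercent"]), 100 * 2 / 12)
  expect_equal(unname(s["inhibitoryPercent"]), 100 * 1 / 12)
  sv <- classifySummary(z, vehicle = s0)
  expect_equal(unname(sv["deltaExcitatory"]), 100 * 2 / 12)
  # a matrix engineered to 33.5% excitatory entries reports 33.5%
  set.seed(3)
  n <- 200
  zm <- matrix(0, n, n); diag(zm) <- NA
  off <- which(row(zm) != col(zm))
  hot <- sample(off, round(0.335 * length(off)))
  zm[hot] <- 4
  expect_equal(unname(classifySummary(zm)["excitatoryPercent"]), 33.5,
               tolerance = 0.01)
  # ECR
  expect_equal(ecr(c(4, 2, 5, 1), 5), 50)
  expect_equal(ecr(c(0, 0, 0, 0), 5), 0)
  expect_equal(ecr(c(9, 9, 9, 9), 5), 100)
  expect_error(ecr(c(1), 1), "2 units")
})

test_that("full connectivity analysis recovers a planted circuit and exports", {
  set.seed(50)
  tr <- simulateSpikeTrains(
    list(unitSpec("a", c(0, 0), firing = list(model = "poisson", rate = 1.2)),
         unitSpec("b", c(0, 0), firing = list(model = "poisson", rate = 1)),
         unitSpec("c", c(0, 0), firing = list(model = "poisson", rate = 1.1))),
    list(couplingSpec("a", "b", p = 0.6)), 150)
  res <- connectivityAnalysis(tr, seed = 7L)
  expect_s4_class(res, "ConnectivityResult")
  expect_equal(res@classification["a", "b"], "excitatory")
  expect_equal(res@classification["c", "a"], "none")
  expect_true(all(is.na(diag(zMatrix(res)))))
  # seeded reproducibility
  res2 <- connectivityAnalysis(tr, seed = 7L)
  expect_identical(zMatrix(res), zMatrix(res2))
  et <- ecrTable(res)
  expect_gte(et$ecr[et$id == "a"], 50)
  d <- file.path(tempdir(), "conn")
  writeConnectivity(res, d)
  expect_true(all(file.exists(file.path(d,
    c("z_matrix.csv", "classification.csv", "ecr.csv",
      "connectivity_meta.json")))))
})
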