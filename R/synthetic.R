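#' Unit specification for the generator
#'
#' A simulated neuron: a soma footprint spanning the electrodes within
#' `footprintRadius` pitches of the centroid, extracellular amplitude
#' decaying with distance as 1/(1 + d/pitch), and a base firing model.
#'
#' @param id unit id (character or coercible)
#' @param centroid numeric (x, y) in micrometers
#' @param footprintRadius footprint radius in electrode pitches
#' @param amplitude negative-peak amplitude at the centroid, microvolts
#' @param firing list: `list(model = "poisson", rate = )` or
#'   `list(model = "bursting", burstRate = , intraRate = , burstDuration = ,
#'   baseRate = )` (rates Hz, duration s), or `list(model = "times",
#'   times = )` for fully specified spike times.
#' @return spec list
#' @export
unitSpec <- function(id, centroid, footprintRadius = 1.5, amplitude = 200,
                     firing = list(model = "poisson", rate = 1)) {
  stopifnot(length(centroid) == 2, footprintRadius >= 0, amplitude >= 0)
  if (!is.null(firing$rate) && firing$rate < 0) stop("rates must be >= 0")
  list(id = as.character(id), centroid = as.numeric(centroid),
       footprintRadius = footprintRadius, amplitude = amplitude,
       firing = firing)
}

#' Directed coupling specification
#'
#' An excitatory coupling makes the target fire with probability `p` at a
#' latency drawn uniformly in (0, window] seconds after each source spike;
#' an inhibitory coupling deletes, with probability `p`, the target spikes
#' inside the window after each source spike.
#'
#' @param source,target unit ids
#' @param p coupling probability in [0, 1]
#' @param sign "excitatory" or "inhibitory"
#' @param window coupling window, seconds (default 0.1)
#' @export
couplingSpec <- function(source, target, p, sign = "excitatory",
                         window = 0.1) {
  stopifnot(p >= 0, p <= 1, sign %in% c("excitatory", "inhibitory"))
  list(source = as.character(source), target = as.character(target),
       p = p, sign = sign, window = window)
}

#' Axon specification
#'
#' A conduction path given as an ordered electrode-index sequence starting
#' next to the soma. The electrode at arc length d (mm, cumulative
#' straight-line distance along the sequence measured from the soma
#' centroid) receives the axonal waveform at `t_spike + d / velocity` ms;
#' with probability `backpropProb`, a soma spike is preceded by the
#' mirrored sequence (arrival at `t_spike - d / velocity`).
#'
#' @param somaUnit id of the unit whose spike train drives the axon
#' @param electrodes ordered integer electrode path
#' @param velocity conduction velocity, m/s
#' @param amplitude axonal waveform negative-peak amplitude, microvolts.
#'   Default 40 (well below somatic amplitudes, above the noise floor).
#' @param backpropProb probability of backpropagation per soma spike
#' @export
axonSpec <- function(somaUnit, electrodes, velocity = 1.0, amplitude = 40,
                     backpropProb = 0) {
  stopifnot(velocity > 0, backpropProb >= 0, backpropProb <= 1)
  list(somaUnit = as.character(somaUnit),
       electrodes = as.integer(electrodes),
       velocity = velocity, amplitude = amplitude,
       backpropProb = backpropProb)
}

#' LFP wave specification
#'
#' A radially expanding, Hann-windowed sinusoid: from each onset the active
#' disc grows at `expansionRate` mm^2/s around the center electrode until
#' `maxArea` mm^2 is swept, so area-versus-time ground truth is linear.
#'
#' @param centerElectrode electrode index of the wave origin
#' @param freq oscillation frequency, Hz
#' @param onsets numeric vector of event onset times, s
#' @param expansionRate areal expansion rate, mm^2/s
#' @param maxArea final swept area, mm^2
#' @param amplitude peak amplitude, microvolts
#' @param region optional label carried to the ground truth
#' @export
lfpWaveSpec <- function(centerElectrode, freq, onsets, expansionRate,
                        maxArea, amplitude = 200, region = "region") {
  stopifnot(freq > 0, expansionRate > 0, maxArea > 0)
  list(centerElectrode = as.integer(centerElectrode), freq = freq,
       onsets = as.numeric(onsets), expansionRate = expansionRate,
       maxArea = maxArea, amplitude = amplitude, region = region)
}

#' Evoked-response specification
#'
#' Assigns a unit one of the five response templates (see
#' [evokedTemplate()]) starting at `onset` seconds; spikes are drawn as an
#' inhomogeneous Poisson process from the template rate profile.
#'
#' @param unit unit id
#' @param cluster template id in 1..5
#' @param onset administration time, s
#' @export
evokedSpec <- function(unit, cluster, onset) {
  if (!cluster %in% 1:5) stop("unknown evoked cluster id: must be 1..5")
  list(unit = as.character(unit), cluster = as.integer(cluster),
       onset = onset)
}

#' Generator configuration
#'
#' Bundles everything [simulateRecording()] needs. Defaults are the
#' recording conditions the analyses assume: 9.43 uV rms additive Gaussian
#' noise and a 5 kHz sampling rate.
#'
#' @param grid [ElectrodeGrid-class]
#' @param duration recording length, s
#' @param samplingRate Hz
#' @param noiseRms additive Gaussian noise, uV rms
#' @param units list of [unitSpec()]
#' @param couplings list of [couplingSpec()]
#' @param axons list of [axonSpec()]
#' @param lfpWaves list of [lfpWaveSpec()]
#' @param evoked list of [evokedSpec()]
#' @param seed integer RNG seed; identical seeds give bit-identical output
#' @return a [SynthConfig-class]
#' @export
synthConfig <- function(grid, duration, samplingRate = 5000,
                        noiseRms = 9.43, units = list(), couplings = list(),
                        axons = list(), lfpWaves = list(), evoked = list(),
                        seed = 1L) {
  stopifnot(duration > 0, samplingRate > 0, noiseRms >= 0)
  cfg <- new("SynthConfig", grid = grid, duration = duration,
             samplingRate = samplingRate, noiseRms = noiseRms,
             units = units, couplings = couplings, axons = axons,
             lfpWaves = lfpWaves, evoked = evoked, seed = as.integer(seed))
  for (u in units) {
    memb <- footprintElectrodes(grid, u$centroid, u$footprintRadius)
    if (!length(memb))
      stop(sprintf("unit '%s': footprint outside grid", u$id))
  }
  cfg
}

footprintElectrodes <- function(grid, centroid, radiusPitches) {
  p <- electrodePositions(grid)
  d <- sqrt((p[, 1] - centroid[1])^2 + (p[, 2] - centroid[2])^2)
  which(d <= radiusPitches * grid@pitch + 1e-9)
}

drawPoissonTrain <- function(rate, duration) {
  if (rate <= 0) return(numeric())
  n <- stats::rpois(1L, rate * duration)
  sort(stats::runif(n, 0, duration))
}

#' Simulate base and coupled spike trains
#'
#' Base trains are homogeneous Poisson or two-state bursting; couplings
#' then add (excitatory) or delete (inhibitory) target spikes inside the
#' coupling window after each source spike. Uses the current RNG state.
#'
#' @param units list of [unitSpec()]
#' @param couplings list of [couplingSpec()]
#' @param duration s
#' @return named list of sorted spike-time vectors (s)
#' @export
simulateSpikeTrains <- function(units, couplings = list(), duration) {
  trains <- list()
  for (u in units) {
    f <- u$firing
    train <- switch(f$model,
      poisson = drawPoissonTrain(f$rate, duration),
      bursting = {
        base <- drawPoissonTrain(f$baseRate %||% 0, duration)
        onsets <- drawPoissonTrain(f$burstRate, duration)
        intra <- unlist(lapply(onsets, function(t0) {
          n <- stats::rpois(1L, f$intraRate * f$burstDuration)
          t0 + sort(stats::runif(n, 0, f$burstDuration))
        }))
        sort(c(base, intra))
      },
      times = sort(f$times),
      stop(sprintf("unknown firing model '%s'", f$model))
    )
    trains[[u$id]] <- train[train >= 0 & train <= duration]
  }
  for (cp in couplings) {
    src <- trains[[cp$source]]
    tgt <- trains[[cp$target]]
    if (is.null(src) || is.null(tgt)) stop("coupling names unknown unit")
    if (cp$sign == "excitatory") {
      hit <- stats::runif(length(src)) < cp$p
      extra <- src[hit] + stats::runif(sum(hit), 0, cp$window)
      tgt <- sort(c(tgt, extra[extra <= duration]))
    } else {
      for (t0 in src) {
        inWin <- tgt > t0 & tgt <= t0 + cp$window
        if (any(inWin)) {
          kill <- inWin & (stats::runif(length(tgt)) < cp$p)
          tgt <- tgt[!kill]
        }
      }
    }
    trains[[cp$target]] <- tgt
  }
  trains
}

# Biphasic extracellular spike template: negative lobe first, then a
# smaller positive lobe (sink before source). Durations in ms.
spikeTemplate <- function(samplingRate, negMs = 1, posMs = 1, posFrac = 0.5) {
  dt <- 1000 / samplingRate
  tNeg <- seq(0, negMs, by = dt); tNeg <- tNeg[tNeg < negMs]
  tPos <- seq(0, posMs, by = dt); tPos <- tPos[tPos < posMs]
  tpl <- c(-sin(pi * tNeg / negMs), posFrac * sin(pi * tPos / posMs))
  attr(tpl, "peakOffset") <- which.min(tpl) - 1L  # samples before the sink
  tpl
}

addTemplateAt <- function(vrow, tpl, idx, amp) {
  n <- length(vrow); L <- length(tpl)
  for (i in idx) {
    if (i < 1L || i > n) next
    j <- i:min(n, i + L - 1L)
    vrow[j] <- vrow[j] + amp * tpl[seq_along(j)]
  }
  vrow
}

#' Per-electrode axonal arc lengths and latencies
#'
#' @param grid [ElectrodeGrid-class]
#' @param pathElectrodes ordered electrode path
#' @param velocity m/s
#' @param somaCentroid (x, y) micrometers of the soma center of gravity
#' @return data.frame (electrode, arcMm, latencyMs)
#' @export
axonLatencies <- function(grid, pathElectrodes, velocity, somaCentroid) {
  stopifnot(velocity > 0)
  p <- electrodePositions(grid)[pathElectrodes, , drop = FALSE]
  seg <- sqrt(diff(c(somaCentroid[1], p[, 1]))^2 +
              diff(c(somaCentroid[2], p[, 2]))^2)
  arcMm <- cumsum(seg) * 1e-3
  data.frame(electrode = pathElectrodes, arcMm = arcMm,
             latencyMs = arcMm / velocity)  # mm / (mm/ms)
}

#' Five evoked-response rate templates
#'
#' Gamma-shaped rate bumps on the 100 x 100-ms post-administration grid,
#' parameterized so that the discrete peak rate, peak time, and 10-s mean
#' rate equal the per-cluster response statistics (cluster 1: flat
#' baseline, no transient; 2: 20.7 Hz peak near 1.5 s, 7.7 Hz mean;
#' 3: 35.8 near 1.5 s, 9.4; 4: 52.8 near 1.3 s, 13.2; 5: 80.2 near 1.2 s
#' with sharp decay, 8.2).
#'
#' @param cluster template id in 1..5
#' @param window response window, s
#' @param bin histogram bin, s
#' @return list with `times` (bin centers, s), `rate` (Hz), `cluster`
#' @export
evokedTemplate <- function(cluster, window = 10, bin = 0.1) {
  if (!cluster %in% 1:5) stop("unknown evoked cluster id: must be 1..5")
  tt <- seq(bin / 2, window - bin / 2, by = bin)
  pars <- list(
    NULL,
    list(k = 1.5, tp = 1.5, peak = 20.7, mean10 = 7.7),
    list(k = 2.5, tp = 1.5, peak = 35.8, mean10 = 9.4),
    list(k = 2.0, tp = 1.3, peak = 52.8, mean10 = 13.2),
    list(k = 9.0, tp = 1.2, peak = 80.2, mean10 = 8.2)
  )
  if (cluster == 1L) {
    rate <- rep(1.0, length(tt))  # spontaneous-level baseline, no transient
  } else {
    p <- pars[[cluster]]
    s <- (tt / p$tp)^p$k * exp(p$k * (1 - tt / p$tp))
    s <- s / max(s)
    mbar <- mean(s)
    A <- (p$peak - p$mean10) / (1 - mbar)
    b <- p$peak - A
    if (b < 0) stop("template parameterization produced a negative baseline")
    rate <- b + A * s
  }
  list(times = tt, rate = rate, cluster = cluster)
}

#' Simulate an evoked firing-rate profile
#'
#' Returns the deterministic template rate profile for a cluster starting
#' at `onset`; spike draws (inhomogeneous Poisson) are added by
#' [simulateRecording()] for units carrying an [evokedSpec()].
#'
#' @inheritParams evokedTemplate
#' @param onset administration time, s
#' @return list with `times` (absolute s), `rate` (Hz), `cluster`
#' @export
simulateEvoked <- function(cluster, onset = 0, window = 10, bin = 0.1) {
  tpl <- evokedTemplate(cluster, window, bin)
  list(times = onset + tpl$times, rate = tpl$rate, cluster = tpl$cluster)
}

drawInhomPoisson <- function(times, rate, bin) {
  counts <- stats::rpois(length(times), rate * bin)
  unlist(lapply(which(counts > 0), function(i)
    times[i] - bin / 2 + stats::runif(counts[i], 0, bin)))
}

#' Simulate a recording with known ground truth
#'
#' Builds the voltage matrix as the sum of unit spike templates, axonal
#' signals, expanding LFP waves and additive Gaussian noise, together with
#' the [GroundTruth-class] that downstream analyses are validated against.
#' Polarity is sink-first: each injected waveform leads with its negative
#' lobe. Identical seeds give bit-identical output.
#'
#' @param config a [SynthConfig-class]
#' @return list with elements `recording` ([MEARecording-class]) and
#'   `truth` ([GroundTruth-class])
#' @export
simulateRecording <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  set.seed(config@seed)
  grid <- config@grid
  fs <- config@samplingRate
  nS <- as.integer(round(config@duration * fs))
  nE <- nElectrodes(grid)
  pos <- electrodePositions(grid)

  trains <- simulateSpikeTrains(config@units, config@couplings,
                                config@duration)

  evokedLabels <- integer()
  for (ev in config@evoked) {
    prof <- simulateEvoked(ev$cluster, ev$onset)
    keepWin <- prof$times <= config@duration
    extra <- drawInhomPoisson(prof$times[keepWin], prof$rate[keepWin], 0.1)
    trains[[ev$unit]] <- sort(c(trains[[ev$unit]],
                                extra[extra >= 0 & extra <= config@duration]))
    evokedLabels[[ev$unit]] <- ev$cluster
  }

  v <- matrix(0, nE, nS)
  tpl <- spikeTemplate(fs)

  memberships <- list()
  for (u in config@units) {
    memb <- footprintElectrodes(grid, u$centroid, u$footprintRadius)
    memberships[[u$id]] <- memb
    tr <- trains[[u$id]]
    if (!length(tr)) next
    idx <- as.integer(round(tr * fs)) + 1L - attr(tpl, "peakOffset")
    d <- sqrt((pos[memb, 1] - u$centroid[1])^2 +
              (pos[memb, 2] - u$centroid[2])^2)
    amps <- u$amplitude / (1 + d / grid@pitch)
    for (k in seq_along(memb))
      v[memb[k], ] <- addTemplateAt(v[memb[k], ], tpl, idx, amps[k])
  }

  axTruth <- list()
  axTpl <- spikeTemplate(fs, negMs = 0.5, posMs = 0.5)
  for (a in config@axons) {
    somaSpec <- Filter(function(u) u$id == a$somaUnit, config@units)[[1]]
    lat <- axonLatencies(grid, a$electrodes, a$velocity, somaSpec$centroid)
    tr <- trains[[a$somaUnit]]
    bp <- which(stats::runif(length(tr)) < a$backpropProb)
    # the axonal signal is also picked up by the electrodes flanking the
    # path, at the latency of the nearest path electrode
    halo <- setdiff(unique(unlist(lapply(lat$electrode, gridNeighbors,
                                         grid = grid))), lat$electrode)
    haloLat <- vapply(halo, function(e) {
      d <- electrodeDistance(grid, rep(e, nrow(lat)), lat$electrode)
      lat$latencyMs[which.min(d)]
    }, 0)
    injE <- c(lat$electrode, halo)
    injLat <- c(lat$latencyMs, haloLat)
    injAmp <- c(rep(a$amplitude, nrow(lat)),
                rep(0.8 * a$amplitude, length(halo)))
    for (k in seq_along(injE)) {
      e <- injE[k]
      tFwd <- tr + injLat[k] / 1000
      idx <- as.integer(round(tFwd * fs)) + 1L - attr(axTpl, "peakOffset")
      v[e, ] <- addTemplateAt(v[e, ], axTpl, idx, injAmp[k])
      if (length(bp)) {
        tBwd <- tr[bp] - injLat[k] / 1000
        idxB <- as.integer(round(tBwd * fs)) + 1L - attr(axTpl, "peakOffset")
        v[e, ] <- addTemplateAt(v[e, ], axTpl, idxB, injAmp[k])
      }
    }
    axTruth[[length(axTruth) + 1L]] <-
      list(somaUnit = a$somaUnit, electrodes = lat$electrode,
           arcMm = lat$arcMm, latencyMs = lat$latencyMs,
           velocity = a$velocity, backpropSpikes = bp,
           haloElectrodes = halo)
  }

  lfpTruth <- list()
  for (w in config@lfpWaves) {
    ctr <- pos[w$centerElectrode, ]
    dMm <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2) * 1e-3
    D <- w$maxArea / w$expansionRate
    tOn <- pi * dMm^2 / w$expansionRate  # activation delay per electrode
    act <- which(tOn < D)
    tAx <- (seq_len(nS) - 1L) / fs
    for (t0 in w$onsets) {
      for (e in act) {
        t1 <- t0 + tOn[e]; t2 <- t0 + D
        j <- which(tAx >= t1 & tAx <= t2)
        if (!length(j)) next
        ph <- tAx[j] - t1
        win <- sin(pi * (tAx[j] - t1) / (t2 - t1))^2
        v[e, j] <- v[e, j] + w$amplitude * sin(2 * pi * w$freq * ph) * win
      }
    }
    lfpTruth[[length(lfpTruth) + 1L]] <-
      list(region = w$region, electrodes = act, onsets = w$onsets,
           expansionRate = w$expansionRate, areaMm2 = w$maxArea,
           durationS = D)
  }

  if (config@noiseRms > 0)
    v <- v + matrix(stats::rnorm(nE * nS, 0, config@noiseRms), nE, nS)

  conns <- if (length(config@couplings)) {
    data.frame(
      source = vapply(config@couplings, `[[`, "", "source"),
      target = vapply(config@couplings, `[[`, "", "target"),
      sign = vapply(config@couplings, `[[`, "", "sign"),
      p = vapply(config@couplings, `[[`, 0, "p"))
  } else {
    data.frame(source = character(), target = character(),
               sign = character(), p = numeric())
  }

  rec <- meaRecording(v, grid, fs, meta = list(seed = config@seed))
  truth <- new("GroundTruth", spikeTrains = trains,
               memberships = memberships, connections = conns,
               axon = axTruth, lfp = lfpTruth,
               evokedLabels = evokedLabels)
  list(recording = rec, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
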