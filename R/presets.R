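#' Built-in generator presets
#'
#' Named [SynthConfig-class] fixtures exercising each analysis stage:
#' \describe{
#'   \item{cortical_net}{12 x 12 grid, 5 kHz, 20 s: ten Poisson/bursting
#'     units with directed excitatory couplings inside a 100 ms window.}
#'   \item{drg}{15 x 15 grid, 5 kHz, 20 s: independent units spanning the
#'     firing-frequency bands, no couplings (peripheral-neuron style).}
#'   \item{axon}{2 x 215 grid, 20 kHz, 4 s: one high-rate soma driving a
#'     2.4 mm straight axon at 1.155 m/s with 40% backpropagation.}
#'   \item{organoid}{16 x 16 grid, 5 kHz, 15 s: bursting units with
#'     network-wide co-active epochs.}
#'   \item{slice_lfp}{24 x 24 grid, 1 kHz, 8 s: expanding gamma-band LFP
#'     waves in two regions with partially synchronized onsets.}
#' }
#'
#' @param name preset name
#' @param seed integer RNG seed stored in the config
#' @param ... preset-specific overrides (e.g. `velocity` and
#'   `backpropProb` for "axon")
#' @return a [SynthConfig-class]
#' @export
synthPreset <- function(name = c("cortical_net", "drg", "axon",
                                 "organoid", "slice_lfp"), seed = 1L,
                        ...) {
  name <- match.arg(name)
  switch(name,
    cortical_net = presetCorticalNet(seed),
    drg = presetDrg(seed),
    axon = presetAxon(seed, ...),
    organoid = presetOrganoid(seed),
    slice_lfp = presetSliceLfp(seed)
  )
}

presetCorticalNet <- function(seed) {
  grid <- makeGrid(12, 12)
  pos <- electrodePositions(grid)
  centers <- c(14, 18, 40, 45, 61, 78, 94, 100, 118, 131)
  units <- lapply(seq_along(centers), function(i) {
    firing <- if (i %% 3 == 0)
      list(model = "bursting", burstRate = 0.2, intraRate = 40,
           burstDuration = 0.3, baseRate = 0.3)
    else list(model = "poisson", rate = 0.5 + 0.2 * i)
    unitSpec(paste0("u", i), pos[centers[i], ], footprintRadius = 1.2,
             amplitude = 220, firing = firing)
  })
  couplings <- list(
    couplingSpec("u1", "u2", 0.6),
    couplingSpec("u3", "u4", 0.5),
    couplingSpec("u5", "u6", 0.4),
    couplingSpec("u7", "u8", 0.5, sign = "inhibitory")
  )
  synthConfig(grid, duration = 20, samplingRate = 5000, units = units,
              couplings = couplings, seed = seed)
}

presetDrg <- function(seed) {
  grid <- makeGrid(15, 15)
  pos <- electrodePositions(grid)
  rates <- c(0, 0.05, 0.3, 0.7, 1.5, 3, 7, 12, 0.9, 0.02, 2.2, 0.4)
  centers <- c(17, 21, 40, 48, 95, 100, 112, 123, 170, 187, 203, 214)
  units <- lapply(seq_along(rates), function(i)
    unitSpec(paste0("drg", i), pos[centers[i], ], footprintRadius = 1.5,
             amplitude = 250,
             firing = list(model = "poisson", rate = rates[i])))
  evoked <- list(evokedSpec("drg1", 4, onset = 5),
                 evokedSpec("drg2", 2, onset = 5),
                 evokedSpec("drg10", 5, onset = 5))
  synthConfig(grid, duration = 20, samplingRate = 5000, units = units,
              evoked = evoked, seed = seed)
}

presetAxon <- function(seed, velocity = 1.155, backpropProb = 0.4) {
  grid <- makeGrid(2, 215)
  somaCtr <- electrodePositions(grid)[electrodeIndex(grid, 1, 4), ]
  soma <- unitSpec("soma", somaCtr, footprintRadius = 1.6, amplitude = 520,
                   firing = list(model = "poisson", rate = 15))
  path <- electrodeIndex(grid, rep(1L, 208), 7:214)
  axon <- axonSpec("soma", path, velocity = velocity, amplitude = 40,
                   backpropProb = backpropProb)
  synthConfig(grid, duration = 4, samplingRate = 20000,
              units = list(soma), axons = list(axon), seed = seed)
}

presetOrganoid <- function(seed) {
  grid <- makeGrid(16, 16)
  pos <- electrodePositions(grid)
  centers <- seq(18, 238, by = 22)
  units <- lapply(seq_along(centers), function(i)
    unitSpec(paste0("org", i), pos[centers[i], ], footprintRadius = 1.2,
             amplitude = 300,
             firing = list(model = "bursting", burstRate = 0.15,
                           intraRate = 30, burstDuration = 0.4,
                           baseRate = 0.2)))
  synthConfig(grid, duration = 15, samplingRate = 5000, units = units,
              seed = seed)
}

presetSliceLfp <- function(seed) {
  grid <- makeGrid(24, 24)
  ca3Center <- electrodeIndex(grid, 7, 7)
  ecCenter <- electrodeIndex(grid, 18, 18)
  onsetsCa3 <- c(0.5, 1.6, 2.7, 3.8, 4.9, 6.0, 7.1)  # 7 events in 8 s
  onsetsEc <- c(0.52, 1.62, 2.72, 3.82, 4.92)        # first 5 synchronous
  waves <- list(
    lfpWaveSpec(ca3Center, freq = 60, onsets = onsetsCa3,
                expansionRate = 0.05, maxArea = 0.01, amplitude = 300,
                region = "CA3"),
    lfpWaveSpec(ecCenter, freq = 60, onsets = onsetsEc,
                expansionRate = 0.04, maxArea = 0.008, amplitude = 250,
                region = "EC")
  )
  synthConfig(grid, duration = 8, samplingRate = 1000, noiseRms = 9.43,
              lfpWaves = waves, seed = seed)
}
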