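#' @import methods
NULL

#' ElectrodeGrid: geometry of a rectangular sensing array
#'
#' Describes a regular rectangular lattice of square electrodes. All
#' distances in the package derive from the stored electrode centers.
#' Indexing is row-major and 1-based in R: electrode `i` sits at
#' `row = (i - 1) %/% nCols + 1`, `col = (i - 1) %% nCols + 1`.
#'
#' @slot nRows,nCols integer, lattice dimensions.
#' @slot pitch numeric, center-to-center distance in micrometers
#'   (electrode side + separation).
#' @slot electrodeSide numeric, side of the square electrode in micrometers.
#' @slot positions numeric matrix (nRows*nCols) x 2 of electrode center
#'   (x, y) coordinates in micrometers, origin at the first electrode.
#'
#' @seealso [makeGrid()], [gridNeighbors()], [electrodeDensity()]
#' @export
setClass("ElectrodeGrid",
  representation(
    nRows = "integer",
    nCols = "integer",
    pitch = "numeric",
    electrodeSide = "numeric",
    positions = "matrix"
  )
)

setValidity("ElectrodeGrid", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (!(object@pitch >= object@electrodeSide && object@electrodeSide > 0))
    msg <- c(msg, "require pitch >= electrodeSide > 0")
  n <- object@nRows * object@nCols
  if (nrow(object@positions) != n || ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be an (nRows*nCols) x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' MEARecording: a multichannel voltage recording on an electrode grid
#'
#' Container for an electrodes x samples voltage matrix in microvolts with
#' its sampling rate (Hz) and [ElectrodeGrid-class] geometry.
#'
#' @slot grid [ElectrodeGrid-class].
#' @slot samplingRate numeric, Hz.
#' @slot voltage numeric matrix, electrodes x samples, microvolts.
#' @slot meta list of free-form metadata (e.g. block structure, labels).
#' @export
setClass("MEARecording",
  representation(
    grid = "ElectrodeGrid",
    samplingRate = "numeric",
    voltage = "matrix",
    meta = "list"
  )
)

setValidity("MEARecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@voltage) != nElectrodes(object@grid))
    msg <- c(msg, "voltage must have one row per electrode")
  if (!all(is.finite(object@voltage)))
    msg <- c(msg, "voltage must be finite")
  if (length(msg)) msg else TRUE
})

#' RegionMask: a labelled set of electrodes
#'
#' @slot label character region name.
#' @slot electrodes integer vector of electrode indices.
#' @export
setClass("RegionMask",
  representation(label = "character", electrodes = "integer")
)

#' Scalogram: continuous wavelet transform magnitude
#'
#' Time-frequency magnitude map |W(b, a)| from the complex Morlet transform,
#' scale a = 1/frequency. `coi` flags time-frequency cells inside the cone
#' of influence (edge-affected by the wavelet support under zero padding).
#'
#' @slot frequencies numeric vector, Hz.
#' @slot times numeric vector, s.
#' @slot magnitude numeric matrix, frequencies x times.
#' @slot coi logical matrix, same shape; TRUE where edge-affected.
#' @slot fb,fc numeric, Morlet bandwidth and center-frequency parameters.
#' @export
setClass("Scalogram",
  representation(
    frequencies = "numeric", times = "numeric",
    magnitude = "matrix", coi = "matrix",
    fb = "numeric", fc = "numeric"
  )
)

setValidity("Scalogram", function(object) {
  ok <- nrow(object@magnitude) == length(object@frequencies) &&
    ncol(object@magnitude) == length(object@times) &&
    all(object@magnitude >= 0)
  if (ok) TRUE else "magnitude must be non-negative, frequencies x times"
})

#' NeuronUnitSet: merged single-neuron units
#'
#' The result of electrode-to-neuron merging: each unit is a connected set
#' of member electrodes, a centroid (center of gravity of member electrode
#' positions, micrometers), and a deduplicated spike train (seconds).
#'
#' @slot units list; each element a list with fields `id`, `electrodes`
#'   (integer), `centroid` (numeric length 2), `spikes` (numeric, sorted s),
#'   `rate` (Hz).
#' @slot duration numeric, recording duration in seconds.
#' @slot grid [ElectrodeGrid-class] the units live on.
#' @export
setClass("NeuronUnitSet",
  representation(units = "list", duration = "numeric", grid = "ElectrodeGrid")
)

setValidity("NeuronUnitSet", function(object) {
  for (u in object@units) {
    if (!all(c("id", "electrodes", "centroid", "spikes", "rate") %in% names(u)))
      return("each unit needs id, electrodes, centroid, spikes, rate")
    if (is.unsorted(u$spikes, strictly = FALSE))
      return("unit spike times must be sorted")
  }
  TRUE
})

#' ConnectivityResult: surrogate-calibrated directed connectivity
#'
#' Directed synchronized-spike Z-score matrix between units, with the
#' surrogate provenance needed to reproduce it. Entry (i, j) quantifies
#' i -> j coupling: the real count of j-spikes within the coincidence
#' window after each i-spike, standardized by ISI-shuffle surrogates.
#'
#' @slot unitIds character vector.
#' @slot real numeric matrix of real synchronized-spike counts.
#' @slot surrogateMean,surrogateSD numeric matrices over the surrogate set.
#' @slot z numeric matrix; NA where the surrogate SD is zero and the real
#'   count differs from the surrogate value.
#' @slot classification character matrix in {"excitatory","inhibitory","none"}.
#' @slot nSurrogates integer.
#' @slot window numeric, coincidence window in seconds.
#' @slot seed integer RNG seed used for the surrogates.
#' @export
setClass("ConnectivityResult",
  representation(
    unitIds = "character",
    real = "matrix", surrogateMean = "matrix", surrogateSD = "matrix",
    z = "matrix", classification = "matrix",
    nSurrogates = "integer", window = "numeric", seed = "integer"
  )
)

#' ConductionPath: a tracked axonal propagation front
#'
#' Time-ordered propagation front from spike-triggered-average maps:
#' per 0.1 ms frame the firing electrode farthest from the soma centroid,
#' with the cumulative straight-line distance between consecutive selected
#' electrodes. Conduction velocity is the least-squares slope of cumulative
#' distance (mm) against time (ms), i.e. m/s.
#'
#' @slot direction "forward" or "backward".
#' @slot times numeric, frame times in ms relative to the soma spike.
#' @slot electrodes integer, selected electrode per frame.
#' @slot cumDist numeric, cumulative distance in mm (non-decreasing).
#' @slot velocity numeric, least-squares slope in m/s (NA if unfit).
#' @slot r2 numeric, coefficient of determination of the fit.
#' @slot endpointVelocity numeric, total distance / total |time| in m/s.
#' @export
setClass("ConductionPath",
  representation(
    direction = "character",
    times = "numeric", electrodes = "integer", cumDist = "numeric",
    velocity = "numeric", r2 = "numeric", endpointVelocity = "numeric"
  )
)

setValidity("ConductionPath", function(object) {
  msg <- character()
  if (!object@direction %in% c("forward", "backward"))
    msg <- c(msg, "direction must be forward or backward")
  if (length(object@cumDist) && any(diff(object@cumDist) < -1e-12))
    msg <- c(msg, "cumulative distance must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' SynthConfig: synthetic-recording generator configuration
#'
#' Holds the full description of a simulated recording: grid, duration,
#' sampling rate, additive Gaussian noise level, unit specifications
#' (centroid, footprint, amplitude, firing model), directed couplings,
#' axon paths, LFP waves, evoked-response templates and the RNG seed.
#' Defaults follow the recording conditions the analyses assume
#' (9.43 uV rms noise, 100 ms coupling window, ~1 m/s conduction).
#'
#' @slot grid [ElectrodeGrid-class].
#' @slot duration numeric, s.
#' @slot samplingRate numeric, Hz.
#' @slot noiseRms numeric, uV.
#' @slot units,couplings,axons,lfpWaves,evoked lists of spec lists; see
#'   [unitSpec()], [couplingSpec()], [axonSpec()], [lfpWaveSpec()],
#'   [evokedSpec()].
#' @slot seed integer RNG seed.
#' @export
setClass("SynthConfig",
  representation(
    grid = "ElectrodeGrid", duration = "numeric", samplingRate = "numeric",
    noiseRms = "numeric", units = "list", couplings = "list",
    axons = "list", lfpWaves = "list", evoked = "list", seed = "integer"
  )
)

#' GroundTruth: what the generator actually injected
#'
#' @slot spikeTrains named list of numeric vectors, true spike times (s)
#'   per unit.
#' @slot memberships named list of integer vectors, true member electrodes
#'   per unit.
#' @slot connections data.frame (source, target, sign, p), true couplings.
#' @slot axon list per axon: electrodes, arcLength (mm), latency (ms),
#'   velocity, backpropSpikes (indices of soma spikes with backprop).
#' @slot lfp list per wave: region electrodes, onset times, expansion rate.
#' @slot evokedLabels named integer vector, true cluster template per unit.
#' @export
setClass("GroundTruth",
  representation(
    spikeTrains = "list", memberships = "list", connections = "data.frame",
    axon = "list", lfp = "list", evokedLabels = "integer"
  )
)
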