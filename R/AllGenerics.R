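#' Number of electrodes in a grid or recording
#' @param x an [ElectrodeGrid-class] or [MEARecording-class]
#' @return integer count
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))

#' Electrode center positions in micrometers
#' @param x an [ElectrodeGrid-class] or [MEARecording-class]
#' @return numeric matrix n x 2
#' @export
setGeneric("electrodePositions",
           function(x) standardGeneric("electrodePositions"))

#' Voltage matrix accessor (electrodes x samples, microvolts)
#' @param x an [MEARecording-class]
#' @export
setGeneric("voltage", function(x) standardGeneric("voltage"))

#' Sampling rate accessor (Hz)
#' @param x an [MEARecording-class]
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Electrode grid accessor
#' @param x an object carrying an [ElectrodeGrid-class]
#' @export
setGeneric("electrodeGrid", function(x) standardGeneric("electrodeGrid"))

#' Recording duration in seconds
#' @param x an [MEARecording-class] or [NeuronUnitSet-class]
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Number of units in a unit set
#' @param x a [NeuronUnitSet-class]
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Spike trains of a unit set
#' @param x a [NeuronUnitSet-class]
#' @return named list of sorted numeric spike-time vectors (s)
#' @export
setGeneric("spikeTrains", function(x) standardGeneric("spikeTrains"))

#' Unit centroids (micrometers)
#' @param x a [NeuronUnitSet-class]
#' @return numeric matrix nUnits x 2
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' Z-score matrix accessor
#' @param x a [ConnectivityResult-class]
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
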