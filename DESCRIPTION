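Package: hdmea
Title: Single-Neuron Analysis of High-Density CMOS Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for high-density CMOS microelectrode array (MEA)
    field-potential recordings at single-neuron resolution: electrode-grid
    geometry and recording containers, block-wise detrending and spike/LFP-band
    filtering, complex Morlet wavelet scalograms, threshold spike detection
    with cosine-similarity soma merging, network and Poisson-Surprise burst
    analytics with vehicle-normalized parameter tables, ISI-shuffle surrogate
    Z-score functional connectivity, axonal conduction-front tracking with
    velocity fitting and backpropagation statistics, LFP propagation area and
    inter-region synchrony, and Ward clustering of evoked responses. Includes
    a synthetic-recording generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
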