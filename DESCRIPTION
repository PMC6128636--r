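Package: fncch
Title: Excitatory and Inhibitory Functional Connectivity from Multi-Electrode
    Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers directed excitatory and inhibitory functional connectivity
    from multi-electrode array (MEA) spike-train recordings using filtered and
    normalized cross-correlation histograms (FNCCH). The signed extreme of the
    mean-subtracted correlogram classifies each putative link as excitatory
    (peak) or inhibitory (trough); a spatio-temporal physiological filter and
    sign-specific hard thresholds prune the resulting connectivity matrix.
    Includes an Izhikevich spiking-network simulator with spike-timing
    dependent plasticity for generating ground-truth networks, ROC/MCC scoring
    of inferred links against the known wiring, and graph-topology analysis
    (clustering coefficient, characteristic path length, small-world index
    against random surrogates, rich-club curves, electrode decimation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
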