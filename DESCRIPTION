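Package: colorspike
Title: Spiking-Network Model of Color-Selective Map Formation in Early
    Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the self-organization of color-selective neuronal
    clusters in primary visual cortex. RGB patches drive trichromatic
    photoreceptor spike trains that feed luminance and red-green /
    blue-yellow opponent channels of the lateral geniculate nucleus, which
    project topographically onto layered V1 populations of single-compartment
    Hodgkin-Huxley neurons with conductance synapses, transmission delays
    and Mexican-hat lateral connectivity. Feed-forward weights are learned
    with spike-timing-dependent plasticity under per-projection weight
    normalization. Includes the accompanying analysis suite (spatial
    clustering coefficient of stimulus-evoked rates, single-cell and
    Bayesian multiple-cell stimulus information, ON/OFF and color-opponent
    cell selection), simplified opponent ON/OFF microcircuits, a synthetic
    color-patch generator, experiment presets and figure recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
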