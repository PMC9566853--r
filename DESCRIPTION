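Package: spikecircuit
Title: Circuit Analysis of Extracellular Spike Trains and Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded cortical single
    units and local field potentials: waveform-based classification of
    putative pyramidal cells and fast-spiking interneurons, optogenetic
    tagging by interspike-interval shuffling, gamma-band spectral analysis
    and spike-phase coupling with pairwise phase consistency, detection of
    monosynaptic pyramidal-to-interneuron connections from cross-correlograms
    with spike-transmission probability, presynaptic synchrony and resonance
    analysis, and cell-assembly detection via the Marchenko-Pastur law and
    independent component analysis. Includes a synthetic-session generator
    that plants known ground truth (connections, phase locking, assemblies,
    light-driven units) so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'core-io.R'
    'unit-classify.R'
    'lfp-spectral.R'
    'phase-coupling.R'
    'monosynaptic.R'
    'synchrony.R'
    'assemblies.R'
    'synthetic-data.R'
    'stats-report.R'
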