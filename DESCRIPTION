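Package: spikePID
Title: Transfer Entropy Networks and Partial Information Decomposition for
    Spike Trains
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying information transmission and computation in
    networks of spiking neurons. Spike trains are discretized into binary
    state series, directed effective connectivity is inferred with transfer
    entropy and spike-jitter surrogate significance testing, and the
    information two input neurons carry about a receiver is dissected into
    synergistic, redundant, and unique parts with the partial information
    decomposition (Imin redundancy). Includes degree-versus-synergy
    correlation analyses with shuffle nulls and skew tests, information-gain
    bounds on higher-order synergy, log-normal connection-weight fits, a
    synthetic spike-train generator with plantable motifs and couplings, and
    a two-layer probabilistic feedforward model with Hebbian and modified
    Hebbian rewiring rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'binning.R'
    'infotheory.R'
    'pid.R'
    'synthetic-data.R'
    'io.R'
    'network-inference.R'
    'degree-computation.R'
    'feedforward-model.R'
    'lattice-search.R'
    'cli.R'
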