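Package: phagelm
Title: LSTM-Based Antibody Sequence Generation and Prioritization from
    Phage Display Panning Data
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for likelihood-guided affinity maturation of antibodies
    selected by phage display. Models combinatorial libraries built from
    IUPAC degenerate codons, processes NGS-like reads into counted
    diversified-residue vectors per panning round, computes repertoire
    statistics and per-residue enrichment ratios, trains an autoregressive
    LSTM language model over the diversified positions, samples new
    candidate sequences with temperature-controlled softmax decoding, and
    prioritizes them by negative log-likelihood. A synthetic panning
    simulator with a known position-weight binding model makes every stage
    testable by parameter recovery without access to real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
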