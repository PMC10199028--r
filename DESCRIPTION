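Package: mfnets
Title: Community Detection in Multi-Frequency Multilayer Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds and analyses multilayer functional connectivity networks
    in which each layer is a frequency band. Intra-layer edges are
    time-frequency phase locking values (PLV) and inter-layer edges are
    direct phase-amplitude coupling (dPAC) estimates, both derived from a
    reduced-interference Rihaczek time-frequency distribution of
    trial-epoched multichannel recordings. Provides a multilayer modularity
    quality function with a layer-strength-preserving configuration null
    model, a greedy multilevel (Louvain/Leiden family) maximizer, surrogate
    based selection of the resolution and inter-layer scale parameters,
    group-level consensus via co-clustering matrices and spectral clustering
    on multi-layer graphs (SC-ML), and partition/graph comparison metrics
    (NMI, Jensen-Shannon graph distance). Includes generators for
    planted-partition multilayer networks and oscillatory epochs with
    planted phase locking and phase-amplitude coupling, so that every stage
    can be validated without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
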