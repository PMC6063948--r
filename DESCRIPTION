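Package: netdim
Title: Network Dimension from Ball-Volume Scaling Laws
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterises the local structure of complex networks through
    ball-volume profiles: the number of nodes reachable within a radius r
    (edge count or summed edge weight) is aggregated over sampled centres and
    fitted by a polynomial volume law |B(r)| = 1 + k*r^d, whose exponent d
    acts as a dimension of the network, or by an exponential alternative.
    Includes the Mocnik spatial-network generator and its hierarchical and
    weighted-hierarchical extensions for studying how global shortcut
    structure perturbs the law, a spatial box-counting (Minkowski-Bouligand)
    dimension estimator for comparison, readers for plain edge lists with
    coordinate sidecars, and a public-transport network builder from GTFS
    schedule tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
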