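Package: tempcomm
Title: Community Detection and Tracking in Dynamic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage community detection for dynamic networks observed as
    an ordered series of snapshots. Stage one partitions each snapshot
    independently by Louvain modularity optimisation and stitches the
    resulting groups into persistent communities by Jaccard-index matching
    with a bounded look-back. Stage two assigns node trajectories either by
    a cost-minimising home-community model (switch, visit and absence costs
    minimised by dynamic programming) or by a sub-community model that
    groups nodes sharing an identical community-membership pattern.
    Includes readers for dynamic GEXF and per-snapshot edge lists, a
    planted-partition generator for benchmarking, node promiscuity
    statistics, threshold sweeps, and CSV/HTML reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    mclust,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
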