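Package: fragsig
Title: Fragment-Based Shape Signatures for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts small molecules into fragment-partitioned shape and
    electrostatic histogram descriptors ("shape signatures") by interior
    ray-tracing of a triangulated solvent-excluded molecular surface, and
    compares and ranks molecules through connectivity-consistent fragment
    mappings scored with a segment-count-weighted L1 histogram distance.
    Includes ring-system-based automatic fragmentation of the molecular
    graph, a grid-accelerated billiard ray tracer, 1D and 2D (shape by
    electrostatic potential) descriptors with reduced and sign-inverted
    variants, an admissible lower-bound prefilter for library screening,
    and a signature database with hit-list ranking and merging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tibble,
    bio3d,
    stats,
    utils,
    tools,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    pROC,
    withr,
    knitr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
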