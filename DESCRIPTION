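Package: ultranet
Title: Subdominant Ultrametrics and Ultrametric Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the subdominant ultrametric of a dissimilarity matrix
    together with its ultrametric network -- the graph whose edges are the
    union of the edge sets of all minimum spanning trees -- by a Prim-style
    incremental algorithm running in optimal O(n^2) time. Supports
    delta-relaxed networks that admit edges within a tolerance of their
    ultrametric value, insertion of artificial median (Steiner) vertices to
    resolve heavy triangles, and construction of weighted stepwise distances
    from STR (microsatellite) haplotype tables. Brute-force reference
    implementations (Floyd-Warshall bottleneck closure, exhaustive
    spanning-tree enumeration, simple-path search) are shipped for
    cross-validation on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
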