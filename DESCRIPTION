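Package: sbgnpd
Title: Compound-Graph Modelling and Complexity Management of SBGN Process Description Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models Systems Biology Graphical Notation Process Description
    (SBGN-PD) maps as compound graphs (complexes and compartments nesting to
    arbitrary depth) and implements domain-aware complexity-management
    operations: focusing on a node group ("Show Selected") and ignoring a node
    group ("Hide Selected") via closure algorithms that always yield valid,
    complete sub-maps. Includes lossless SBGN-ML reading and writing, a
    five-invariant sub-map validity checker, a structural well-formedness
    validator, a seeded generator of random structurally valid maps, a
    nesting-preserving force-directed layout, SVG export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
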