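Package: protgap
Title: Spatial Null Models and Tiered Coverage Analysis for Protected-Area Gap Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well a protected-area network covers
    endangered species ranges. Implements an ecoregion-stratified spatial
    null model that re-places protected-area polygons at random positions
    and orientations within their ecoregion and classifies each ecoregion
    as better, equal or worse than random by a one-species margin; a tiered
    land-designation cascade (highly protected, easement, USFS/BLM, other
    federal, state, undeveloped private) reporting the percent of each
    species' range per tier against a 30 percent adequacy threshold; a
    landcover-based undeveloped-private-land classification; and a seeded
    synthetic-world generator with ground-truth bookkeeping so the whole
    pipeline is testable without external geodatabases. Geometry is handled
    by a built-in planar overlay engine on convex decompositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
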