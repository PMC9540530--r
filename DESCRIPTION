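Package: faunadiv
Title: Losses, Gains, and Net Change in Regional Mammal Taxonomic,
    Phylogenetic, and Functional Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how regional mammal faunas have changed
    between a mid-Holocene baseline (8000 BP) and the present day, and how
    much diversity future reintroductions could restore. Species pools per
    region are reconstructed from status categories (persisting, extirpated,
    regained, colonist, introduced, plus a future-potential overlay), and
    three scaled diversity metrics are computed for each assemblage:
    species richness divided by the continental pool, Faith's phylogenetic
    diversity averaged over an ensemble of dated trees and rescaled by the
    total tree length, and functional richness as the convex-hull volume of
    the assemblage in a principal-coordinates trait space built from
    weighted Gower dissimilarities, rescaled by the all-species hull. Net
    change per region is decomposed additively into a loss term
    (extirpations) and a gain term (introductions, reintroductions, and
    range expansions). Includes a d-dimensional convex hull and polytope
    intersection engine, a synthetic-data generator for complete
    tree/trait/status bundles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    picante,
    cluster,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
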