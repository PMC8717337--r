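Package: phylocomgrad
Title: Phylogenetic Community Structure Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community phylogenetics toolkit for presence-absence data along
    edaphic gradients. Computes per-site alpha metrics (species richness,
    root-excluded Faith's PD, mean pairwise distance, mean nearest taxon
    distance, variance of pairwise distances), pairwise beta metrics (Sorensen
    and PhyloSor dissimilarities), and standardized effect sizes under
    independent-swap community nulls and tip-shuffle phylogeny nulls, with
    aggregation across a posterior sample of trees. Includes PCoA ordination
    with environmental vectors, linear and quadratic gradient regressions, a
    synthetic-data generator that emulates a stratified soil-gradient study
    design with phylogenetically structured edaphic niches, and a reproducible
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    withr
Config/testthat/edition: 3
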