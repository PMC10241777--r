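Package: driftline
Title: Ocean-Current Dispersal Simulation and Clonal Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dual pipeline for testing whether ocean currents can explain
    the genetic structure of passively dispersed coastal species. One side
    simulates passive surface drift of propagules released daily from
    habitat sites over gridded daily current fields (bilinear velocity
    interpolation, hourly stepping, a maximum pelagic duration, and
    beached/lost/expired fate rules), aggregates trajectories into
    asymmetric site-to-site connectivity probability matrices, and closes
    them over multiple generations with Floyd-Warshall stepping-stone
    probabilities on -log-transformed edge weights. The other side analyses
    clonal multilocus microsatellite genotypes: multilocus genotype
    discrimination with the Psex criterion, clonal richness R = (G-1)/(N-1),
    rarefied allelic richness and private alleles, Nei gene diversity,
    observed heterozygosity, FIS, and pairwise Weir-Cockerham FST. A
    concordance layer compares genetic differentiation with modelled
    connectivity through permutation (Mantel) tests. Synthetic generators
    for velocity fields, occurrence records and clonal genotype samples
    with known ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
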