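Package: sibpop
Title: Spatial Iterative Bifurcation and Genetic Structure for
    Continuously Distributed Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes population genetic structure in wide-ranging,
    continuously distributed species from codominant multi-locus genotypes
    (microsatellites) with per-individual spatial coordinates.  Provides
    spatial sample thinning by hierarchical clustering, a maximum-likelihood
    admixture clusterer with replicate alignment and Evanno-style K
    diagnostics, thin-plate-spline interpolation of cluster memberships with
    isocline-based retention, a spatial iterative bifurcation process (SIBP)
    that resolves nested subpopulation centers, kernel-density center
    polygons, and diversity, divergence (Weir-Cockerham theta, Jost's D),
    Hardy-Weinberg/gametic-disequilibrium and Mantel-correlogram statistics.
    Includes seeded hierarchical-drift and stepping-stone simulators of
    spatial microsatellite data, plus GENEPOP, STRUCTURE and CSV input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
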