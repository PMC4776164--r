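Package: rivst
Title: Spatio-Temporal Analysis of River Bacterioplankton Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for partitioning spatial versus seasonal
    variation in river bacterioplankton community composition. Implements a
    high-dimensional test contrasting per-taxon residual sums of squares under
    seasonal and spatial one-way ANOVA groupings (with asymptotic, Monte-Carlo
    and permutation p-values), together with the surrounding community-ecology
    toolkit: Shannon and Chao1 diversity with rarefaction, Dice, Bray-Curtis
    and unweighted UniFrac distances, principal coordinates analysis,
    environmental PCA and average-linkage clustering, BIOENV environmental
    subset selection, ANOSIM, and moving-window analysis of DGGE fingerprints.
    A seeded synthetic-community generator emulating a multi-season,
    multi-site river transect design makes the whole pipeline testable
    without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
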