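Package: burstlab
Title: Morphological Disparity and Evolutionary Rates Through Time from
    Discrete Characters and Fossil Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for macroevolutionary analyses of clades known from
    fossils: reads discrete morphological character matrices (NEXUS),
    converts them to inter-taxon distance matrices (raw and generalised
    Euclidean, Gower, maximum observable rescaled distances), ordinates
    morphospaces by principal coordinates analysis with negative-eigenvalue
    corrections, computes time-binned disparity with bootstrap confidence
    intervals and rarefaction, tests morphospace separation (pairwise
    PERMANOVA) and disparity differences (Welch t-tests) with false
    discovery rate control, time-scales fossil phylogenies (Bayesian
    outgroup node dating and minimum branch lengths), estimates per-bin
    rates of discrete character evolution with Poisson likelihood-ratio
    classification, and fits variable-rates Brownian-motion models to
    continuous traits by reversible-jump MCMC with stepping-stone marginal
    likelihoods and Bayes factors. A synthetic-data module generates
    birth-death trees with extinct tips, Mk characters with realistic
    missingness, stratigraphic ranges and traits with planted rate shifts,
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    jsonlite
Config/testthat/edition: 3
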