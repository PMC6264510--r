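Package: kleptopop
Title: Population Genetic Structure of Group-Living and Solitary
    Kleptoparasitic Spiders from Dominant Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for binary dominant-marker (AFLP) data from
    kleptoparasitic spiders sampled from host webs along a transect.
    Implements marker and web filtering, Jaccard dissimilarity with
    three-dimensional nonmetric multidimensional scaling, average-silhouette
    selection of the number of genetic clusters, a haploid admixture Gibbs
    sampler with Evanno delta-K model selection, band-frequency-corrected
    pairwise relatedness with per-web permutation tests, and multivariate
    genetic spatial autocorrelation correlograms with bootstrap confidence
    intervals and permutation nulls.  A synthetic colony simulator with
    known sib-family structure, dispersal limitation and two-source
    admixture provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    cluster,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
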