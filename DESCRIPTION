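Package: ldnescan
Title: Effective Population Size from Linkage Disequilibrium Under Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of diploid populations
    with selection, linkage, mutation, partial self-fertilisation and
    arbitrary census trajectories, together with three families of effective
    population size (Ne) estimators: linkage-disequilibrium-based (pairwise
    r2 binned by recombination distance, Sved-type inversion and the
    1/(2c)-generations time mapping), diversity-based (pi/(4*mu)) and
    pedigree/analytic (variance of family sizes, partial selfing).  Includes
    a windowed genome-scan stage (2 cM regions, per-window diversity and
    regional Ne, Spearman correlations against recombination rate and
    annotation tracks) and generators for synthetic human-like genotype,
    genetic-map and annotation-track inputs, so that the sensitivity of each
    estimator to background selection and selective sweeps can be studied at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
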