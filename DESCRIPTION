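Package: ldnesim
Title: Population-Structure Biases in Linkage-Disequilibrium Estimates of
    Recent Historical Effective Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time diploid Wright-Fisher simulation of structured
    populations (admixture, island-model migration, source-sink gene flow,
    and balanced chromosomal inversions) together with a moment-based
    estimator of the recent historical effective population size (Ne) from
    genetic-distance-binned linkage disequilibrium between SNPs. Includes
    expected-NeVk reference baselines, PLINK PED/MAP and VCF export of
    sampled genotypes, principal-component screening for population
    structure with group-restricted re-estimation, and masking of inversion
    regions, so that the bias signatures created by each kind of population
    structure -- and the remedies that remove them -- can be studied end to
    end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
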