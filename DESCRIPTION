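Package: ancfreq
Title: Local Ancestry Frequency Inference in Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population-level local ancestry frequencies from
    un-phased SNP genotypes in admixed populations using a continuous
    correlated beta process model. Discriminant analysis of SNP windows,
    anchored by reference panels from the two source populations and
    simulated inter-population heterozygotes, yields per-locus likelihoods
    of individual ancestry dosage; Gibbs sampling with a squared-exponential
    kernel shares latent ancestry counts across linked loci to estimate
    autocorrelated ancestry frequencies along chromosomes. Includes a
    tract-based Wright-Fisher admixture simulator with allele-frequency
    drift, underdominant selection and migration, convergence diagnostics,
    accuracy metrics against simulated truth, and extraction of regions of
    excess ancestry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse,
    withr
Config/testthat/edition: 3
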