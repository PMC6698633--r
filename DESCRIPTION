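Package: rhizopop
Title: Population Genetics and Demographic Inference for Rhizobial MLST Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multilocus sequence typing (MLST) data from
    haploid bacterial populations such as black locust-associated rhizobia:
    per-locus diversity and neutrality statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, Fu's Fs, Nei-Gojobori pN/pS and dN/dS),
    multilocus linkage disequilibrium (index of association with permutation
    tests on clone-corrected data) and a parsimony-based homoplasy index,
    minimum spanning networks over multilocus haplotypes, mismatch-distribution
    analysis with constant-size, sudden-demographic-expansion and
    spatial-expansion models (least-squares fitting, SSD and raggedness
    goodness-of-fit with parametric bootstrap), a native multi-deme structured
    coalescent simulator with divergence events, ghost demes, growth, migration
    and infinite-sites mutation, and approximate Bayesian computation (ABC)
    model choice and parameter estimation with rejection sampling, GLM marginal
    densities, Bayes factors, and full validation (type I and II error on
    pseudo-observed data sets, posterior predictive checks, posterior-quantile
    coverage). Includes a synthetic-data generator emulating a three-clade,
    multi-locus study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
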