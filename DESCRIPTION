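Package: markerstruct
Title: Comparing Genetic Structure and Diversity Between SNP and
    Microsatellite Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative assessment of population genetic
    structure and diversity between biallelic SNP panels and multiallelic
    microsatellite panels genotyped on the same individuals or localities.
    Implements DArT-style SNP quality filtering with a per-step audit trail,
    Bayesian admixture-model clustering with correlated allele frequencies
    (Gibbs sampling with alpha and lambda estimation), K-selection
    diagnostics (Gelman-Rubin, Pr[X|K], Evanno's delta-K, a parsimony
    index), CLUMPP-style Q-matrix alignment and symmetric similarity
    coefficients across replicate runs and marker types, a coefficient of
    admixture, standardized multilocus heterozygosity with spatial gradient
    models, and a paired-marker genotype simulator with known admixture
    structure and a latitudinal diversity cline for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
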