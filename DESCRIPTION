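Package: prebreedsim
Title: Stochastic Simulation of Genomic Pre-Breeding Programs for Maize
    Landraces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the initiation and improvement of a maize
    pre-bridging germplasm from landrace accessions using genomic
    selection. Founder haplotypes are drawn from a coalescent model with
    recombination, landrace accessions are assembled at a target
    within-accession inbreeding level, and an elite hybrid enriched for
    favorable QTL alleles is bred by truncation selection. Three designs
    for initiating the germplasm (from selected landrace seeds, their
    doubled haploids, or landrace x elite testcrosses) are evaluated over
    a factorial grid of genetic and logistical design factors, with
    genotyping-by-sequencing dosage genotypes, ridge-regression (RR-BLUP)
    prediction, recurrent selection of a synthetic population, stage
    metrics (genetic merit, prediction accuracy, identity-by-descent
    segment kinship, heterozygosity), marginal linear-model summaries,
    and significance-gated regression trees for decision support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: python (>= 3.8) with msprime and numpy, available on
    the PATH, for coalescent founder simulation
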