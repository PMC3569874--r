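Package: rvburden
Title: Gene-Based Rare-Variant Burden Tests for Typed and Imputed
    Genotypes, with a Coalescent Power-Simulation Framework
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests for association of quantitative and binary traits with
    accumulations of minor alleles at rare variants (minor allele frequency
    below 1%) within genes or other functional units.  The burden of rare
    variation carried by each individual is summarised as the proportion of
    successfully assayed rare variants at which they carry at least one
    minor allele, and tested in a generalised linear model whose likelihood
    contributions are weighted by per-individual call rates, via a one
    degree-of-freedom likelihood-ratio test.  Imputed variants enter the
    test through their posterior genotype probabilities (SNPTEST/IMPUTE GEN
    format) and are screened by an IMPUTE-style info score.  The package
    also provides a genome-wide scan driver (genomic-control inflation
    factor, Bonferroni thresholds, conditional adjustment for a lead SNP,
    Manhattan/QQ table export) and a coalescent simulation framework that
    compares the power of four strategies for assaying rare variation:
    re-sequencing, reference-panel genotyping, GWAS-chip genotyping, and
    GWAS-chip genotyping supplemented by imputation under a haploid
    Li-Stephens hidden Markov model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with numpy and msprime, for coalescent
    population simulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
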