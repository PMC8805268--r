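Package: epikpc
Title: Gene-Level Epistasis Detection with Diffusion Kernel Principal Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene-gene interactions (statistical epistasis) from GWAS
    genotype data. SNPs mapped to the same gene are connected by their bivariate
    synergy with the phenotype; a diffusion kernel on the resulting graph is
    combined with the genotypes into a per-gene sample kernel whose first kernel
    principal component summarises the gene with one score per individual. Gene
    summaries enter a semi-parametric Bayesian regression with spike-and-slab
    priors, and genes and gene pairs are ranked by Posterior Inclusion
    Probability. Includes k-nearest-neighbour genotype imputation, population
    structure correction, within-gene network statistics, a gene-level epistasis
    network exporter, and a synthetic-study generator with planted main and
    epistatic effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
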