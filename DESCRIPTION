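Package: clonescope
Title: Single-Cell Clonal Diversity and Evolution Analysis for Leukemia
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring clonal diversity and evolution of cancer
    cell populations at single-cell resolution. Implements unique molecular
    identifier (UMI) consensus calling and tumor/normal somatic testing for
    error-corrected sequencing, per-cell genotyping quality estimators
    (allelic dropout, germline recall, linked-read precision, false
    heterozygous rate), mirrored B-allele-frequency windowed copy-number
    calling with ROC evaluation, somatic-SNV phylogeny reconstruction with
    bootstrap support and Poisson-branch time calibration, generalized
    skyline population-size reconstruction, Blomberg's-K phenotype
    heritability, Wright-Fisher clone-dynamics inference by approximate
    Bayesian computation, SBS96 mutational-signature fitting and de novo
    extraction, hierarchical clustering of treatment-response variant
    frequencies, and emergent-clone detection. A synthetic-data generator
    reproduces the statistical structure each stage assumes (clone trees
    with Poisson mutation accumulation, whole-genome-amplification allelic
    dropout and allelic imbalance, hemizygous-deletion BAF shifts, UMI read
    families, Brownian-motion phenotypes) so the whole pipeline is
    exercisable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
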