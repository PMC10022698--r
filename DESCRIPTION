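Package: indelkit
Title: Forensic Statistics and Population Structure for Biallelic InDel Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing panels of biallelic insertion/deletion
    (InDel) markers in forensic genetics. Computes per-locus forensic
    efficiency parameters (allele frequencies, observed and unbiased expected
    heterozygosity, polymorphism information content, match probability,
    power of discrimination, probability of paternity exclusion) and their
    panel-level combined values in log/complement space; performs exact and
    Monte Carlo Hardy-Weinberg tests and EM-based linkage-disequilibrium
    estimation from unphased genotypes; measures population differentiation
    (Nei's DA distance, Weir-Cockerham and Hudson FST) and infers structure
    (neighbor-joining trees, allele-frequency PCA, an admixture model fitted
    by EM). Includes seeded synthetic-data generators and a reconstruction of
    exact genotype counts from published per-locus summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
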