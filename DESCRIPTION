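Package: teapop
Title: Population Genetics and Metabolite GWAS for Clonally Bred Tea Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for RNA-seq derived genotype collections of tea
    (Camellia sinensis) and similar outcrossing perennial crops: a six-step
    variant quality-control cascade with per-site statistics (MAF, missingness,
    heterozygosity, polymorphic information content), likelihood-based parentage
    assignment with simulation-calibrated confidence and a multi-marker-set
    consensus rule, linkage-disequilibrium decay statistics with a half-maximum
    decay distance, kinship-corrected mixed-model association scans for
    metabolite phenotypes with effective-marker significance thresholds and
    LD-based QTL clumping, and multi-SNP genotype-class analysis (ANOVA, Tukey
    post-hoc letters, Fisher-exact subpopulation enrichment). Includes a
    synthetic-data generator producing pedigreed, admixed, LD-structured
    populations with planted metabolite QTLs so every stage is testable against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
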