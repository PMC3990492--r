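Package: lancsv
Title: Local Ancestry Inference from Continent-Specific Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers local ancestry in sequenced admixed genomes from
    continent-specific variants (CSVs): alleles observed in exactly one
    continental reference group. Calls CSVs and sub-continental
    population-specific variants (sCSVs) from labeled phased haplotype
    panels, decodes per-individual diploid ancestry with a hidden Markov
    model over observed CSVs, iteratively refines the CSV set using
    confidently called homozygous-ancestry segments of the admixed sample
    itself, and supports low-coverage sequencing through genotype dosages
    under a Hardy-Weinberg prior. Ships an admixture-tract simulator and a
    synthetic reference-panel generator with truth bookkeeping, plus
    accuracy metrics (per-SNP squared correlation, haploid/diploid
    accuracy, switch-point resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
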