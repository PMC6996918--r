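Package: lofase
Title: Allele-Specific Expression of Loss-of-Function Tumor-Suppressor Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A paired normal/tumor allele-specific expression (ASE) analysis
    pipeline for loss-of-function (LOF) alleles of tumor-suppressor genes.
    Provides reference mapping-bias correction via nucleotide-pair expected
    allelic ratios, exact binomial SNP-level ASE testing with Benjamini-Hochberg
    false-discovery-rate control, pseudo-phased gene-level ASE with Monte-Carlo
    calibration, six-pattern paired normal/tumor classification using a combined
    binomial-Fisher procedure, LOF variant triage from consequence and
    SIFT/PolyPhen-2/ClinVar annotations, two-hit genotype classification against
    copy-number segments, attribution of ASE to candidate mechanisms (DNA allelic
    imbalance, copy-number duplication, cis-eQTL phase, methylation change,
    splice-site mutation, exon skipping, antisense RNA), and a synthetic paired
    cohort generator with planted truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
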