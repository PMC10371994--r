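Package: malamp
Title: Targeted Amplicon Genotyping of Human Malaria Host-Susceptibility Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete targeted amplicon-sequencing genotyping workflow for
    human variants associated with malaria disease outcomes (HBB sickle-cell
    and haemoglobinopathy alleles, G6PD deficiency variants, the ACKR1 Duffy
    polymorphism, and the intergenic Dantu blood-group variant). Covers
    dual-index demultiplexing of pooled reads, amplicon-local Smith-Waterman
    alignment and pileup, depth- and allele-fraction-threshold genotype
    calling with hemizygote handling on the X chromosome, sex-aware G6PD
    A-/A+/B classification, haemoglobin/Duffy/Dantu phenotype inference, and
    cohort-level frequency, completeness and concordance reporting. Includes
    a synthetic read and cohort simulator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
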