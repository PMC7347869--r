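Package: gastroPDX
Title: Molecular Subtyping and Clonal Dynamics of Gastric Cancer
    Patient-Derived Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for molecular characterization of gastric cancer
    patient-derived xenograft (PDX) cohorts. Implements qPCR-based ACRG and
    TCGA-style molecular subtyping (microsatellite instability, EBV load,
    TP53 activation and proliferation scores, CDH1-low EMT calling), the
    xenograft somatic-variant hygiene chain (mouse-read deconvolution,
    three-caller consensus, support/allele-fraction/polymorphism/impact
    filters, germline subtraction), mutation-burden and trinucleotide
    spectrum summaries with nonnegative least-squares signature matching,
    per-gene copy-number event classification with genomically-stable versus
    chromosome-instable assignment, passage-wise allele-fraction trajectory
    analysis with allelic banding detection and droplet digital PCR
    minor-clone quantification, cohort-level engraftment and concordance
    reporting, and a fully seeded synthetic-cohort generator for end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, pracma, ape
Suggests: testthat (>= 3.0.0), withr, vcfR, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
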