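Package: MBAmplicon
Title: Dual Molecular Barcode Amplicon Sequencing Error Suppression and
    Rare Variant Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Molecular-barcode (dual unique molecular tag, UMT) consensus
    calling for amplicon deep sequencing. Reads carrying a random tag at both
    the 5' and 3' end of each template molecule are clustered into molecular
    families; a variant is credited to a family only when every member read
    carries it, which suppresses PCR and sequencing errors and allows somatic
    variants below 1% allele fraction to be detected in tumor and plasma
    cell-free DNA. The package provides panel and tagged-read input, family
    construction and unanimous consensus, a molecular variant caller with a
    binomial background-error model and the full filter cascade, a
    conventional read-level tumor-normal caller for comparison, a seeded
    amplicon read simulator with ground truth (serial-dilution and plasma
    scenarios), and evaluation utilities (detection tables, limit-of-detection
    ladders, VAF concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics,
    SummarizedExperiment,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
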