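Package: cbekit
Title: Design and Quantification Toolkit for PAM-Flexible Cytosine Base Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cytosine base editor (CBE) experiments with
    PAM-flexible Cas9 variants. Enumerates candidate guides under arbitrary
    IUPAC PAM patterns, designs premature-STOP C-to-T edits from coding
    annotations, annotates bystander edits, and scans for mismatch
    off-targets. Quantifies editing outcomes from amplicon deep sequencing
    (expected C:G-to-T:A conversions, other substitutions, and indels
    overlapping the spacer) and from Sanger chromatograms, and models
    phenotype-based co-selection of highly edited mosaic founders with a
    latent-dose cohort simulator and a permutation trend test. A synthetic
    data module generates references, reads, and traces with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
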