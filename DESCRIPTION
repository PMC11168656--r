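Package: cas12atk
Title: Cas12a PAM Discovery, Editing Quantification, and Allele-Specific
    Guide Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for characterising Cas12a nucleases with degenerate,
    pyrimidine-rich PAMs. Implements the computational side of a
    GFP-activation PAM screen: a synthetic-data generator for randomized-PAM
    reporter libraries with staggered-cut editing outcomes, PAM discovery
    from GFP-selected reads (anchored 5-mer extraction, in-frame filtering,
    position frequency matrices, information-content logos and PAM wheels),
    amplicon indel quantification with allele-resolved rates and off/on
    specificity normalisation, gel-based cleavage quantitation, and an
    allele-specific crRNA designer that scans SNV flanks on both strands for
    YYN PAMs placing the variant in the mismatch-sensitive spacer window.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
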