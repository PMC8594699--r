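Package: epiamplicon
Title: Methylation Pattern Analysis for Ultra-Deep Amplicon Bisulfite
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls per-molecule CpG methylation patterns (epihaplotypes) from
    paired-end amplicon bisulfite sequencing reads: primer-anchored read pair
    extraction, bisulfite-aware alignment to in-silico converted amplicon
    templates, proportional overlap truncation and merging, length/gap quality
    filtering, per-read binary pattern calling, maximum-likelihood estimation
    of the true pattern distribution under an explicit conversion and
    sequencing error model with elimination of spurious patterns, and
    cross-condition comparison of pattern repertoires (Venn region counts,
    pooled group comparisons, per-CpG and overall methylation levels). A
    read-level simulator with truth tables supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
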