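Package: ampdel
Title: Split-Read Deletion Calling and Breakpoint VAF Quantification for
    UMI-Tagged Amplicon ctDNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large intragenic deletions from targeted single-primer-
    extension amplicon sequencing of circulating tumor DNA and quantifies
    their variant allele frequency from breakpoint-informative read pairs.
    Candidate deletions are enumerated as reference gaps between split-read
    segments, microhomology-ambiguous junctions are canonicalized by
    assigning ambiguous bases to the first (primer-side) read segment, and
    the best-supported deletion is retained. Read pairs are deduplicated by
    mapping position plus unique molecular identifier (UMI) so that all
    counts are per unique input molecule, and per-breakpoint allele
    frequencies are combined as a depth-weighted average. A built-in
    synthetic amplicon library simulator (truth-aligned SAM output, spiked
    deletion allele, genome-equivalent molecule pools) supports
    limit-of-detection and limit-of-blank evaluation over dilution series
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
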