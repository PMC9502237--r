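Package: liftkit
Title: Lift SAM/BAM Alignments Between a Variant-Aware and a Standard Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds succinct per-contig coordinate maps from a VCF that
    describes SNV and indel differences between a variant-aware ("source")
    reference and a standard ("target") reference, and uses them to lift
    SAM/BAM alignments from source to target coordinates. Translates the
    alignment position and CIGAR string (including spliced N operations),
    mate fields and template length, optionally recomputes the MD and NM
    tags against the target FASTA, rewrites the header, and can export the
    coordinate map as a UCSC chain file. Streaming input/output with
    order-preserving multi-worker batching, plus a synthetic-fixture
    generator and brute-force oracles for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    Biostrings,
    Rsamtools,
    parallel,
    stats,
    utils,
    methods,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
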