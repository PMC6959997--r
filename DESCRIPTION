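Package: nanodrs
Title: Differential Error and 3' End Analysis of Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for downstream analysis of nanopore direct RNA
    sequencing (DRS) alignments. Detects N6-methyladenosine (m6A) sites from
    two-condition differences in per-base basecall error profiles using G-tests
    with replicate homogeneity filtering, Benjamini-Hochberg correction and
    Haldane-corrected log2 fold changes; tests phasing of modification signal
    with poly(A) site choice; detects alternative 3' end usage, poly(A) tail
    length changes and chimeric readthrough RNAs; classifies splice junctions
    against U2/U12 position weight matrices; and provides motif enrichment with
    dinucleotide-preserving shuffles. Includes a fully seeded synthetic-data
    generator that plants ground truth (modified sites, 3' shifts, chimeras,
    over-split read pairs) into miniature genomes and BAM alignments for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
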