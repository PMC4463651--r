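Package: usintrons
Title: Detection and Validation of Ultra-Short Pre-mRNA Introns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying, screening and validating
    evolutionarily conserved ultra-short (<= 65 nt) pre-mRNA introns.
    Extracts introns from genome sequence and transcript annotation, builds
    the intron length distribution and locates the ultra-short threshold
    from the non-GT-AG contamination ratio, screens candidates for
    cross-species conservation from tabular local-alignment hits, calls
    splicing support from junction-spanning short reads, classifies the
    consequence of intron retention (reading frame, premature termination
    codons, nonsense-mediated decay), scores splice-site and branch-site
    signals, scans G-rich and intronic-splicing-enhancer sequence features,
    and integrates all channels into an evidence report. A seeded synthetic
    data generator produces genomes, isoforms, reads and ortholog hit
    tables with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
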