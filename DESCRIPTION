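Package: honeytrace
Title: Hemiptera COI Metabarcoding of Honey Environmental DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for insect (Hemiptera) DNA metabarcoding of
    honey. Extracts the 135-140 bp COI amplicon delimited by degenerate
    primers from a taxonomy-annotated reference set (in-silico PCR), quality
    trims and filters single-end amplicon reads, assigns reads to taxa by
    banded semi-global alignment under identity and coverage thresholds with
    lowest-common-ancestor tie-breaking and honey-bee host accounting,
    summarises per-library communities into categorical abundance profiles,
    and calls within-species mitochondrial haplotypes (mitotypes) with a
    read-count/frequency reliability filter. Includes a seeded amplicon
    library simulator with an Ion-Torrent-like error model and truth
    manifests so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
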