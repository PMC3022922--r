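Package: ap2erf
Title: Genome-Wide Survey and Expression Profiling of AP2/ERF Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genome-wide identification and expression analysis of
    AP2/ERF transcription-factor superfamilies in plant genomes. Detects AP2
    and B3 DNA-binding domains with position-specific scoring matrices built
    from seed alignments, applies gene-model reliability rules (long-intron
    flagging, splitting of fused multi-domain models, pseudogene exclusion),
    classifies genes into the ERF, AP2, RAV and Soloist families and the
    Nakano ERF groups by nearest-reference similarity, builds neighbor-joining
    trees with bootstrap support from pairwise-deletion distances, summarizes
    chromosomal distribution and tandem duplication clusters, and analyzes
    RT-qPCR data with housekeeping-gene normalization, delta-delta-Ct fold
    changes, differential-expression calling and Fisher's exact group
    enrichment. A synthetic-data module generates reference panels, target
    proteomes with planted defects, and Ct tables with planted expression
    structure so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
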