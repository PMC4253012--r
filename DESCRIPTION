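Package: orthosat
Title: Commensurability of Cross-Species Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing whether PCR-fragment-length genotypes at
    orthologous microsatellites are commensurable between species. Detects
    short-tandem-repeat (STR) structure inside reference amplicons, performs
    in-silico PCR with the retention decision tree used for human-derived
    marker panels, classifies putative orthologs by fragment-length range
    overlap, aligns flanking sequence to quantify non-STR length imbalances,
    calibrates fragment lengths into repeat numbers, and quantifies how
    length-based genotypes inflate interspecies F_ST and allele-sharing
    distance relative to repeat-based genotypes. Includes a synthetic-data
    generator that emulates orthologous amplicon pairs and drifted
    multi-population diploid genotypes so the whole pipeline is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
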