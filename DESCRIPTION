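Package: epivector
Title: Quantification of Histone-Modification Enrichment on Episomal AAV
    Vector Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage quantification machinery for chromatin profiling
    (Cut&Tag) of episomal recombinant AAV vector genomes on a combined
    host+vector reference: fragment deduplication, per-base CPM coverage
    tracks in bedGraph semantics, ITR-masked length-weighted vector coverage
    statistics, Tn5 input-library ratio normalization, and replicate-level
    group statistics (Tukey-hinge boxplot summaries, Welch t tests, one- and
    two-way ANOVA, timepoint ratio-of-means). Includes a synthetic fragment
    and qPCR plate simulator with known ground-truth enrichment so every
    stage is verifiable without sequencing data, plus molecular-assay math:
    delta-delta-Ct relative expression, qPCR standard curves and absolute
    copy number, DNase-protection encapsidated fraction, and tissue-weight
    normalized luciferase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
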