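Package: bbrelex
Title: Co-Reference-Aware Extraction of Bacteria-Biotope Relations from Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for acquiring Localization and PartOf
    relations between bacteria, habitats and geographical locations from
    encyclopedia-style texts in the BRAT standoff dialect of the Bacteria
    Biotope task. Provides standoff annotation input/output with paragraph,
    sentence and token segmentation; lexicon loaders for OBO ontologies,
    taxon name lists, word-cluster path files and Cocoa-style category
    annotations; an L1-regularized log-linear sequence labeler for typed
    entity mention detection with nested-mention post-processing;
    precision-oriented rule-based co-reference resolution combining
    similarity of form (identity, conventional abbreviation, strain
    designators, bounded Damerau-Levenshtein edit distance) with
    centering/recentness anaphora rules; co-reference-aware supervised
    relation detection with balanced example sampling and a logistic
    (maximum-entropy) classifier; intrinsic (MUC, B-cubed, CEAF) and
    extrinsic (equivalence-aware relation matching) scorers; and a seeded
    synthetic corpus generator so the whole pipeline is trainable and
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
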