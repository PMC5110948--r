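Package: eppmotif
Title: Entropy-Based Position Projection for DNA Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic discovery of transcription-factor binding motifs
    in DNA sequence sets by entropy-based position projection (EPP): the full
    l-mer set is recursively partitioned at the column of maximal relative
    entropy into bounded-size candidate subsets, candidates are filtered by a
    joint complexity / information-content outlier criterion, refined by
    2d-hamming pruning and greedy instance recruitment, and similar motifs
    are merged with the average log-likelihood ratio (ALLR) into longer
    composites. Includes a third-order Markov background model,
    dependency-aware information content, site- and nucleotide-level
    evaluation metrics (precision/recall/F and the performance coefficient),
    and a planted-motif synthetic benchmark generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
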