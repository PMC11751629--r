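Package: txscout
Title: Two-Stage Text and Transcriptome Retrieval over RNA-Seq Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Search large RNA-seq corpora with free-text and gene-set
    queries. Study metadata is embedded into a fixed-length vector space
    (a deterministic signed feature-hashing embedder is built in and any
    sentence embedder can be plugged in), condition-averaged expression
    profiles are projected with a seeded Johnson-Lindenstrauss transform,
    and retrieval runs as a two-stage cosine-similarity search: a first
    pass over one embedding space followed by expansion of the candidate
    study list over the other. Retrieved samples can be filtered by
    single-sample gene set enrichment (ssGSEA) with gene-permutation
    p-values and Benjamini-Hochberg FDR control. Includes retrieval
    benchmarking metrics (enriched-sample counts, query-metadata cosine,
    interpoint distances, normalized Jaccard distance), strategy
    comparison with Wilcoxon and Fisher tests, hyperparameter grid
    search, and a seeded generator of ARCHS4-style synthetic corpora
    with planted topics for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
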