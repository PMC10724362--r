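Package: chessr
Title: Chemical Semantic Search with Alternative SMILES Canonicalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Embedding-based chemical similarity search in which the query
    SMILES string is canonicalized by a different algorithm (or rooted at a
    different atom) than the database, so that string-level memorization is
    suppressed and whole-molecule semantics dominate the comparison. Provides
    the full pipeline: achiral canonicalization and rooted-SMILES enumeration
    (via OpenBabel), a deterministic token-hashing embedder with an adapter
    slot for transformer encoders, a chunked L2-normalized vector store with
    a filter cascade (deduplication, multi-fragment and over-length removal),
    exact cosine top-k search, a suite of pairwise similarity metrics
    (gestalt pattern matching, fingerprint and Murcko-scaffold Tanimoto,
    token Jaccard, token-length ratio), the statistical panels used to
    compare canonicalizations, and an offline-testable LLM-assisted patent
    functional-labeling pipeline with injectable backends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
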