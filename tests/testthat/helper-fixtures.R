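# Shared fixtures for the test suite.  Everything is generated in code;
# seeds are pinned so runs are reproducible.

# Small pool of drug-like and simple molecules exercising rings, fused
# rings, charges, heteroatoms and acyclic structures.
fixture_smiles <- function() {
  c(
    zidovudine = "Cc1cn(C2CC(N=[N+]=[N-])C(CO)O2)c(=O)[nH]c1=O",
    caffeine   = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen  = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    toluene    = "Cc1ccccc1",
    phenol     = "Oc1ccccc1",
    ethanol    = "CCO",
    hexane     = "CCCCCC",
    piperidone = "O=C1CCNCC1",
    naphthol   = "Oc1ccc2ccccc2c1"
  )
}

test_embedder <- function(dim = 96L, seed = 11L, max_tokens = 512L) {
  mock_embedder(dim = dim, seed = seed, max_tokens = max_tokens)
}

# The three published canonical writings of zidovudine used as the worked
# divergence example.
zidovudine_trio <- function() zidovudine_variants()$smiles

# Random printable strings for gestalt property tests.
random_strings <- function(n, max_len = 40L, alphabet = c(letters, LETTERS, 0:9)) {
  vapply(seq_len(n), function(i) {
    len <- sample.int(max_len, 1L)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Hand-built embedding store with prescribed unit vectors (bypasses the
# embedder; for search-ordering tests with known cosines).
manual_store <- function(smiles, mat, chunk_size = nrow(mat)) {
  nrm <- sqrt(rowSums(mat^2))
  mat <- mat / nrm
  starts <- seq(1L, nrow(mat), by = chunk_size)
  chunks <- lapply(starts, function(s) {
    e <- min(s + chunk_size - 1L, nrow(mat))
    list(smiles = smiles[s:e], mat = mat[s:e, , drop = FALSE])
  })
  structure(list(chunks = chunks, dim = ncol(mat),
                 chunk_size = as.integer(chunk_size),
                 manifest = list(filter_counts = list())),
            class = "embedding_store")
}

# Embedder whose vectors are dictated by a lookup table keyed on the input
# string (for argmin/selection tests with prescribed cosines).
lookup_embedder <- function(vectors) {
  dim <- length(vectors[[1]])
  transformer_embedder(
    tokenize_fn = function(s) s,
    encode_fn = function(ids) {
      v <- vectors[[ids]]
      if (is.null(v)) stop("no vector for ", ids)
      matrix(v, nrow = 1L)
    },
    dim = dim
  )
}

# Internal constructor surfaced for tests that prescribe variants directly.
canonical_variant_for_test <- function(smiles, scheme, root_atom = NA_integer_) {
  chessr:::canonical_variant(smiles, scheme, root_atom)
}
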