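#' Deterministic mock SMILES embedder
#'
#' The search method only relies on three properties of the sequence
#' encoder: it is deterministic, it is sensitive to the *order* of tokens
#' (so that different writings of the same molecule land at different
#' points of feature space), and it emits fixed-width L2-normalized
#' vectors.  The mock embedder supplies exactly these properties without
#' any trained weights: token uni/bi/tri-grams are hashed into a
#' `n_bins`-dimensional count vector, projected through a seeded fixed
#' Gaussian random matrix to `dim` dimensions, and L2-normalized.
#'
#' @param dim output vector width (default 768, a typical BERT hidden size).
#' @param seed integer seed fixing the projection matrix; two embedders with
#'   the same seed produce byte-identical vectors.
#' @param n_bins number of hash bins for the n-gram counts.
#' @param max_tokens maximum token-vector length accepted by [embed()]
#'   (default 512, the usual encoder context limit).
#' @return An object of class `c("mock_embedder", "chess_embedder")`.
#' @export
mock_embedder <- function(dim = 768L, seed = 42L, n_bins = 4096L,
                          max_tokens = 512L) {
  stopifnot(dim >= 1L, n_bins >= 1L, max_tokens >= 1L)
  obj <- list(
    backend = "mock",
    dim = as.integer(dim),
    seed = as.integer(seed),
    n_bins = as.integer(n_bins),
    max_tokens = as.integer(max_tokens),
    vocab = new_vocab(),
    env = new.env(parent = emptyenv())
  )
  class(obj) <- c("mock_embedder", "chess_embedder")
  obj
}

#' Adapter for a real transformer encoder
#'
#' Carries the contract a pretrained chemical language model must satisfy to
#' drive the search: a tokenizer, an encoder returning per-position hidden
#' states of the final layer, and first-token pooling.  The encode function
#' is injected, so model weights never enter this package.
#'
#' @param tokenize_fn function(smiles) -> integer token ids.
#' @param encode_fn function(ids) -> numeric matrix (positions x dim) of
#'   final-layer hidden states; the first row (the sequence-level token) is
#'   pooled as the embedding.
#' @param dim embedding width returned by `encode_fn`.
#' @param max_tokens maximum accepted token-vector length.
#' @export
transformer_embedder <- function(tokenize_fn, encode_fn, dim,
                                 max_tokens = 512L) {
  stopifnot(is.function(tokenize_fn), is.function(encode_fn), dim >= 1L)
  obj <- list(
    backend = "transformer",
    dim = as.integer(dim),
    max_tokens = as.integer(max_tokens),
    tokenize_fn = tokenize_fn,
    encode_fn = encode_fn
  )
  class(obj) <- c("transformer_embedder", "chess_embedder")
  obj
}

#' @export
print.chess_embedder <- function(x, ...) {
  cat("<chess_embedder>", x$backend, "dim", x$dim,
      "max_tokens", x$max_tokens, "\n")
  invisible(x)
}

# Seeded projection matrix, generated once per embedder and cached.  The
# global RNG state is saved and restored so embedding never perturbs user
# simulations.
mock_projection <- function(embedder) {
  e <- embedder$env
  if (is.null(e$proj)) {
    e$proj <- with_preserved_seed(embedder$seed, {
      matrix(stats::rnorm(embedder$n_bins * embedder$dim),
             nrow = embedder$n_bins, ncol = embedder$dim)
    })
  }
  e$proj
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Polynomial rolling hash of a string into [0, n_bins).  Exact in double
# precision because the running value is reduced modulo a prime < 2^21.
hash_bin <- function(strings, n_bins) {
  vapply(strings, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 1048573
    as.integer(h %% n_bins)
  }, integer(1), USE.NAMES = FALSE)
}

# Hashed n-gram bins for one token sequence, with a per-embedder cache so
# repeated grams across a database are hashed once.
gram_bins <- function(embedder, toks) {
  n <- length(toks)
  grams <- toks
  if (n >= 2L) grams <- c(grams, paste(toks[-n], toks[-1L], sep = "\x1f"))
  if (n >= 3L) {
    grams <- c(grams,
               paste(toks[1:(n - 2L)], toks[2:(n - 1L)], toks[3:n],
                     sep = "\x1f"))
  }
  cache <- embedder$env
  if (is.null(cache$bins)) cache$bins <- new.env(parent = emptyenv())
  known <- vapply(grams, function(g) {
    exists(g, envir = cache$bins, inherits = FALSE)
  }, logical(1), USE.NAMES = FALSE)
  if (any(!known)) {
    new_grams <- unique(grams[!known])
    new_bins <- hash_bin(new_grams, embedder$n_bins)
    for (i in seq_along(new_grams)) {
      assign(new_grams[i], new_bins[i], envir = cache$bins)
    }
  }
  vapply(grams, function(g) get(g, envir = cache$bins, inherits = FALSE),
         integer(1), USE.NAMES = FALSE)
}

over_length_error <- function(smiles, n_tokens, max_tokens) {
  structure(
    class = c("chess_overlength_error", "error", "condition"),
    list(message = sprintf(
           "SMILES tokenizes to %d tokens, above the %d-token limit: %s",
           n_tokens, max_tokens, smiles),
         call = NULL, smiles = smiles, n_tokens = n_tokens)
  )
}

#' Embed SMILES strings
#'
#' `embed_smiles()` maps a character vector of SMILES to a numeric matrix
#' (one row per string, `dim` columns) of L2-normalized embeddings;
#' `embed()` wraps a single string into an `Embedding` object carrying its
#' source string and token vector.  Identical strings always receive
#' identical vectors; different writings of the same molecule generally do
#' not, which is the substrate the search exploits.
#'
#' @param embedder a [mock_embedder()] or [transformer_embedder()].
#' @param smiles character vector (for `embed_smiles`) or single string.
#' @return `embed_smiles`: numeric matrix with `length(smiles)` rows, each
#'   of unit Euclidean norm.  `embed`: object of class `chess_embedding`
#'   with fields `vector`, `dim`, `source_smiles`, `token_vector`.
#' @export
embed_smiles <- function(embedder, smiles) {
  UseMethod("embed_smiles")
}

#' @export
embed_smiles.mock_embedder <- function(embedder, smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = embedder$dim))
  }
  tok_list <- vector("list", n)
  for (i in seq_len(n)) {
    tv <- tokenize(smiles[i], vocab = embedder$vocab)
    if (tv$length > embedder$max_tokens) {
      stop(over_length_error(smiles[i], tv$length, embedder$max_tokens))
    }
    tok_list[[i]] <- tv$strings
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    bins <- gram_bins(embedder, tok_list[[i]]) + 1L
    tab <- table(bins)
    ii <- c(ii, rep.int(i, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(n, embedder$n_bins))
  emb <- as.matrix(counts %*% mock_projection(embedder))
  l2_normalize_rows(emb)
}

#' @export
embed_smiles.transformer_embedder <- function(embedder, smiles) {
  stopifnot(is.character(smiles))
  out <- matrix(NA_real_, nrow = length(smiles), ncol = embedder$dim)
  for (i in seq_along(smiles)) {
    ids <- embedder$tokenize_fn(smiles[i])
    if (length(ids) > embedder$max_tokens) {
      stop(over_length_error(smiles[i], length(ids), embedder$max_tokens))
    }
    hidden <- embedder$encode_fn(ids)
    if (!is.matrix(hidden) || ncol(hidden) != embedder$dim) {
      stop("encode_fn must return a positions x dim matrix")
    }
    out[i, ] <- hidden[1L, ]  # first-token (sequence-level) pooling
  }
  l2_normalize_rows(out)
}

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m * m))
  if (any(nrm == 0)) stop("cannot L2-normalize a zero embedding vector")
  m / nrm
}

#' @rdname embed_smiles
#' @export
embed <- function(embedder, smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  v <- embed_smiles(embedder, smiles)[1L, ]
  tv <- if (inherits(embedder, "mock_embedder")) {
    tokenize(smiles, vocab = embedder$vocab)
  } else NULL
  structure(list(vector = v, dim = length(v), source_smiles = smiles,
                 token_vector = tv),
            class = "chess_embedding")
}

#' @export
print.chess_embedding <- function(x, ...) {
  cat("<chess_embedding> dim", x$dim, "for", x$source_smiles, "\n")
  invisible(x)
}
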