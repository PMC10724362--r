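#' Cosine similarity between two embeddings
#'
#' For the unit vectors this package produces, the cosine is the plain dot
#' product; 1 means identical direction, 0 orthogonal, -1 opposite.
#' Accumulation is in double precision.
#'
#' @param a,b `chess_embedding` objects or numeric vectors of equal length.
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "chess_embedding")) a$vector else as.numeric(a)
  vb <- if (inherits(b, "chess_embedding")) b$vector else as.numeric(b)
  if (length(va) != length(vb)) {
    stop("embedding dimension mismatch: ", length(va), " vs ", length(vb))
  }
  na <- sqrt(sum(va * va)); nb <- sqrt(sum(vb * vb))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(va * vb) / (na * nb)
}

#' Exact top-k cosine search over an embedding store
#'
#' Scans every chunk (no approximation), scoring the query embedding
#' against each stored vector by dot product, and returns the k best hits.
#' Ties in similarity are broken by store position (chunk, then row), so
#' results are reproducible across runs.  Peak memory is bounded by one
#' chunk plus the running candidate list.
#'
#' @param query a `canonical_variant`, a SMILES string, or a
#'   `chess_embedding`.
#' @param store an `embedding_store`.
#' @param k number of hits (default 250); if k exceeds the store size all
#'   rows are returned with a warning.
#' @param embedder the `chess_embedder` the store was built with (not
#'   needed when `query` is already an embedding).
#' @param metric `"cosine"` (default) or `"euclidean"`; with unit vectors
#'   the two orderings coincide, the switch only changes the reported score.
#' @return data.frame of `SearchResult`s: rank (1-based), smiles,
#'   similarity, sorted by similarity descending.
#' @export
top_k <- function(query, store, k = 250L, embedder = NULL,
                  metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(k >= 1L)
  v <- query_embedding(query, embedder)
  if (length(v) != store$dim) {
    stop("query embedding dim ", length(v), " does not match store dim ",
         store$dim)
  }
  n_total <- store_nrow(store)
  if (k > n_total) {
    warning("k = ", k, " exceeds store size ", n_total,
            "; returning all rows")
    k <- n_total
  }
  cand_sim <- numeric(0); cand_smi <- character(0); cand_pos <- numeric(0)
  offset <- 0
  for (ch in store$chunks) {
    sims <- as.numeric(ch$mat %*% v)
    n_ch <- length(sims)
    keep <- utils::head(order(-sims, seq_len(n_ch)), k)
    cand_sim <- c(cand_sim, sims[keep])
    cand_smi <- c(cand_smi, ch$smiles[keep])
    cand_pos <- c(cand_pos, offset + keep)
    offset <- offset + n_ch
  }
  sel <- utils::head(order(-cand_sim, cand_pos), k)
  sim <- cand_sim[sel]
  if (metric == "euclidean") sim <- sqrt(pmax(0, 2 - 2 * sim))
  data.frame(rank = seq_along(sel), smiles = cand_smi[sel],
             similarity = sim, stringsAsFactors = FALSE)
}

query_embedding <- function(query, embedder) {
  if (inherits(query, "chess_embedding")) return(query$vector)
  smi <- if (inherits(query, "canonical_variant")) query$smiles
         else if (is.character(query) && length(query) == 1L) query
         else stop("query must be a canonical_variant, SMILES string, or embedding")
  if (is.null(embedder)) stop("an embedder is required to embed the query")
  embed_smiles(embedder, smi)[1L, ]
}

#' Rank database molecules by fingerprint Tanimoto to a query
#'
#' The classical structure-based baseline: every database molecule is
#' scored by whole-molecule path-fingerprint Tanimoto similarity to the
#' query and ranked descending.  Unparseable database entries are skipped
#' (their indices are attached as the `skipped` attribute).  Ties are
#' broken by database position.
#'
#' @param query a `molecule_record` or SMILES string.
#' @param store_smiles character vector of database SMILES.
#' @param k number of rows to return; `NULL` (default) ranks the whole
#'   database, as needed for rank-vs-rank comparisons.
#' @return data.frame: rank, smiles, similarity (Tanimoto in `[0, 1]`).
#' @export
tanimoto_rank <- function(query, store_smiles, k = NULL) {
  query <- as_molecule_record(query)
  qbits <- fingerprint_bits(query$std_smiles)[[1]]
  fps <- fingerprint_bits(store_smiles)
  ok <- !vapply(fps, is.null, logical(1))
  sims <- rep(NA_real_, length(store_smiles))
  sims[ok] <- vapply(fps[ok], function(b) set_tanimoto(qbits, b), numeric(1))
  idx <- which(ok)
  ordod <- idx[order(-sims[idx], idx)]
  if (!is.null(k)) ordod <- utils::head(ordod, k)
  out <- data.frame(rank = seq_along(ordod), smiles = store_smiles[ordod],
                    similarity = sims[ordod], stringsAsFactors = FALSE)
  attr(out, "skipped") <- which(!ok)
  out
}
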