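#' Pairwise divergence of the three query canonicalizations
#'
#' For each query molecule, the three representations (default-root
#' canonical, maximum-distance rooted, external) are compared pairwise
#' with four metrics: gestalt string similarity, shared-token ratio,
#' token-length ratio, and feature (embedding cosine) similarity.
#' Deviations from 1 quantify how far the canonicalizations diverge as
#' model inputs.
#'
#' Variants can either be built from the molecules (supply `queries` plus
#' `external_smiles`) or supplied pre-computed (a `variant_table` with
#' columns `query`, `default_smiles`, `alt_smiles`, `external_smiles`),
#' e.g. when the alternative forms come from another toolkit.
#'
#' @param queries list of `molecule_record`s or SMILES strings (ignored
#'   when `variant_table` is given).
#' @param embedder a `chess_embedder` (used both to select the rooted
#'   variant and for feature similarity).
#' @param external_smiles character vector of external canonical forms,
#'   parallel to `queries`.
#' @param variant_table optional pre-computed variant table (see above).
#' @return Object of class `divergence_panel`: list with `pairs` (one row
#'   per query and canonicalization pair) and `means` (grand means over
#'   all pairs).
#' @export
divergence_panel <- function(queries = NULL, embedder,
                             external_smiles = NULL, variant_table = NULL) {
  if (is.null(variant_table)) {
    stopifnot(!is.null(queries), !is.null(external_smiles),
              length(queries) == length(external_smiles))
    rows <- lapply(seq_along(queries), function(i) {
      rec <- as_molecule_record(queries[[i]])
      v <- query_variants(rec, embedder, external_smiles[i])
      data.frame(query = rec$std_smiles,
                 default_smiles = v$default_root$smiles,
                 alt_smiles = v$alt_root$smiles,
                 external_smiles = v$external$smiles,
                 stringsAsFactors = FALSE)
    })
    variant_table <- do.call(rbind, rows)
  }
  need <- c("query", "default_smiles", "alt_smiles", "external_smiles")
  stopifnot(all(need %in% names(variant_table)))

  pair_defs <- list(
    c("default_alt", "default_smiles", "alt_smiles"),
    c("default_external", "default_smiles", "external_smiles"),
    c("alt_external", "alt_smiles", "external_smiles")
  )
  out <- list()
  for (q in seq_len(nrow(variant_table))) {
    row <- variant_table[q, ]
    for (pd in pair_defs) {
      s1 <- row[[pd[2]]]; s2 <- row[[pd[3]]]
      t1 <- tokenize(s1); t2 <- tokenize(s2)
      e <- embed_smiles(embedder, c(s1, s2))
      out[[length(out) + 1L]] <- data.frame(
        query = row$query, pair = pd[1],
        string_similarity = gestalt_similarity(s1, s2),
        shared_token_ratio = token_jaccard(t1, t2),
        token_length_ratio = token_length_ratio(t1, t2),
        feature_similarity = cosine_similarity(e[1, ], e[2, ]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  metric_cols <- c("string_similarity", "shared_token_ratio",
                   "token_length_ratio", "feature_similarity")
  structure(list(pairs = pairs, means = colMeans(pairs[metric_cols])),
            class = "divergence_panel")
}

#' @export
print.divergence_panel <- function(x, ...) {
  cat("<divergence_panel>", nrow(x$pairs), "pairs\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Similarity profile of a query's top-k search results
#'
#' Runs the cosine top-k search for one query representation and computes,
#' for every hit, its structural, scaffold, string, shared-token and
#' token-length similarity to the query, plus the column means.
#'
#' @param query a `canonical_variant` (or SMILES string, treated as a
#'   default-root query).
#' @param store an `embedding_store`.
#' @param k number of results to profile (default 250).
#' @param embedder the store's `chess_embedder`.
#' @return Object of class `result_profile`: list with `rows` (the top-k
#'   table joined with metric columns), `means`, `scheme`, and `k`.
#' @export
result_profile <- function(query, store, k = 250L, embedder) {
  if (is.character(query)) query <- canonical_variant(query, "default_root", 0L)
  hits <- top_k(query, store, k = k, embedder = embedder)
  mt <- metrics_table(query$smiles, hits$smiles)
  rows <- cbind(hits, mt[, setdiff(names(mt), "smiles")])
  metric_cols <- c("structural", "scaffold", "string", "shared_token",
                   "token_length")
  structure(list(rows = rows,
                 means = colMeans(rows[metric_cols], na.rm = TRUE),
                 scheme = query$scheme, k = nrow(rows)),
            class = "result_profile")
}

#' @export
print.result_profile <- function(x, ...) {
  cat("<result_profile>", x$scheme, "k =", x$k, "\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Fraction of results above a similarity cutoff
#'
#' The share of profiled results whose structural similarity to the query
#' is at least `cutoff` -- i.e. the fraction of the embedding search's
#' hits that a classical fingerprint search with that cutoff would also
#' have found.
#'
#' @param profile a `result_profile`.
#' @param cutoff similarity threshold (default 0.8).
#' @param metric which profile column to threshold (default
#'   `"structural"`).
#' @export
cutoff_fraction <- function(profile, cutoff = 0.8, metric = "structural") {
  vals <- profile$rows[[metric]]
  mean(vals >= cutoff, na.rm = TRUE)
}

#' Embedding-search rank versus fingerprint-search rank
#'
#' For each of the query's top-k embedding hits, finds the 1-based rank
#' that same molecule receives in a full fingerprint-Tanimoto ranking of
#' the whole store, enabling rank-vs-rank comparison of the two searches.
#'
#' @param query a `canonical_variant` or SMILES string.
#' @param store an `embedding_store`.
#' @param k number of embedding hits (default 250).
#' @param embedder the store's `chess_embedder`.
#' @return data.frame with columns smiles, chess_rank, tanimoto_rank,
#'   tanimoto_similarity.
#' @export
rank_comparison <- function(query, store, k = 250L, embedder) {
  if (is.character(query)) query <- canonical_variant(query, "default_root", 0L)
  hits <- top_k(query, store, k = k, embedder = embedder)
  record <- standardize(query$smiles)
  tani <- tanimoto_rank(record, store_smiles(store))
  m <- match(hits$smiles, tani$smiles)
  data.frame(smiles = hits$smiles, chess_rank = hits$rank,
             tanimoto_rank = tani$rank[m],
             tanimoto_similarity = tani$similarity[m],
             stringsAsFactors = FALSE)
}

#' Two-sided independent two-sample t-test with significance stars
#'
#' Classical independent t-test (pooled-variance Student by default, Welch
#' via `var_equal = FALSE`), two-sided, with the conventional star coding:
#' `ns` for p >= 0.05, then `*` (p < 0.05), `**` (p < 0.01), `***`
#' (p < 0.001), `****` (p < 0.0001), each threshold strict.  When both
#' samples have zero variance: equal means give t = 0, p = 1 (`ns`);
#' unequal means give p = 0.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param var_equal pooled-variance (TRUE, default) or Welch (FALSE).
#' @return List with `t`, `p`, `stars`.
#' @export
independent_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p = 1, stars = "ns"))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                stars = significance_stars(0)))
  }
  res <- stats::t.test(a, b, var.equal = var_equal,
                       alternative = "two.sided")
  list(t = unname(res$statistic), p = res$p.value,
       stars = significance_stars(res$p.value))
}

#' @rdname independent_ttest
#' @param p a p-value.
#' @export
significance_stars <- function(p) {
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}
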