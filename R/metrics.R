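#' Gestalt pattern matching (Ratcliff-Obershelp) string similarity
#'
#' Computes `2 * Km / (|s1| + |s2|)` where `Km` is the number of matching
#' characters found by recursive longest-common-substring decomposition:
#' the longest common substring is matched first, then the regions to its
#' left and to its right are decomposed recursively.  No junk or
#' popularity heuristics are applied (the pure algorithm).  Ties among
#' equal-length longest blocks are broken toward the smallest position in
#' `s1`, then in `s2`.
#'
#' Two empty strings are defined to have similarity 1 (identity
#' convention).
#'
#' @param s1,s2 character strings.
#' @return Similarity in `[0, 1]`.
#' @examples
#' gestalt_similarity("abc", "abc")   # 1
#' gestalt_similarity("abcd", "bc")   # 2*2/6
#' @export
gestalt_similarity <- function(s1, s2) {
  stopifnot(is.character(s1), length(s1) == 1L,
            is.character(s2), length(s2) == 1L)
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 + n2 == 0L) return(1)
  km <- gestalt_matching_chars(utf8ToInt(s1), utf8ToInt(s2))
  2 * km / (n1 + n2)
}

#' Decompose a string pair into matching blocks
#'
#' Returns the recursive longest-common-substring decomposition underlying
#' [gestalt_similarity()]: the matching blocks (1-based start positions in
#' each string, and length) and the total matched character count.
#'
#' @param s1,s2 character strings.
#' @return List with `s1`, `s2`, `matching_chars`, and `blocks` (a
#'   data.frame with columns pos1, pos2, length).
#' @export
gestalt_decompose <- function(s1, s2) {
  a <- utf8ToInt(s1); b <- utf8ToInt(s2)
  blocks <- collect_blocks(a, b, 1L, length(a), 1L, length(b))
  if (length(blocks) == 0L) {
    df <- data.frame(pos1 = integer(0), pos2 = integer(0),
                     length = integer(0))
  } else {
    df <- do.call(rbind, lapply(blocks, as.data.frame))
    df <- df[order(df$pos1), , drop = FALSE]
    rownames(df) <- NULL
  }
  list(s1 = s1, s2 = s2, matching_chars = sum(df$length), blocks = df)
}

# Longest matching block of a[alo..ahi] vs b[blo..bhi]; among maximal
# blocks the one starting earliest in a, then earliest in b.
longest_match <- function(a, b, alo, ahi, blo, bhi) {
  besti <- alo; bestj <- blo; bestsize <- 0L
  if (alo > ahi || blo > bhi) {
    return(list(i = besti, j = bestj, size = bestsize))
  }
  j2len <- integer(length(b) + 1L)
  for (i in alo:ahi) {
    js <- which(b[blo:bhi] == a[i]) + blo - 1L
    newj2len <- integer(length(b) + 1L)
    if (length(js) > 0L) {
      ks <- j2len[js] + 1L   # j2len is indexed by j+1 shifted: see below
      newj2len[js + 1L] <- ks
      mx <- max(ks)
      if (mx > bestsize) {
        jj <- js[ks == mx][1L]
        bestsize <- mx
        besti <- i - mx + 1L
        bestj <- jj - mx + 1L
      }
    }
    j2len <- newj2len
  }
  list(i = besti, j = bestj, size = bestsize)
}

gestalt_matching_chars <- function(a, b) {
  total <- 0L
  stack <- list(c(1L, length(a), 1L, length(b)))
  while (length(stack) > 0L) {
    r <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    m <- longest_match(a, b, r[1], r[2], r[3], r[4])
    if (m$size > 0L) {
      total <- total + m$size
      stack[[length(stack) + 1L]] <- c(r[1], m$i - 1L, r[3], m$j - 1L)
      stack[[length(stack) + 1L]] <- c(m$i + m$size, r[2],
                                       m$j + m$size, r[4])
    }
  }
  total
}

collect_blocks <- function(a, b, alo, ahi, blo, bhi) {
  m <- longest_match(a, b, alo, ahi, blo, bhi)
  if (m$size == 0L) return(list())
  c(collect_blocks(a, b, alo, m$i - 1L, blo, m$j - 1L),
    list(list(pos1 = m$i, pos2 = m$j, length = m$size)),
    collect_blocks(a, b, m$i + m$size, ahi, m$j + m$size, bhi))
}

#' Tanimoto (Jaccard) similarity of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined to have
#' similarity 1 (identity convention).
#'
#' @param a,b vectors treated as sets (duplicates ignored).
#' @export
set_tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Whole-molecule structural similarity
#'
#' Path-fingerprint Tanimoto similarity between two molecules
#' (see [fingerprint_bits()]).
#'
#' @param m1,m2 `molecule_record`s or SMILES strings.
#' @export
structural_similarity <- function(m1, m2) {
  s1 <- if (inherits(m1, "molecule_record")) m1$std_smiles else m1
  s2 <- if (inherits(m2, "molecule_record")) m2$std_smiles else m2
  bits <- fingerprint_bits(c(s1, s2))
  if (is.null(bits[[1]]) || is.null(bits[[2]])) {
    stop("unparseable SMILES in structural_similarity")
  }
  set_tanimoto(bits[[1]], bits[[2]])
}

#' Scaffold similarity
#'
#' Structural similarity of the two molecules' Murcko scaffolds.  If both
#' molecules are acyclic (both scaffolds empty) the similarity is 1; if
#' exactly one is acyclic it is 0.
#'
#' @param m1,m2 `molecule_record`s or SMILES strings.
#' @export
scaffold_similarity <- function(m1, m2) {
  s1 <- if (inherits(m1, "molecule_record")) m1$std_smiles else m1
  s2 <- if (inherits(m2, "molecule_record")) m2$std_smiles else m2
  sc <- murcko_scaffold(c(s1, s2))
  if (anyNA(sc)) stop("unparseable SMILES in scaffold_similarity")
  if (!nzchar(sc[1]) && !nzchar(sc[2])) return(1)
  if (!nzchar(sc[1]) || !nzchar(sc[2])) return(0)
  structural_similarity(sc[1], sc[2])
}

#' Token-level similarity metrics
#'
#' `token_jaccard` is the Tanimoto similarity of the sets of *distinct*
#' token ids of two token vectors (shared-token ratio);
#' `token_length_ratio` is `min(len1, len2) / max(len1, len2)`, a
#' symmetric length comparison in `(0, 1]`.
#'
#' @param t1,t2 `token_vector`s from [tokenize()].
#' @export
token_jaccard <- function(t1, t2) {
  stopifnot(inherits(t1, "token_vector"), inherits(t2, "token_vector"))
  set_tanimoto(t1$strings, t2$strings)
}

#' @rdname token_jaccard
#' @export
token_length_ratio <- function(t1, t2) {
  stopifnot(inherits(t1, "token_vector"), inherits(t2, "token_vector"))
  min(t1$length, t2$length) / max(t1$length, t2$length)
}

#' All pairwise metrics of a query against a list of molecules
#'
#' Vectorized batch call computing, per database SMILES: structural and
#' scaffold fingerprint Tanimoto (against the query's standardized
#' structure), gestalt string similarity, shared-token ratio, and
#' token-length ratio (against the query string as written).
#'
#' @param query_smiles the query string as presented to the model (any
#'   canonicalization).
#' @param smiles character vector of database SMILES (standardized forms).
#' @return data.frame with one row per database molecule.
#' @export
metrics_table <- function(query_smiles, smiles) {
  qrec <- standardize(query_smiles)
  qtok <- tokenize(query_smiles)
  qbits <- fingerprint_bits(qrec$std_smiles)[[1]]
  qscaf <- murcko_scaffold(qrec$std_smiles)
  qscaf_bits <- if (nzchar(qscaf)) fingerprint_bits(qscaf)[[1]] else NULL

  bits <- fingerprint_bits(smiles)
  scafs <- murcko_scaffold(smiles)
  scaf_bits <- vector("list", length(smiles))
  has_scaf <- !is.na(scafs) & nzchar(scafs)
  if (any(has_scaf)) scaf_bits[has_scaf] <- fingerprint_bits(scafs[has_scaf])

  n <- length(smiles)
  structural <- scaffold <- string <- shared_token <- token_length <-
    rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.null(bits[[i]])) next
    structural[i] <- set_tanimoto(qbits, bits[[i]])
    scaffold[i] <- if (is.null(qscaf_bits) && !has_scaf[i]) 1
      else if (is.null(qscaf_bits) || !has_scaf[i]) 0
      else set_tanimoto(qscaf_bits, scaf_bits[[i]])
    string[i] <- gestalt_similarity(query_smiles, smiles[i])
    ti <- tokenize(smiles[i])
    shared_token[i] <- token_jaccard(qtok, ti)
    token_length[i] <- token_length_ratio(qtok, ti)
  }
  data.frame(smiles = smiles, structural = structural, scaffold = scaffold,
             string = string, shared_token = shared_token,
             token_length = token_length, stringsAsFactors = FALSE)
}
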