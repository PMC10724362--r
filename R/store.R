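#' Build a searchable embedding store from raw SMILES
#'
#' Applies the database construction cascade in order: standardization to
#' achiral canonical SMILES (unparseable records are dropped and counted,
#' with their line numbers retained), deduplication on the canonical form
#' (first occurrence wins), removal of multi-fragment records (any
#' canonical string containing the `.` separator), removal of records
#' tokenizing past the embedder's token limit, then embedding, L2
#' normalization, and chunking.
#'
#' @param smiles character vector of raw SMILES (stream order is
#'   meaningful: deduplication keeps the first occurrence).
#' @param embedder a `chess_embedder`; its `max_tokens` is the length
#'   filter.
#' @param chunk_size maximum rows per chunk (default 100000).
#' @return list with `store` (an `embedding_store`) and `report` (a
#'   `build_report` with per-stage counts).
#' @export
build_store <- function(smiles, embedder, chunk_size = 100000L) {
  stopifnot(is.character(smiles), chunk_size >= 1L)
  n_input <- length(smiles)

  if (n_input == 0L) {
    std <- character(0)
    parse_failed_lines <- integer(0)
  } else {
    batch <- standardize_batch(smiles)
    parse_failed_lines <- which(is.na(batch$std_smiles))
    std <- batch$std_smiles[!is.na(batch$std_smiles)]
  }
  n_parsed <- length(std)

  keep <- !duplicated(std)
  std <- std[keep]
  n_after_dedup <- length(std)

  frag <- grepl(".", std, fixed = TRUE)
  std <- std[!frag]
  n_after_fragment <- length(std)

  tok_len <- vapply(smiles_tokens(std), length, integer(1))
  std <- std[tok_len <= embedder$max_tokens]
  n_after_length <- length(std)

  mat <- embed_smiles(embedder, std)

  chunks <- list()
  if (length(std) > 0L) {
    starts <- seq(1L, length(std), by = chunk_size)
    chunks <- lapply(starts, function(s) {
      e <- min(s + chunk_size - 1L, length(std))
      list(smiles = std[s:e], mat = mat[s:e, , drop = FALSE])
    })
  }

  report <- structure(
    list(n_input = n_input,
         n_parse_failed = n_input - n_parsed,
         parse_failed_lines = parse_failed_lines,
         n_after_dedup = n_after_dedup,
         n_after_fragment_filter = n_after_fragment,
         n_after_length_filter = n_after_length,
         n_embedded = length(std)),
    class = "build_report"
  )
  store <- structure(
    list(chunks = chunks, dim = embedder$dim,
         chunk_size = as.integer(chunk_size),
         manifest = list(filter_counts = unclass(report)[
           c("n_input", "n_parse_failed", "n_after_dedup",
             "n_after_fragment_filter", "n_after_length_filter",
             "n_embedded")])),
    class = "embedding_store"
  )
  list(store = store, report = report)
}

#' @export
print.build_report <- function(x, ...) {
  cat("<build_report>\n")
  cat("  input:               ", x$n_input, "\n")
  cat("  parse failures:      ", x$n_parse_failed, "\n")
  cat("  after dedup:         ", x$n_after_dedup, "\n")
  cat("  after fragment drop: ", x$n_after_fragment_filter, "\n")
  cat("  after length drop:   ", x$n_after_length_filter, "\n")
  cat("  embedded rows:       ", x$n_embedded, "\n")
  invisible(x)
}

#' @export
print.embedding_store <- function(x, ...) {
  cat("<embedding_store>", store_nrow(x), "rows, dim", x$dim, ",",
      length(x$chunks), "chunk(s)\n")
  invisible(x)
}

#' Store accessors
#'
#' `store_nrow` counts rows; `store_smiles` concatenates the SMILES of all
#' chunks in stable order; `store_matrix` stacks all chunk matrices (for
#' desk-scale stores).
#'
#' @param store an `embedding_store`.
#' @export
store_nrow <- function(store) {
  sum(vapply(store$chunks, function(ch) length(ch$smiles), integer(1)))
}

#' @rdname store_nrow
#' @export
store_smiles <- function(store) {
  unlist(lapply(store$chunks, function(ch) ch$smiles), use.names = FALSE)
}

#' @rdname store_nrow
#' @export
store_matrix <- function(store) {
  do.call(rbind, lapply(store$chunks, function(ch) ch$mat))
}

#' Persist / load an embedding store
#'
#' A store directory holds `manifest.json` plus, per chunk, a SMILES text
#' file and a binary little-endian float64 vector file.  The round trip is
#' lossless: SMILES byte-identical, vectors bit-identical.
#'
#' @param store an `embedding_store`.
#' @param path directory path.
#' @export
save_store <- function(store, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  chunk_files <- list()
  for (i in seq_along(store$chunks)) {
    ch <- store$chunks[[i]]
    smi_file <- sprintf("chunk-%06d.smi", i)
    vec_file <- sprintf("chunk-%06d.vec", i)
    writeLines(ch$smiles, file.path(path, smi_file))
    con <- file(file.path(path, vec_file), "wb")
    writeBin(as.numeric(t(ch$mat)), con, size = 8L, endian = "little")
    close(con)
    chunk_files[[i]] <- list(smiles = smi_file, vectors = vec_file,
                             n_rows = length(ch$smiles))
  }
  manifest <- list(dim = store$dim, chunk_size = store$chunk_size,
                   n_rows = store_nrow(store), chunks = chunk_files,
                   filter_counts = store$manifest$filter_counts)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", path)
  mf <- jsonlite::read_json(mf_path)
  dim <- as.integer(mf$dim)
  chunks <- lapply(mf$chunks, function(cf) {
    smi <- readLines(file.path(path, cf$smiles))
    n <- as.integer(cf$n_rows)
    if (length(smi) != n) {
      stop("corrupt store: chunk ", cf$smiles, " has ", length(smi),
           " SMILES but manifest says ", n)
    }
    vec_path <- file.path(path, cf$vectors)
    expected_bytes <- as.numeric(n) * dim * 8
    if (!file.exists(vec_path) || file.size(vec_path) != expected_bytes) {
      stop("corrupt store: ", cf$vectors, " is truncated or missing")
    }
    con <- file(vec_path, "rb")
    v <- readBin(con, what = "numeric", n = n * dim, size = 8L,
                 endian = "little")
    close(con)
    list(smiles = smi, mat = matrix(v, nrow = n, ncol = dim, byrow = TRUE))
  })
  total <- sum(vapply(chunks, function(ch) length(ch$smiles), integer(1)))
  if (total != as.integer(mf$n_rows)) {
    stop("corrupt store: row count mismatch with manifest")
  }
  structure(
    list(chunks = chunks, dim = dim,
         chunk_size = as.integer(mf$chunk_size),
         manifest = list(filter_counts = lapply(mf$filter_counts, as.integer))),
    class = "embedding_store"
  )
}
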