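#' SMILES-aware lexer
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' (`[...]`) as a single token, the two-letter organic-subset halogens `Cl`
#' and `Br`, two-digit ring-bond labels (`%nn`), single-letter atoms
#' (aromatic or aliphatic), ring-closure digits, and bond/branch/charge
#' punctuation, each as one token.  This is the tokenization used by the
#' mock embedder and by the token-level similarity metrics.
#'
#' @param smiles character vector of SMILES strings.
#' @return A list with one character vector of tokens per input string.
#' @examples
#' smiles_tokens("CCO")[[1]]      # "C" "C" "O"
#' smiles_tokens("c1ccccc1")[[1]] # 8 tokens: 6 aromatic carbons + 2 ring digits
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles))
  pat <- "\\[[^][]*\\]|Cl|Br|%[0-9]{2}|[A-Za-z]|[0-9]|[=#$:/\\\\.+*()@~-]"
  regmatches(smiles, gregexpr(pat, smiles, perl = TRUE))
}

# Element symbol of each token ("" for non-atom tokens); used for heavy-atom
# counting on canonical strings, where every atom appears as exactly one
# token and implicit hydrogens are not written.
token_elements <- function(tokens) {
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
               "b", "c", "n", "o", "p", "s")
  el <- character(length(tokens))
  plain <- tokens %in% organic
  el[plain] <- toupper(tokens[plain])
  br <- startsWith(tokens, "[")
  el[br] <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", tokens[br])
  # inside brackets the element may be aromatic lowercase; normalize case
  el[br] <- paste0(toupper(substr(el[br], 1, 1)), substring(el[br], 2))
  el
}

heavy_atom_count <- function(smiles) {
  toks <- smiles_tokens(smiles)
  vapply(toks, function(tk) {
    el <- token_elements(tk)
    sum(nzchar(el) & el != "H")
  }, integer(1))
}

#' Tokenize a SMILES string into a token vector
#'
#' Maps lexer tokens to integer ids through a lazily grown vocabulary, as a
#' transformer tokenizer would.  Ids are assigned on first encounter and are
#' stable for the lifetime of the vocabulary; [save_vocab()] / [load_vocab()]
#' persist them across sessions so the same string always maps to the same
#' id sequence.
#'
#' @param smiles a single nonempty SMILES string.
#' @param vocab a vocabulary environment from [new_vocab()]; defaults to a
#'   package-level shared vocabulary.
#' @return An object of class `token_vector`: a list with `tokens` (integer
#'   ids), `strings` (the lexer tokens) and `length`.
#' @export
tokenize <- function(smiles, vocab = default_vocab()) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("tokenize() requires a single nonempty SMILES string")
  }
  strings <- smiles_tokens(smiles)[[1]]
  ids <- vocab_ids(vocab, strings)
  structure(list(tokens = ids, strings = strings, length = length(ids)),
            class = "token_vector")
}

#' @export
print.token_vector <- function(x, ...) {
  cat("<token_vector> length", x$length, "\n")
  cat(" ", paste(x$strings, collapse = " "), "\n")
  invisible(x)
}

#' Create an empty token vocabulary
#'
#' @return An environment mapping token strings to integer ids.
#' @export
new_vocab <- function() {
  e <- new.env(parent = emptyenv())
  assign(".next_id", 1L, envir = e)
  e
}

vocab_ids <- function(vocab, strings) {
  vapply(strings, function(s) {
    key <- paste0("t:", s)
    if (!exists(key, envir = vocab, inherits = FALSE)) {
      id <- get(".next_id", envir = vocab)
      assign(key, id, envir = vocab)
      assign(".next_id", id + 1L, envir = vocab)
    }
    get(key, envir = vocab, inherits = FALSE)
  }, integer(1), USE.NAMES = FALSE)
}

.chessr_vocab <- new.env(parent = emptyenv())

default_vocab <- function() {
  if (!exists("v", envir = .chessr_vocab, inherits = FALSE)) {
    assign("v", new_vocab(), envir = .chessr_vocab)
  }
  get("v", envir = .chessr_vocab, inherits = FALSE)
}

#' Persist or restore a token vocabulary
#'
#' @param vocab a vocabulary environment.
#' @param path a JSON file path.
#' @export
save_vocab <- function(vocab, path) {
  keys <- setdiff(ls(vocab), ".next_id")
  toks <- sub("^t:", "", keys)
  ids <- vapply(keys, get, integer(1), envir = vocab)
  jsonlite::write_json(
    list(tokens = as.list(stats::setNames(as.integer(ids), toks))),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(path) {
  dat <- jsonlite::read_json(path)
  v <- new_vocab()
  ids <- unlist(dat$tokens)
  for (tok in names(ids)) assign(paste0("t:", tok), as.integer(ids[[tok]]), envir = v)
  assign(".next_id", if (length(ids)) max(as.integer(ids)) + 1L else 1L, envir = v)
  v
}
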