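# LLM-assisted patent functional labeling.
#
# Every network-facing step is injectable: a resolver maps patent ids to
# text records, and an "llm" is any function(system, user) -> character.
# Tests and offline runs use canned transcripts (see make_llm_transcript),
# so the pipeline is fully exercisable without credentials.

SUMMARIZATION_SYSTEM_PROMPT <- "You are an organic chemist summarizing chemical patents."

SUMMARIZATION_USER_PROMPT <- paste0(
  "Return a short set of three 1\u20133 word descriptors that best describe ",
  "the chemical or pharmacological function(s) of the molecule described by ",
  "the given patent title, abstract, and partial description (giving more ",
  "weight to title and abstract). Be specific and concise, but not ",
  "necessarily comprehensive (choose a small number of great descriptor). ",
  "Follow the syntax '{descriptor_1}/{descriptor_2}/{etc}', writing 'NA' if ",
  "nothing is provided. DO NOT BREAK THIS SYNTAX. The following is the patent:")

SIMILARITY_SYSTEM_PROMPT <- "You are an organic chemistry expert."

SIMILARITY_USER_PROMPT <- paste0(
  "The following is a set of functional labels for two different molecules. ",
  "Determine if the two molecules have similar functionality. If similar ",
  "elements are found in both lists, these molecules have similar function. ",
  "You must respond in the format '{yes or no} --- {20 word maximum ",
  "explanation}'")

#' Create a patent text record
#'
#' Holds one patent's title, abstract and description; the description is
#' truncated to `char_cap` characters (default 3,500) to bound downstream
#' token usage.
#'
#' @param patent_id patent identifier string.
#' @param title,abstract,description patent text fields.
#' @param char_cap description character cap (default 3500).
#' @return Object of class `patent_record` with a `truncated` flag.
#' @export
patent_record <- function(patent_id, title = "", abstract = "",
                          description = "", char_cap = 3500L) {
  truncated <- nchar(description) > char_cap
  if (truncated) description <- substr(description, 1L, char_cap)
  structure(list(patent_id = patent_id, title = title, abstract = abstract,
                 description = description, truncated = truncated),
            class = "patent_record")
}

#' Sample patent ids for a molecule
#'
#' At most `limit` patent ids are kept per molecule; when more are linked,
#' a seeded uniform sample without replacement is drawn.
#'
#' @param patent_ids character vector of linked patent ids.
#' @param limit maximum ids retained (default 10).
#' @param seed integer seed making the sample reproducible.
#' @export
sample_patents <- function(patent_ids, limit = 10L, seed = 1L) {
  if (length(patent_ids) <= limit) return(patent_ids)
  with_preserved_seed(seed, sample(patent_ids, limit, replace = FALSE))
}

#' Assemble the patent-summarization prompt
#'
#' @param rec a `patent_record`.
#' @return List with `system`, `user` (the fixed instruction followed by
#'   the patent fields), and `temperature` (0).
#' @export
build_summarization_prompt <- function(rec) {
  stopifnot(inherits(rec, "patent_record"))
  body <- paste0("\n\nTitle: ", rec$title,
                 "\nAbstract: ", rec$abstract,
                 "\nDescription: ", rec$description)
  list(system = SUMMARIZATION_SYSTEM_PROMPT,
       user = paste0(SUMMARIZATION_USER_PROMPT, body),
       temperature = 0)
}

#' Parse a functional-label response
#'
#' Splits on `/`, trims whitespace, drops empty and `NA` entries, and
#' lowercases.  A response that has no separator, is not `NA`, and runs
#' longer than three words breaks the required syntax: it yields an empty
#' label set with `parse_ok = FALSE` so the molecule is still processed
#' and the failure is auditable.
#'
#' @param text the raw model response.
#' @return List with `labels` (character set) and `parse_ok`.
#' @export
parse_label_response <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    return(list(labels = character(0), parse_ok = FALSE))
  }
  trimmed <- trimws(text)
  if (toupper(trimmed) == "NA") {
    return(list(labels = character(0), parse_ok = TRUE))
  }
  if (!grepl("/", trimmed, fixed = TRUE) &&
      length(strsplit(trimmed, "\\s+")[[1]]) > 3L) {
    return(list(labels = character(0), parse_ok = FALSE))
  }
  parts <- trimws(strsplit(trimmed, "/", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts) & toupper(parts) != "NA"]
  list(labels = unique(tolower(parts)), parse_ok = TRUE)
}

#' Assemble the functional-similarity prompt
#'
#' @param query_labels character vector of the query molecule's functional
#'   descriptors.
#' @param molecule_labels character vector of the candidate molecule's
#'   aggregated labels.
#' @return List with `system`, `user`, `temperature` (0).
#' @export
build_similarity_prompt <- function(query_labels, molecule_labels) {
  body <- paste0("\n\nQuery molecule labels: ",
                 paste(query_labels, collapse = ", "),
                 "\nCandidate molecule labels: ",
                 paste(molecule_labels, collapse = ", "))
  list(system = SIMILARITY_SYSTEM_PROMPT,
       user = paste0(SIMILARITY_USER_PROMPT, body),
       temperature = 0)
}

#' Parse a functional-similarity verdict
#'
#' Expects `{yes or no} --- {explanation}` (case-insensitive verdict);
#' anything else is a parse failure.
#'
#' @param text the raw model response.
#' @return List with `verdict` (logical, NA on failure), `explanation`,
#'   `parse_ok`.
#' @export
parse_similarity_verdict <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    return(list(verdict = NA, explanation = NA_character_, parse_ok = FALSE))
  }
  m <- regmatches(text,
                  regexec("^\\s*(yes|no)\\s*---\\s*(.*?)\\s*$", text,
                          ignore.case = TRUE))[[1]]
  if (length(m) != 3L) {
    return(list(verdict = NA, explanation = NA_character_, parse_ok = FALSE))
  }
  list(verdict = tolower(m[2]) == "yes", explanation = m[3], parse_ok = TRUE)
}

#' Aggregate functional labels for one molecule
#'
#' Runs the summarization stage offline: samples at most `limit` linked
#' patents, resolves each to a text record, assembles the prompt, queries
#' the injected `llm`, parses the response, and unions the labels
#' (lowercased, deduplicated; `NA` responses contribute nothing).
#'
#' @param std_smiles the molecule's standardized SMILES (used as its key).
#' @param patent_ids character vector of linked patent ids.
#' @param resolver function(patent_id) -> `patent_record` (or a list with
#'   title/abstract/description fields).
#' @param llm function(system, user) -> character response.
#' @param limit patent cap per molecule (default 10).
#' @param seed sampling seed.
#' @param char_cap description character cap (default 3500).
#' @return Object of class `patent_label_set`: `std_smiles`, `labels`,
#'   `provenance` (per-patent parsed labels and `parse_ok` flags).
#' @export
label_molecule <- function(std_smiles, patent_ids, resolver, llm,
                           limit = 10L, seed = 1L, char_cap = 3500L) {
  ids <- sample_patents(patent_ids, limit = limit, seed = seed)
  provenance <- list()
  labels <- character(0)
  for (pid in ids) {
    rec <- resolver(pid)
    if (!inherits(rec, "patent_record")) {
      rec <- patent_record(pid, title = rec$title %||% "",
                           abstract = rec$abstract %||% "",
                           description = rec$description %||% "",
                           char_cap = char_cap)
    }
    prompt <- build_summarization_prompt(rec)
    response <- llm(prompt$system, prompt$user)
    parsed <- parse_label_response(response)
    provenance[[pid]] <- list(response = response, labels = parsed$labels,
                              parse_ok = parsed$parse_ok)
    labels <- union(labels, parsed$labels)
  }
  structure(list(std_smiles = std_smiles, labels = labels,
                 provenance = provenance),
            class = "patent_label_set")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.patent_label_set <- function(x, ...) {
  cat("<patent_label_set>", x$std_smiles, "\n  ",
      if (length(x$labels)) paste(x$labels, collapse = " / ") else "(none)",
      "\n")
  invisible(x)
}

#' Decide functional similarity between a query and a labeled molecule
#'
#' @param query_labels the query's pre-defined functional descriptors.
#' @param label_set a `patent_label_set` (or character vector of labels).
#' @param llm function(system, user) -> character response.
#' @return List with `verdict`, `explanation`, `parse_ok`, and the raw
#'   `response`.
#' @export
functional_verdict <- function(query_labels, label_set, llm) {
  labels <- if (inherits(label_set, "patent_label_set")) label_set$labels
            else label_set
  prompt <- build_similarity_prompt(query_labels, labels)
  response <- llm(prompt$system, prompt$user)
  parsed <- parse_similarity_verdict(response)
  c(parsed, list(response = response))
}

#' Confusion-matrix validation metrics
#'
#' Accuracy, precision and recall of predicted boolean verdicts against a
#' gold standard.  With no positive predictions, precision is undefined
#' and reported as 0 with `precision_defined = FALSE`; likewise recall
#' when there are no gold positives.
#'
#' @param predicted,gold logical vectors of equal length.
#' @export
validation_metrics <- function(predicted, gold) {
  stopifnot(length(predicted) == length(gold))
  predicted <- as.logical(predicted); gold <- as.logical(gold)
  tp <- sum(predicted & gold); fp <- sum(predicted & !gold)
  fn <- sum(!predicted & gold); tn <- sum(!predicted & !gold)
  precision_defined <- (tp + fp) > 0L
  recall_defined <- (tp + fn) > 0L
  list(accuracy = (tp + tn) / length(gold),
       precision = if (precision_defined) tp / (tp + fp) else 0,
       recall = if (recall_defined) tp / (tp + fn) else 0,
       precision_defined = precision_defined,
       recall_defined = recall_defined,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Stable key for a prompt pair
#'
#' Hash used to index canned transcripts; depends only on the system and
#' user prompt text.
#'
#' @param system,user prompt strings.
#' @export
prompt_key <- function(system, user) {
  s <- paste(system, user, sep = "\x1e")
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(s)) {
    h1 <- (h1 * 131 + b) %% 1048573
    h2 <- (h2 * 137 + b) %% 999983
  }
  sprintf("%06x%06x", h1, h2)
}
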