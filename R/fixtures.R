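# Synthetic fixture generation.
#
# Everything here is generated in code at run time: SMILES databases with a
# controlled number of duplicates, multi-fragment (salt-like) records and
# over-length records, so every stage of the database filter cascade is
# exercisable offline; scaffold families sharing one Murcko framework; and
# canned LLM transcripts for the patent pipeline.

#' Specification for a synthetic SMILES database
#'
#' @param n_molecules total number of emitted records.
#' @param frac_duplicates fraction of records that duplicate an earlier
#'   record's structure (possibly written differently).
#' @param frac_multifragment fraction of `.`-joined multi-fragment records.
#' @param frac_overlength fraction of records engineered to tokenize past
#'   512 tokens (long explicit-double-bond chains).
#' @param n_scaffold_families number of ring cores the base molecules are
#'   drawn from.
#' @param seed integer seed; the same spec always yields the same database.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 100L, frac_duplicates = 0.1,
                         frac_multifragment = 0.05, frac_overlength = 0.02,
                         n_scaffold_families = 8L, seed = 1L) {
  fr <- c(frac_duplicates, frac_multifragment, frac_overlength)
  stopifnot(n_molecules >= 1L, all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            n_scaffold_families >= 1L)
  structure(list(n_molecules = as.integer(n_molecules),
                 frac_duplicates = frac_duplicates,
                 frac_multifragment = frac_multifragment,
                 frac_overlength = frac_overlength,
                 n_scaffold_families = as.integer(n_scaffold_families),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Ring cores with one substitution slot.  All parse under OpenBabel.
fixture_cores <- c(
  "c1ccc(%s)cc1",        # benzene
  "c1ccnc(%s)c1",        # pyridine
  "c1cc(%s)co1",         # furan
  "c1cc(%s)cs1",         # thiophene
  "C1CCN(%s)CC1",        # piperidine
  "C1CCC(%s)CC1",        # cyclohexane
  "c1ccc2cc(%s)ccc2c1",  # naphthalene
  "C1COC(%s)C1"          # tetrahydrofuran
)

fixture_chain_units <- c("C", "CC", "CO", "CN", "CCO", "CCN", "OC", "NC")

# One random linear side chain; concatenation of the units above is always
# a valid SMILES chain.
random_chain <- function(max_units = 4L) {
  k <- sample.int(max_units, 1L)
  paste(sample(fixture_chain_units, k, replace = TRUE), collapse = "")
}

#' Generate a synthetic SMILES database with known filter violations
#'
#' Base molecules are substituted ring systems drawn from
#' `n_scaffold_families` cores, mutually distinct after standardization.
#' Into the stream are injected: duplicates of earlier base records (half
#' as exact copies, half re-written with a different root atom, so
#' deduplication on the canonical form is exercised), `.`-joined
#' fragment records, and over-length records built from long explicit
#' double-bond chains.  The three violation groups are disjoint, so the
#' expected surviving row count is
#' `n_molecules - n_dup - n_frag - n_over`.
#'
#' @param spec a [fixture_spec()].
#' @return List with `smiles` (the record stream) and `manifest` (expected
#'   per-filter counts: `n_input`, `n_duplicates`, `n_multifragment`,
#'   `n_overlength`, `n_expected_rows`).
#' @export
make_smiles_db <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_molecules
  n_dup <- as.integer(round(spec$frac_duplicates * n))
  n_frag <- as.integer(round(spec$frac_multifragment * n))
  n_over <- as.integer(round(spec$frac_overlength * n))
  n_base <- n - n_dup - n_frag - n_over
  stopifnot(n_base >= 1L)

  with_preserved_seed(spec$seed, {
    cores <- fixture_cores[((seq_len(spec$n_scaffold_families) - 1L) %%
                              length(fixture_cores)) + 1L]
    # draw base molecules until n_base distinct canonical forms
    base_std <- character(0)
    base_raw <- character(0)
    guard <- 0L
    while (length(base_std) < n_base) {
      guard <- guard + 1L
      if (guard > 200L) stop("fixture generation failed to find enough distinct molecules")
      need <- n_base - length(base_std)
      cand <- vapply(seq_len(need * 2L), function(i) {
        sprintf(sample(cores, 1L), random_chain())
      }, character(1))
      std <- ob_canonical(cand)
      ok <- !is.na(std) & !duplicated(std) & !(std %in% base_std)
      take <- utils::head(which(ok), need)
      base_raw <- c(base_raw, cand[take])
      base_std <- c(base_std, std[take])
    }

    frag_entries <- if (n_frag > 0L) {
      counter <- c("Cl", "O=C(O)C(=O)O", "OS(=O)(=O)O", "CC(=O)O")
      paste0(base_raw[seq_len(n_frag)], ".",
             counter[((seq_len(n_frag) - 1L) %% length(counter)) + 1L])
    } else character(0)
    over_entries <- if (n_over > 0L) {
      vapply(seq_len(n_over), function(i) {
        strrep("C=C", 260L + i)  # > 512 tokens, single fragment, all distinct
      }, character(1))
    } else character(0)

    # stream layout: slot 1 is always a base record so every duplicate can
    # point at an earlier occurrence
    slots <- rep("base", n)
    extra <- c(rep("dup", n_dup), rep("frag", n_frag), rep("over", n_over))
    if (length(extra) > 0L) {
      pos <- 1L + sample.int(n - 1L, length(extra))
      slots[pos] <- extra[sample.int(length(extra))]
    }
    stream <- character(n)
    base_i <- 0L
    base_slot_pos <- integer(0)
    for (i in seq_len(n)) {
      kind <- slots[i]
      if (kind == "base") {
        base_i <- base_i + 1L
        stream[i] <- base_raw[base_i]
        base_slot_pos <- c(base_slot_pos, i)
      } else if (kind == "frag") {
        frag_i <- sum(slots[seq_len(i)] == "frag")
        stream[i] <- frag_entries[frag_i]
      } else if (kind == "over") {
        over_i <- sum(slots[seq_len(i)] == "over")
        stream[i] <- over_entries[over_i]
      } else {
        earlier <- sum(slots[seq_len(i - 1L)] == "base")
        src <- sample.int(earlier, 1L)
        src_std <- base_std[src]
        # half exact copies, half re-rooted writings of the same structure
        if (stats::runif(1) < 0.5) {
          stream[i] <- src_std
        } else {
          rerooted <- ob_rooted(src_std, 2L)
          stream[i] <- if (is.na(rerooted)) src_std else rerooted
        }
      }
    }
    list(smiles = stream,
         manifest = list(n_input = n, n_duplicates = n_dup,
                         n_multifragment = n_frag, n_overlength = n_over,
                         n_expected_rows = n_base))
  })
}

#' Generate a family of molecules sharing one Murcko scaffold
#'
#' @param core_pattern a SMILES template with one `%s` substitution slot
#'   (e.g. `"c1ccc(%s)cc1"`).
#' @param n_variants number of molecules; side chains differ, the ring
#'   framework does not.
#' @param seed integer seed.
#' @return Character vector of distinct canonical SMILES.
#' @export
make_scaffold_family <- function(core_pattern, n_variants, seed = 1L) {
  stopifnot(grepl("%s", core_pattern, fixed = TRUE), n_variants >= 1L)
  with_preserved_seed(seed, {
    out <- character(0)
    guard <- 0L
    while (length(out) < n_variants) {
      guard <- guard + 1L
      if (guard > 200L) stop("could not generate enough distinct variants")
      cand <- vapply(seq_len((n_variants - length(out)) * 2L), function(i) {
        sprintf(core_pattern, random_chain())
      }, character(1))
      std <- ob_canonical(cand)
      ok <- !is.na(std) & !duplicated(std) & !(std %in% out)
      out <- c(out, utils::head(std[ok], n_variants - length(out)))
    }
    out
  })
}

#' Canned LLM transcripts for offline pipeline runs
#'
#' Builds a transcript table (prompt key -> response) for a list of
#' prompts, with responses that follow the pipeline's response syntax
#' (`behavior = "faithful"`), deliberately violate it (`"malformed"`), or
#' decline to label (`"na"`).  Summarization and similarity prompts are
#' recognized by their system prompt, so one transcript can drive both
#' stages.
#'
#' @param prompts list of prompt pairs (each a list with `system` and
#'   `user`), e.g. from [build_summarization_prompt()].
#' @param behavior `"faithful"`, `"malformed"`, or `"na"`.
#' @return data.frame with columns `key`, `system`, `response`.
#' @export
make_llm_transcript <- function(prompts,
                                behavior = c("faithful", "malformed", "na")) {
  behavior <- match.arg(behavior)
  rows <- lapply(prompts, function(p) {
    is_similarity <- identical(p$system, SIMILARITY_SYSTEM_PROMPT)
    response <- switch(
      behavior,
      faithful = if (is_similarity) faithful_verdict(p$user)
                 else faithful_labels(p$user),
      malformed = "I am afraid I cannot commit to a structured answer here.",
      na = if (is_similarity) "unclear" else "NA"
    )
    data.frame(key = prompt_key(p$system, p$user), system = p$system,
               response = response, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Deterministic plausible label response derived from the prompt text.
faithful_labels <- function(user) {
  title <- sub(".*Title: ([^\n]*).*", "\\1", user)
  words <- strsplit(tolower(gsub("[^A-Za-z ]", "", title)), "\\s+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) words <- c("chemical", "compound", "synthesis")
  paste(utils::head(unique(words), 3L), collapse = "/")
}

# Verdict yes iff the two printed label lists share an element.
faithful_verdict <- function(user) {
  q <- sub(".*Query molecule labels: ([^\n]*).*", "\\1", user)
  m <- sub(".*Candidate molecule labels: ([^\n]*).*", "\\1", user)
  qs <- trimws(strsplit(q, ",")[[1]])
  ms <- trimws(strsplit(m, ",")[[1]])
  if (length(intersect(qs[nzchar(qs)], ms[nzchar(ms)])) > 0L) {
    "yes --- the two label sets share functional elements"
  } else {
    "no --- the label sets describe unrelated functionality"
  }
}

#' Replay a transcript as an LLM backend
#'
#' @param transcript a data.frame from [make_llm_transcript()] or
#'   [read_transcript()].
#' @return function(system, user) -> response; unknown prompts raise an
#'   error naming the missing key.
#' @export
transcript_llm <- function(transcript) {
  stopifnot(all(c("key", "response") %in% names(transcript)))
  function(system, user) {
    k <- prompt_key(system, user)
    i <- match(k, transcript$key)
    if (is.na(i)) stop("no canned response for prompt key ", k)
    transcript$response[i]
  }
}

#' Write / read a transcript as JSON lines
#'
#' @param transcript data.frame with columns key, system, response.
#' @param path file path.
#' @export
write_transcript <- function(transcript, path) {
  lines <- vapply(seq_len(nrow(transcript)), function(i) {
    jsonlite::toJSON(as.list(transcript[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
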