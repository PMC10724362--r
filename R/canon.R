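#' Standardize a raw SMILES string
#'
#' Produces the package's reference representation of a molecule: the
#' stereochemistry is removed on the parsed structure (never by character
#' surgery, so bond-direction slashes cannot corrupt ring closures), and
#' the achiral graph is written by the default canonical writer.  All
#' database entries and all query records pass through this function, so
#' any two writings of the same connectivity collapse to one string.
#'
#' @param raw_smiles a single SMILES string.
#' @return An object of class `molecule_record`: list with `raw_smiles`,
#'   `std_smiles` (achiral canonical form) and `n_atoms` (heavy atoms).
#' @examples
#' \donttest{
#' standardize("C[C@@H](N)C(=O)O")$std_smiles  # stereo stripped
#' }
#' @export
standardize <- function(raw_smiles) {
  stopifnot(is.character(raw_smiles), length(raw_smiles) == 1L)
  std <- ob_canonical(raw_smiles)
  if (is.na(std)) {
    stop("unparseable SMILES: '", raw_smiles, "'")
  }
  structure(
    list(raw_smiles = raw_smiles, std_smiles = std,
         n_atoms = heavy_atom_count(std)),
    class = "molecule_record"
  )
}

# Vectorized standardization for database builds; NA rows mark parse
# failures instead of raising.
standardize_batch <- function(raw_smiles) {
  std <- ob_canonical(raw_smiles)
  data.frame(raw_smiles = raw_smiles, std_smiles = std,
             stringsAsFactors = FALSE)
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record>", x$std_smiles, "(", x$n_atoms, "heavy atoms )\n")
  invisible(x)
}

as_molecule_record <- function(x) {
  if (inherits(x, "molecule_record")) x else standardize(x)
}

canonical_variant <- function(smiles, scheme, root_atom = NA_integer_,
                              distance_to_default = NA_real_) {
  scheme <- match.arg(scheme, c("default_root", "alt_root", "external"))
  structure(
    list(smiles = smiles, scheme = scheme,
         root_atom = if (is.na(root_atom)) NA_integer_ else as.integer(root_atom),
         distance_to_default = distance_to_default),
    class = "canonical_variant"
  )
}

#' @export
print.canonical_variant <- function(x, ...) {
  cat("<canonical_variant>", x$scheme,
      if (!is.na(x$root_atom)) paste0("(root ", x$root_atom, ")") else "",
      "\n ", x$smiles, "\n")
  if (!is.na(x$distance_to_default)) {
    cat("  cosine to default:", format(x$distance_to_default), "\n")
  }
  invisible(x)
}

#' Enumerate rooted canonical writings of a molecule
#'
#' Writes one SMILES per heavy-atom root index 0..n_atoms-1.  Root 0 is the
#' default canonical form itself; every other root forces the traversal of
#' the canonical atom order to begin at that atom, yielding a different but
#' equivalent string.  All variants re-canonicalize to `std_smiles`.
#'
#' @param record a `molecule_record` (or a SMILES string, standardized
#'   first).
#' @return A list of `canonical_variant` objects ordered by root index;
#'   element 1 (root 0) has scheme `default_root`.
#' @export
enumerate_rooted <- function(record) {
  record <- as_molecule_record(record)
  n <- record$n_atoms
  out <- vector("list", n)
  out[[1L]] <- canonical_variant(record$std_smiles, "default_root",
                                 root_atom = 0L)
  if (n > 1L) {
    rooted <- vapply(2L:n, function(k) ob_rooted(record$std_smiles, k),
                     character(1))
    if (anyNA(rooted)) {
      stop("rooted SMILES generation failed at root atom ",
           which(is.na(rooted))[1], " for ", record$std_smiles)
    }
    rooted <- repair_rooted(rooted, record$std_smiles)
    for (k in 2L:n) {
      out[[k]] <- canonical_variant(rooted[k - 1L], "alt_root",
                                    root_atom = k - 1L)
    }
  }
  out
}

# The rooted writer occasionally drops the implicit hydrogen of a bracket
# root atom (e.g. an aromatic [nH] written as bare [n]), which would change
# the molecular graph.  Every rooted writing is validated against the
# canonical form; a failing writing is first repaired by restoring the H
# inside the leading bracket atom and, if that still fails, replaced by the
# canonical writing itself (a duplicate string, deduplicated downstream).
repair_rooted <- function(rooted, std_smiles) {
  recanon <- ob_canonical(rooted)
  bad <- which(is.na(recanon) | recanon != std_smiles)
  if (length(bad) == 0L) return(rooted)
  fixed <- sub("^(\\[[A-Za-z][a-z]?)\\]", "\\1H]", rooted[bad])
  refixed <- ob_canonical(fixed)
  ok <- !is.na(refixed) & refixed == std_smiles
  rooted[bad[ok]] <- fixed[ok]
  rooted[bad[!ok]] <- std_smiles
  rooted
}

#' Select the maximum-distance rooted variant ("Atom n" query)
#'
#' Embeds every rooted writing and returns the one whose embedding has the
#' *minimum* cosine similarity to the default-root embedding, i.e. the
#' writing farthest from the default in feature space.  Identical strings
#' produced by different roots are embedded once and mapped back to the
#' lowest producing root index; ties in cosine (within 1e-12) are broken
#' toward the lowest root index.
#'
#' @param variants nonempty list of `canonical_variant`s whose first element
#'   is the default-root variant (as produced by [enumerate_rooted()]).
#' @param embedder a `chess_embedder`.
#' @return The selected variant with scheme `alt_root` and
#'   `distance_to_default` set to its cosine similarity to the default root.
#' @export
select_max_distance_variant <- function(variants, embedder) {
  stopifnot(is.list(variants), length(variants) >= 1L)
  if (variants[[1L]]$scheme != "default_root") {
    stop("variants[[1]] must be the default_root variant")
  }
  smiles <- vapply(variants, function(v) v$smiles, character(1))
  roots <- vapply(variants, function(v) v$root_atom, integer(1))
  # deduplicate identical strings, keeping the lowest producing root
  first_idx <- !duplicated(smiles)
  uniq <- smiles[first_idx]
  uniq_root <- roots[first_idx]
  emb <- tryCatch(
    embed_smiles(embedder, uniq),
    error = function(e) {
      stop("embedding failed while scoring rooted variants (",
           conditionMessage(e), ")")
    }
  )
  ref <- emb[match(variants[[1L]]$smiles, uniq), ]
  cosines <- as.numeric(emb %*% ref)
  best <- min(cosines)
  cand <- which(cosines <= best + 1e-12)
  sel <- cand[which.min(uniq_root[cand])]
  canonical_variant(uniq[sel], "alt_root", root_atom = uniq_root[sel],
                    distance_to_default = cosines[sel])
}

#' Attach an externally canonicalized SMILES as a query variant
#'
#' A third-party canonical writing (for example one obtained from a
#' different toolkit's canonicalizer) is accepted verbatim -- including its
#' Kekule/aromatic conventions, since the representational difference is
#' the point -- after checking that it encodes the same connectivity as the
#' record.
#'
#' @param record a `molecule_record`.
#' @param external_smiles the externally supplied SMILES string.
#' @return A `canonical_variant` with scheme `external` and no root atom.
#' @export
attach_external <- function(record, external_smiles) {
  record <- as_molecule_record(record)
  stopifnot(is.character(external_smiles), length(external_smiles) == 1L)
  ext_std <- ob_canonical(external_smiles)
  if (is.na(ext_std)) {
    stop("unparseable external SMILES: '", external_smiles, "'")
  }
  if (!identical(ext_std, record$std_smiles)) {
    stop("external SMILES has different connectivity: canonical form '",
         ext_std, "' does not match record '", record$std_smiles, "'")
  }
  canonical_variant(external_smiles, "external")
}

#' Build the three query representations of a molecule
#'
#' Convenience wrapper returning the default-root canonical form, the
#' maximum-distance rooted form (via [select_max_distance_variant()]), and,
#' when supplied, an external canonical form.
#'
#' @param record a `molecule_record` or SMILES string.
#' @param embedder a `chess_embedder` used to score rooted variants.
#' @param external_smiles optional third-party canonical SMILES.
#' @return Named list of `canonical_variant`s: `default_root`, `alt_root`,
#'   and optionally `external`.
#' @export
query_variants <- function(record, embedder, external_smiles = NULL) {
  record <- as_molecule_record(record)
  variants <- enumerate_rooted(record)
  out <- list(
    default_root = variants[[1L]],
    alt_root = select_max_distance_variant(variants, embedder)
  )
  if (!is.null(external_smiles)) {
    out$external <- attach_external(record, external_smiles)
  }
  out
}

#' Read query SMILES from a file
#'
#' Accepts either a newline-delimited SMILES file or a CSV with a `smiles`
#' column (optionally `external_smiles` for third-party canonical forms).
#'
#' @param path input file path.
#' @return data.frame with columns `smiles` and (possibly NA)
#'   `external_smiles`.
#' @export
read_smiles_input <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first) && grepl("smiles", tolower(first))) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV input needs a 'smiles' column")
    if (!"external_smiles" %in% names(df)) df$external_smiles <- NA_character_
    df[c("smiles", "external_smiles")]
  } else {
    smi <- readLines(path)
    smi <- smi[nzchar(trimws(smi))]
    data.frame(smiles = trimws(smi), external_smiles = NA_character_,
               stringsAsFactors = FALSE)
  }
}

#' Tabulate query variants for export
#'
#' @param record a `molecule_record` or SMILES string.
#' @param variants list of `canonical_variant`s (e.g. from
#'   [query_variants()]).
#' @return data.frame with columns std_smiles, scheme, root_atom, smiles,
#'   distance_to_default.
#' @export
variants_table <- function(record, variants) {
  record <- as_molecule_record(record)
  do.call(rbind, lapply(variants, function(v) {
    data.frame(std_smiles = record$std_smiles, scheme = v$scheme,
               root_atom = if (is.na(v$root_atom)) NA_integer_ else v$root_atom,
               smiles = v$smiles,
               distance_to_default = v$distance_to_default,
               stringsAsFactors = FALSE)
  }))
}

#' Kekule writing of a molecule
#'
#' Canonical atom order but with explicit alternating double bonds instead
#' of lowercase aromatic notation.  Since preferring the Kekule form is the
#' hallmark of several alternative canonicalization algorithms, this writer
#' provides a convenient synthetic "external" canonical form for testing
#' and desk-scale studies when no third-party canonicalizer output is at
#' hand.
#'
#' @param smiles character vector of SMILES.
#' @return Character vector of Kekule writings (NA for unparseable input).
#' @export
kekule_smiles <- function(smiles) {
  ob_convert(smiles, out_format = "smi", write_opts = c("-xi", "-xk"))
}
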