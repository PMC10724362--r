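# Thin batch wrapper around the OpenBabel `obabel` executable.
#
# The in-process ChemmineOB bindings do not forward the SMILES writer
# options this package depends on (`i` to drop stereo annotations, `f` to
# root the output at a given atom), so conversions are performed by the
# command-line tool, one process call per batch.  Input lines carry a title
# (the input index) so that records dropped by OpenBabel's parser can be
# identified: `-e` makes obabel continue past unparseable records, and any
# index missing from the output is reported as a parse failure.

ob_available <- function() nzchar(Sys.which("obabel"))

# Run obabel over a character vector of SMILES.  Returns a character vector
# aligned with `smiles`; entries OpenBabel could not parse are NA.
ob_convert <- function(smiles, out_format = "can", write_opts = character()) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  if (!ob_available()) {
    stop("the 'obabel' executable was not found on the PATH")
  }
  bad <- is.na(smiles) | !nzchar(smiles) | grepl("[\t\n]", smiles)
  idx <- which(!bad)
  out <- rep(NA_character_, n)
  if (length(idx) == 0L) return(out)

  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste0(smiles[idx], "\t", idx), infile)

  args <- c("-ismi", infile, paste0("-o", out_format), "-e", write_opts)
  res <- suppressWarnings(
    system2("obabel", args, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L && length(res) == 0L) {
    stop("obabel failed (exit status ", status, ")")
  }
  for (line in res) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    i <- suppressWarnings(as.integer(trimws(parts[2L])))
    if (is.na(i)) next
    smi <- trimws(parts[1L])
    if (nzchar(smi)) out[i] <- smi
  }
  out
}

# Achiral canonical SMILES (the package's default canonicalization):
# stereochemistry is removed on the parsed structure (writer option `i`),
# then the canonical writer picks the standard atom order.
ob_canonical <- function(smiles) {
  ob_convert(smiles, out_format = "can", write_opts = "-xi")
}

# SMILES rooted at `root` (1-based atom index in the input atom order).
# Deterministic given the input string; used on already-canonical input so
# the atom order itself is canonical.
ob_rooted <- function(smiles, root) {
  stopifnot(length(root) == 1L, root >= 1L)
  ob_convert(smiles, out_format = "smi",
             write_opts = c("-xi", "-xf", as.character(as.integer(root))))
}
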