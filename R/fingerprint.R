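# Structural fingerprints and Murcko scaffolds.
#
# Fingerprints are OpenBabel FP2 path fingerprints (linear fragments of
# 1-7 atoms hashed into 1024 bits), computed in-process through
# ChemmineR/ChemmineOB.  The bit *sets* are exposed so that structural
# similarity goes through the same Tanimoto definition as every other
# set metric in the package.

#' Fingerprint bit sets
#'
#' @param smiles character vector of SMILES.
#' @return A list, one element per input: an integer vector of set bit
#'   positions (1-based, in 1..1024), or `NULL` for unparseable input.
#' @export
fingerprint_bits <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  if (length(smiles) == 0L) return(out)
  std <- ob_canonical(smiles)
  ok <- which(!is.na(std))
  if (length(ok) == 0L) return(out)
  sdf <- parse_sdf(smiles[ok])
  # bond-less molecules (single heavy atom) carry no linear paths: their
  # fingerprint is the empty bit set, not a failure
  for (i in ok) out[[i]] <- integer(0)
  valid <- which(ChemmineR::validSDF(sdf))
  if (length(valid) == 0L) return(out)
  fp <- ChemmineR::fingerprintOB(sdf[valid], "FP2")
  m <- methods::slot(fp, "fpma")
  for (j in seq_along(valid)) {
    out[[ok[valid[j]]]] <- which(m[j, ] != 0)
  }
  out
}

parse_sdf <- function(smiles) {
  names(smiles) <- paste0("m", seq_along(smiles))
  suppressWarnings(ChemmineR::smiles2sdf(smiles))
}

#' Murcko scaffold of a molecule
#'
#' The scaffold is the union of all ring systems plus the linker atoms
#' connecting them (the 2-core of the molecular graph), keeping atoms
#' attached to that framework by a double or triple bond (e.g. exocyclic
#' carbonyl oxygens); all other side-chain atoms are removed.  An acyclic
#' molecule has an empty scaffold, returned as `""`.
#'
#' @param smiles character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for unparseable input).
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)
  std <- ob_canonical(smiles)
  ok <- which(!is.na(std))
  if (length(ok) == 0L) return(out)
  sdf <- parse_sdf(std[ok])
  valid <- ChemmineR::validSDF(sdf)
  blocks <- character(0)
  block_owner <- integer(0)
  for (j in which(valid)) {
    mol <- sdf[[j]]
    sdftxt <- scaffold_sdf(mol)
    if (is.null(sdftxt)) {
      out[ok[j]] <- ""
    } else {
      blocks <- c(blocks, sdftxt)
      block_owner <- c(block_owner, ok[j])
    }
  }
  if (length(blocks) > 0L) {
    scaff <- sdf_to_canonical(blocks)
    out[block_owner] <- scaff
  }
  out
}

# V2000 text for the scaffold substructure of one SDF molecule, or NULL if
# the molecule is acyclic.
scaffold_sdf <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  n_atoms <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0L || n_atoms == 0L) return(NULL)
  from <- as.integer(bb[, 1]); to <- as.integer(bb[, 2])
  order <- as.integer(bb[, 3])

  # 2-core: iteratively prune degree-<=1 atoms; what survives is exactly
  # the ring systems plus the linkers between them.
  alive <- rep(TRUE, n_atoms)
  repeat {
    deg <- tabulate(c(from[alive[from] & alive[to]],
                      to[alive[from] & alive[to]]), nbins = n_atoms)
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  if (!any(alive)) return(NULL)

  # keep side-chain atoms multiply bonded to the framework (carbonyls etc.)
  keep <- alive
  attach_bonds <- which(order >= 2L &
                          (alive[from] + alive[to] == 1L))
  for (b in attach_bonds) {
    keep[from[b]] <- TRUE
    keep[to[b]] <- TRUE
  }

  kept <- which(keep)
  remap <- integer(n_atoms)
  remap[kept] <- seq_along(kept)
  kb <- which(keep[from] & keep[to])

  elements <- sub("_[0-9]+$", "", rownames(ab))
  charges <- atom_charges(ab)

  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, elements[kept])
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        remap[from[kb]], remap[to[kb]], order[kb])
  chg <- which(charges[kept] != 0L)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, charges[kept][i])
    }, character(1))
  } else character(0)

  paste(c("scaffold", "  chessr", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(kept), length(kb)),
          atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

atom_charges <- function(ab) {
  cn <- colnames(ab)
  if ("charge" %in% cn) return(as.integer(ab[, "charge"]))
  # V2000 legacy charge codes in column 5 of the atom block (C3 here)
  if ("C3" %in% cn) {
    code <- as.integer(ab[, "C3"])
    chg <- integer(nrow(ab))
    chg[code == 1L] <- 3L; chg[code == 2L] <- 2L; chg[code == 3L] <- 1L
    chg[code == 5L] <- -1L; chg[code == 6L] <- -2L; chg[code == 7L] <- -3L
    return(chg)
  }
  integer(nrow(ab))
}

sdf_to_canonical <- function(sdf_blocks) {
  infile <- tempfile(fileext = ".sdf")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(sdf_blocks, collapse = "\n"), infile)
  res <- suppressWarnings(
    system2("obabel", c("-isdf", infile, "-ocan", "-xi", "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  smi <- vapply(res, function(line) {
    trimws(strsplit(line, "\t", fixed = TRUE)[[1]][1])
  }, character(1), USE.NAMES = FALSE)
  if (length(smi) != length(sdf_blocks)) {
    stop("scaffold canonicalization failed for ",
         length(sdf_blocks) - length(smi), " molecule(s)")
  }
  smi
}
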