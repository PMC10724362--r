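# Independent oracles implemented outside the package code paths.

# Reference gestalt (Ratcliff-Obershelp) ratios from Python's difflib,
# the classical reference implementation of the algorithm, with the junk
# heuristic disabled.  One interpreter call scores a whole batch of pairs.
difflib_gestalt <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  stopifnot(nzchar(py))
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  scriptf <- tempfile(fileext = ".py")
  on.exit(unlink(c(inp, outp, scriptf)), add = TRUE)
  jsonlite::write_json(list(a = s1, b = s2), inp)
  writeLines(c(
    "import json, sys",
    "from difflib import SequenceMatcher",
    "d = json.load(open(sys.argv[1]))",
    "r = [SequenceMatcher(None, x, y, autojunk=False).ratio()",
    "     for x, y in zip(d['a'], d['b'])]",
    "json.dump(r, open(sys.argv[2], 'w'))"
  ), scriptf)
  status <- system2(py, c(scriptf, inp, outp))
  stopifnot(status == 0L)
  as.numeric(jsonlite::read_json(outp, simplifyVector = TRUE))
}

# Reference Murcko scaffolds from RDKit (Python), compared at the level of
# the molecular graph: both scaffold strings are re-canonicalized through
# the package's default canonicalizer before comparison, since the two
# toolkits write different canonical strings for the same graph.
rdkit_murcko <- function(smiles) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  stopifnot(nzchar(py))
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  scriptf <- tempfile(fileext = ".py")
  on.exit(unlink(c(inp, outp, scriptf)), add = TRUE)
  jsonlite::write_json(smiles, inp)
  writeLines(c(
    "import json, sys",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "smis = json.load(open(sys.argv[1]))",
    "out = []",
    "for s in smis:",
    "    m = Chem.MolFromSmiles(s)",
    "    if m is None:",
    "        out.append(None)",
    "        continue",
    "    sc = MurckoScaffold.GetScaffoldForMol(m)",
    "    out.append(Chem.MolToSmiles(sc))",
    "json.dump(out, open(sys.argv[2], 'w'))"
  ), scriptf)
  status <- system2(py, c(scriptf, inp, outp), stderr = FALSE)
  stopifnot(status == 0L)
  res <- jsonlite::read_json(outp, simplifyVector = FALSE)
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}
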