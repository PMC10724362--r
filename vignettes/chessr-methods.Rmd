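---
title: "Representation-sensitive chemical similarity search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representation-sensitive chemical similarity search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

A molecule has many valid SMILES writings; a canonicalizer picks one
deterministically, and different algorithms pick different ones. A
sequence encoder embeds the *writing*, not the graph, so embeddings of
the same molecule under different canonicalizations disagree. `chessr`
operationalizes that disagreement as a search strategy with three query
schemes against one fixed database embedding:

* `default_root` — the database's own canonical form. Query and
  database share a writing convention, so string-level overlap dominates
  and the search approximates a structural-similarity search.
* `alt_root` — among all rooted canonical writings of the query (one
  per heavy atom, the traversal forced to begin at that atom), the one
  whose embedding has *minimum* cosine similarity to the default
  writing's embedding. This is the cheapest in-toolkit way to push the
  query away from its database representation while keeping the graph
  fixed.
* `external` — a canonical form produced by a different algorithm and
  supplied verbatim (never re-canonicalized, since the representational
  difference is the point; e.g. algorithms that prefer Kekulé writings
  over aromatic lowercase).

Search itself is an exact, chunk-streamed top-k scan by cosine
similarity over L2-normalized vectors. No approximate index is used, so
results are bit-reproducible and independent of chunk layout.

The working hypothesis the schemes probe: an alternatively canonicalized
query is out-of-distribution at the level of local token relationships
but not of token identities, which suppresses memorized string matching
while leaving whole-molecule information intact. The analysis panels
(`divergence_panel`, `result_profile`, `rank_comparison`) quantify
exactly this: how far the query writings diverge as model inputs, and
how the character of the result set changes per scheme.

## Canonicalization backend

Standardization parses the molecule, removes all tetrahedral and
double-bond stereo annotations on the parsed structure (never by
character surgery), and writes the achiral canonical SMILES with
OpenBabel's canonical writer. "Achiral" is implemented as full removal
of stereo layers, because the downstream encoders do not support
isomeric SMILES. Canonical forms are toolkit-relative: the same graph
canonicalized elsewhere yields a different string, which is precisely
the effect the `external` scheme exploits.

Rooted writings come from OpenBabel's first-atom writer option applied
to the canonical string, so the atom numbering is itself canonical and
the enumeration is deterministic. Two robustness measures apply:

* The writer occasionally drops the implicit hydrogen of a bracket root
  atom (an aromatic `[nH]` written as bare `[n]`), which would silently
  change the graph. Every rooted writing is therefore validated by
  re-canonicalization; a failing writing is repaired by restoring the H
  in the leading bracket atom, and if that still fails, it is replaced
  by the canonical writing itself (a duplicate, removed downstream).
* Different roots can produce identical strings. Enumeration keeps all
  of them (one per root index), but selection deduplicates before
  embedding and maps back to the lowest producing root.

Tie-breaking in the maximum-distance selection: cosines within 1e-12 of
the minimum are considered tied and the lowest root index wins, so the
selected variant is reproducible across platforms.

Multi-fragment inputs are rejected as queries and filtered from
databases; rooting across disconnected fragments is ill-defined and the
database filter removes such records anyway.

## The mock embedder

The search method relies on exactly three properties of the encoder:
determinism, sensitivity to token order, and fixed-width unit-norm
output. The mock embedder supplies these without trained weights: the
SMILES-aware lexer (bracket atoms as one token, two-letter halogens,
`%nn` ring labels, single-character atoms/bonds/branches) produces a
token sequence; uni-, bi- and tri-grams of tokens are hashed into 4,096
count bins; the counts are projected through a fixed Gaussian random
matrix seeded by the embedder's `seed`; the result is L2-normalized.
Defaults: `dim = 768` (a typical BERT hidden width), `max_tokens = 512`
(the usual encoder context limit, which is also the database length
filter), `n_bins = 4096`.

What the mock does *not* emulate is chemical semantics: its notion of
similarity is n-gram overlap, not learned molecular properties. Tests
passing under the mock therefore certify the pipeline — enumeration,
selection, filtering, exact search, metrics, statistics — not the
chemistry of any particular language model. A pretrained encoder enters
through `transformer_embedder`, which fixes the pooling convention
(first-position vector of the final layer) and the token limit but
leaves tokenizer and encoder injectable.

Embeddings are kept and stored as 64-bit floats. Storing 32-bit floats
was considered and rejected: quantizing a normalized vector perturbs its
norm at about 1e-7, which is incompatible with holding stored rows to
unit norm within 1e-9 and with bit-identical save/load round-trips.

## Database construction

The filter cascade runs in a fixed order: parse/standardize (failures
dropped and counted with their line numbers), deduplicate on the
canonical form keeping the first occurrence in stream order, drop
records containing the `.` fragment separator (salts, counterions,
complexes — whole-record removal), drop records tokenizing beyond the
embedder's limit, then embed and chunk. Deduplication before the
fragment/length filters is a choice of bookkeeping, not of outcome for
the surviving set; the build report makes each stage's count explicit,
and conservation (`input = embedded + dropped per stage`) is asserted in
tests. Chunks default to 100,000 rows; iteration order is stable and
chunk-size invariant, and persistence (text SMILES + little-endian
float64 vectors + JSON manifest) round-trips byte-identically.

## Metrics and numerical conventions

* **Gestalt (Ratcliff–Obershelp) similarity** `2·Km/(|S1|+|S2|)`: `Km`
  counts matched characters from the longest common substring plus
  recursive matching in the unmatched regions on both sides. The pure
  algorithm is implemented — no junk or popularity heuristics, which in
  common library defaults alter results on long strings. Ties among
  equal-length longest blocks are broken toward the smallest position in
  the first, then the second string; the recursion is therefore
  order-dependent in rare tie constellations (the reference
  implementation shares this asymmetry, and the test suite pins our
  implementation to it in both argument orders). Two empty strings score
  1 by convention.
* **Set Tanimoto** `|A∩B|/|A∪B|`, with the both-empty convention 1.
  Applied to path-fingerprint bit sets (structural similarity),
  scaffold-fingerprint bit sets, and distinct-token sets (shared-token
  ratio). Token multiplicities are deliberately ignored; the multiset
  variant was considered and not adopted because the panel is meant to
  measure vocabulary overlap, not length effects, which the length ratio
  captures separately.
* **Fingerprints** are OpenBabel FP2: hashed linear paths of one to
  seven atoms, 1,024 bits. Any backend substitution must either match
  these parameters or be declared, since absolute Tanimoto values are
  parameter-dependent.
* **Murcko scaffolds**: the 2-core of the molecular graph (ring systems
  plus linkers) with atoms attached to that framework by a double or
  triple bond retained (exocyclic carbonyls and the like), side chains
  removed, and the result re-canonicalized. Acyclic molecules have the
  empty scaffold; two acyclic molecules score scaffold similarity 1
  (both reduce to the same nothing), one acyclic versus one cyclic
  scores 0.
* **Token length ratio** `min(len)/max(len)`: symmetric by
  construction and in (0, 1]; the undirected form is used because the
  panels aggregate over unordered pairs.
* **t-test**: classical two-sided independent two-sample test, pooled
  variance by default with a Welch switch, delegated to `stats::t.test`.
  Significance stars use strict thresholds (`*` p < 0.05, `**` p < 0.01,
  `***` p < 0.001, `****` p < 0.0001). Degenerate zero-variance inputs
  follow the stated convention: equal means give t = 0, p = 1 ("ns").

## Patent functional labeling

The pipeline that turns patent text into functional labels is
implemented as pure prompt assembly, response parsing and aggregation,
with both network-facing dependencies injected: a resolver (patent id to
title/abstract/description) and an LLM (system + user prompt to text).
Canned transcripts keyed by a prompt hash replay either faithful,
deliberately malformed, or label-free responses, so the full pipeline is
testable offline and malformed model output can never crash a run —
syntax violations are flagged (`parse_ok = FALSE`) and retained for
audit rather than retried, since retry policy belongs to the backend.
Descriptions are truncated to 3,500 characters and at most 10 patents
are sampled per molecule (seeded, uniform without replacement); both are
configuration values. Labels are lowercased, trimmed and unioned per
molecule — set union was chosen for aggregation because descriptor
multiplicity across patents carries no meaning for the downstream
similarity verdict; provenance keeps the per-patent originals.

## Synthetic data

`make_smiles_db` emits a stream of substituted ring systems (eight core
templates, random linear side chains) with controlled violations: exact
or re-rooted duplicates of earlier records, `.`-joined salt-like
records, and over-length records built as long explicit double-bond
chains (`C=C` repeated), the construction that realistically produces
token counts beyond an encoder's limit. The three violation groups are
disjoint, and the first stream position is always a clean record so
every duplicate has an earlier source; the expected surviving count is
therefore exact, and the generator's manifest is asserted against the
build report in tests. The generator emulates the bookkeeping structure
of a real corpus, not drug-like chemical space: passing tests
demonstrate correct cascade arithmetic and search behavior, not
pharmacological realism.

Problem sizes used by the test suite and the acceptance script are
desk-scale by design: the exact-search oracle runs on a 10,000-row
store, the cascade fixture on 100–1,200 records, result profiles on
top-25/50 of a few-hundred-row store. These sizes exercise every code
path (including multi-chunk streaming) while keeping runs reproducible
on a laptop; the store and search layers scale by chunking, not by
algorithmic change.

## Known limitations

* The mock embedder's feature space has no chemical meaning; per-scheme
  result-profile values under it are illustrative of the mechanics, not
  of any real model's behavior.
* Canonical forms, rooted writings and fingerprints are
  OpenBabel-relative; other toolkits produce different strings and
  different absolute Tanimoto values, though all invariants
  (idempotency, graph invariance, metric axioms) are toolkit-agnostic.
* Gestalt similarity is order-dependent in rare tie cases, as inherent
  to the recursive decomposition.
* The external scheme ingests third-party canonical forms; it does not
  reimplement a second canonicalization algorithm.
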