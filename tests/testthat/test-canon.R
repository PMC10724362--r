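test_that("standardization strips stereochemistry and is idempotent", {
  rec <- standardize("C[C@H](N)C(=O)O")
  expect_false(grepl("[@/\\\\]", rec$std_smiles))
  # oracle: canonicalizing the manually destereoized graph gives the same form
  expect_identical(rec$std_smiles, standardize("CC(N)C(=O)O")$std_smiles)
  # idempotency over the whole fixture pool
  for (smi in fixture_smiles()) {
    std <- standardize(smi)$std_smiles
    expect_identical(standardize(std)$std_smiles, std)
    expect_false(grepl("[@/\\\\]", std))
  }
})

test_that("single-atom and unparseable inputs are handled", {
  rec <- standardize("C")
  expect_identical(rec$std_smiles, "C")
  expect_identical(rec$n_atoms, 1L)
  expect_error(standardize("not_a_smiles"), "unparseable")
})

test_that("heavy-atom counts match the parsed structure", {
  smis <- fixture_smiles()
  recs <- lapply(smis, standardize)
  counted <- vapply(recs, function(r) r$n_atoms, integer(1))
  # oracle: count non-hydrogen atoms in the parsed SDF atom block
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(
      vapply(recs, function(r) r$std_smiles, character(1)),
      paste0("m", seq_along(recs))))
  )
  parsed <- vapply(seq_along(smis), function(i) {
    el <- sub("_[0-9]+$", "", rownames(ChemmineR::atomblock(sdf[[i]])))
    sum(el != "H")
  }, integer(1))
  expect_equal(unname(counted), parsed)
})

test_that("rooted enumeration yields one graph-equivalent variant per atom", {
  expect_length(enumerate_rooted(standardize("C")), 1L)
  eth <- enumerate_rooted(standardize("CCO"))
  expect_length(eth, 3L)
  expect_identical(eth[[1]]$smiles, standardize("CCO")$std_smiles)
  expect_identical(eth[[1]]$scheme, "default_root")
  expect_identical(eth[[1]]$root_atom, 0L)

  for (smi in fixture_smiles()[c("zidovudine", "toluene", "piperidone")]) {
    rec <- standardize(smi)
    vars <- enumerate_rooted(rec)
    expect_length(vars, rec$n_atoms)
    expect_identical(vapply(vars, function(v) v$root_atom, integer(1)),
                     seq(0L, rec$n_atoms - 1L))
    recanon <- vapply(vars, function(v) standardize(v$smiles)$std_smiles,
                      character(1))
    expect_true(all(recanon == rec$std_smiles))
    # deterministic
    vars2 <- enumerate_rooted(rec)
    expect_identical(vapply(vars2, function(v) v$smiles, character(1)),
                     vapply(vars, function(v) v$smiles, character(1)))
  }
})

test_that("max-distance selection is an exact argmin over rootings", {
  # prescribed cosines: variant with cosine 0.2 must win
  vecs <- list(a = c(1, 0), b = c(0.9, sqrt(1 - 0.81)), c = c(0.2, sqrt(1 - 0.04)))
  emb <- lookup_embedder(vecs)
  vars <- list(canonical_variant_for_test("a", "default_root", 0L),
               canonical_variant_for_test("b", "alt_root", 1L),
               canonical_variant_for_test("c", "alt_root", 2L))
  sel <- select_max_distance_variant(vars, emb)
  expect_identical(sel$smiles, "c")
  expect_equal(sel$distance_to_default, 0.2, tolerance = 1e-12)

  # single variant: self-similarity 1
  sel1 <- select_max_distance_variant(vars[1], emb)
  expect_identical(sel1$smiles, "a")
  expect_equal(sel1$distance_to_default, 1.0, tolerance = 1e-12)

  # exhaustive oracle on real molecules under the mock embedder
  embm <- test_embedder()
  for (smi in fixture_smiles()[c("zidovudine", "ibuprofen", "piperidone")]) {
    rec <- standardize(smi)
    vars <- enumerate_rooted(rec)
    sel <- select_max_distance_variant(vars, embm)
    smis <- vapply(vars, function(v) v$smiles, character(1))
    mats <- embed_smiles(embm, smis)
    cosines <- as.numeric(mats %*% mats[1, ])
    best <- min(cosines)
    oracle_idx <- which(cosines <= best + 1e-12)[1]  # lowest root on ties
    expect_identical(sel$smiles, smis[oracle_idx])
    expect_equal(sel$distance_to_default, cosines[oracle_idx],
                 tolerance = 1e-12)
    expect_identical(sel$scheme, "alt_root")
    # determinism under a fresh embedder with the same seed
    sel2 <- select_max_distance_variant(vars, test_embedder())
    expect_identical(sel2$smiles, sel$smiles)
  }
})

test_that("external canonical forms are validated by connectivity", {
  zv <- zidovudine_trio()
  rec <- standardize(zv[1])
  ext <- attach_external(rec, zv[3])
  expect_identical(ext$scheme, "external")
  expect_identical(ext$smiles, zv[3])  # stored verbatim, no re-canonicalization
  expect_true(is.na(ext$root_atom))
  expect_error(attach_external(rec, "CCO"), "connectivity")
  same <- attach_external(rec, rec$std_smiles)
  expect_identical(same$smiles, rec$std_smiles)
})

test_that("the three query representations of one molecule stay on one graph", {
  emb <- test_embedder()
  zv <- zidovudine_trio()
  rec <- standardize(zv[1])
  v <- query_variants(rec, emb, external_smiles = zv[3])
  expect_named(v, c("default_root", "alt_root", "external"))
  stds <- vapply(v, function(x) standardize(x$smiles)$std_smiles, character(1))
  expect_true(all(stds == rec$std_smiles))
  tab <- variants_table(rec, v)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$std_smiles == rec$std_smiles))
})

test_that("smiles input files are read in both accepted layouts", {
  plain <- tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1"), plain)
  df <- read_smiles_input(plain)
  expect_identical(df$smiles, c("CCO", "c1ccccc1"))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(smiles = "CCO", external_smiles = "OCC"),
                   csv, row.names = FALSE)
  df2 <- read_smiles_input(csv)
  expect_identical(df2$external_smiles, "OCC")
})

test_that("the Kekule writer produces an equivalent alternative writing", {
  for (smi in c("Cc1ccccc1O", "c1ccc2ccccc2c1")) {
    kek <- kekule_smiles(smi)
    expect_false(identical(kek, standardize(smi)$std_smiles))
    expect_identical(standardize(kek)$std_smiles, standardize(smi)$std_smiles)
  }
})
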