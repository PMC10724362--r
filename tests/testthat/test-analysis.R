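test_that("divergence panel reports three pairs per query with exact means", {
  emb <- test_embedder()
  # a molecule whose three representations are the same string: everything 1
  pan1 <- divergence_panel(
    variant_table = data.frame(query = "C", default_smiles = "C",
                               alt_smiles = "C", external_smiles = "C"),
    embedder = emb)
  expect_identical(nrow(pan1$pairs), 3L)
  expect_equal(unname(pan1$means), rep(1, 4), tolerance = 1e-9)

  # published trio: means equal direct recomputation outside the panel code
  zv <- zidovudine_trio()
  pan <- divergence_panel(
    variant_table = data.frame(query = "zidovudine",
                               default_smiles = zv[1], alt_smiles = zv[2],
                               external_smiles = zv[3]),
    embedder = emb)
  pairs <- list(c(zv[1], zv[2]), c(zv[1], zv[3]), c(zv[2], zv[3]))
  direct_string <- mean(vapply(pairs, function(p) {
    gestalt_similarity(p[1], p[2])
  }, numeric(1)))
  expect_equal(unname(pan$means["string_similarity"]), direct_string,
               tolerance = 1e-12)
  direct_feature <- mean(vapply(pairs, function(p) {
    m <- embed_smiles(emb, p)
    cosine_similarity(m[1, ], m[2, ])
  }, numeric(1)))
  expect_equal(unname(pan$means["feature_similarity"]), direct_feature,
               tolerance = 1e-12)

  # end-to-end construction from molecules
  pan2 <- divergence_panel(queries = list("Cc1ccccc1O"), embedder = emb,
                           external_smiles = kekule_smiles("Cc1ccccc1O"))
  expect_identical(nrow(pan2$pairs), 3L)
  expect_true(all(pan2$pairs$string_similarity <= 1))
})

test_that("result profiles join search hits with per-row metrics", {
  emb <- test_embedder()
  fam <- make_scaffold_family("c1ccc(%s)cc1", 40L, seed = 23L)
  built <- build_store(fam, emb, chunk_size = 15L)
  rec <- standardize(fam[5])
  prof <- result_profile(query_variants(rec, emb)$default_root, built$store,
                         k = 10L, embedder = emb)
  expect_identical(nrow(prof$rows), 10L)
  expect_identical(prof$rows$smiles[1], rec$std_smiles)
  # means equal independent per-row recomputation
  expect_equal(unname(prof$means["structural"]),
               mean(vapply(prof$rows$smiles, function(s) {
                 structural_similarity(rec, s)
               }, numeric(1))), tolerance = 1e-12)
  # k larger than the store: profile over all rows, with warning
  expect_warning(prof_all <- result_profile(rec$std_smiles, built$store,
                                            k = 10000L, embedder = emb),
                 "exceeds store size")
  expect_identical(nrow(prof_all$rows), store_nrow(built$store))
})

test_that("cutoff fractions count the structurally recoverable results", {
  fake <- structure(list(rows = data.frame(structural = c(rep(0.9, 55),
                                                          rep(0.5, 195)))),
                    class = "result_profile")
  expect_equal(cutoff_fraction(fake, 0.8), 55 / 250, tolerance = 1e-12)
  all_hi <- structure(list(rows = data.frame(structural = rep(1, 10))),
                      class = "result_profile")
  expect_equal(cutoff_fraction(all_hi, 0.8), 1.0)
  expect_equal(cutoff_fraction(fake, 0.95), 0.0)
  # monotone non-increasing in the cutoff
  cuts <- seq(0, 1, by = 0.1)
  fr <- vapply(cuts, function(ct) cutoff_fraction(fake, ct), numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("rank comparison matches a brute-force double sort", {
  emb <- test_embedder()
  fam <- c(make_scaffold_family("c1ccc(%s)cc1", 30L, seed = 41L),
           make_scaffold_family("C1CCC(%s)CC1", 30L, seed = 42L))
  built <- build_store(fam, emb, chunk_size = 20L)
  store <- built$store
  rec <- standardize(fam[2])
  rc <- rank_comparison(query_variants(rec, emb)$default_root, store,
                        k = 15L, embedder = emb)
  expect_identical(nrow(rc), 15L)
  # the self-match tops both rankings
  expect_true(any(rc$chess_rank == 1L & rc$tanimoto_rank == 1L))
  expect_identical(rc$chess_rank, 1:15)
  expect_true(all(rc$tanimoto_rank >= 1L &
                    rc$tanimoto_rank <= store_nrow(store)))
  # oracle: independent full sorts of both scores
  smis <- store_smiles(store)
  cos <- as.numeric(store_matrix(store) %*%
                      embed_smiles(emb, rec$std_smiles)[1, ])
  chess_ord <- order(-cos, seq_along(cos))
  qb <- fingerprint_bits(rec$std_smiles)[[1]]
  tani <- vapply(fingerprint_bits(smis), function(b) set_tanimoto(qb, b),
                 numeric(1))
  tani_rank_of <- match(seq_along(smis), order(-tani, seq_along(tani)))
  for (j in 1:15) {
    idx <- chess_ord[j]
    expect_identical(rc$smiles[j], smis[idx])
    expect_identical(rc$tanimoto_rank[j], tani_rank_of[idx])
  }
  # k = 1 degenerates to the single top pair
  rc1 <- rank_comparison(rec$std_smiles, store, k = 1L, embedder = emb)
  expect_identical(nrow(rc1), 1L)
})

test_that("the independent t-test matches the closed pooled form and stars", {
  a <- c(0, 1); b <- c(2, 3)
  res <- independent_ttest(a, b)
  # closed form: pooled s^2 = 0.5, t = (0.5 - 2.5) / sqrt(0.5 * (1/2 + 1/2))
  t_hand <- (mean(a) - mean(b)) / sqrt(0.5 * (1 / 2 + 1 / 2))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), df = 2), tolerance = 1e-12)

  same <- independent_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_identical(same$stars, "ns")

  shifted <- independent_ttest(c(0, 0, 0, 0) + rnorm(4, sd = 1e-9),
                               c(1, 1, 1, 1) + rnorm(4, sd = 1e-9))
  expect_lt(shifted$p, 1e-4)
  expect_identical(shifted$stars, "****")

  flat <- independent_ttest(c(2, 2), c(2, 2))
  expect_identical(flat$p, 1)
  expect_identical(flat$stars, "ns")

  # star thresholds are strict as printed
  expect_identical(significance_stars(0.04), "*")
  expect_identical(significance_stars(0.004), "**")
  expect_identical(significance_stars(0.05), "ns")
  expect_identical(significance_stars(0.0004), "***")
  expect_identical(significance_stars(0.00004), "****")

  # Welch switch delegates to the Welch statistic
  w <- independent_ttest(c(1, 2, 3, 9), c(2, 2.5, 3, 3.5), var_equal = FALSE)
  ref <- stats::t.test(c(1, 2, 3, 9), c(2, 2.5, 3, 3.5))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
})
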