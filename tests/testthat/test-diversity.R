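test_that("tanimoto matches set arithmetic", {
  a <- integer(16); a[c(1, 5, 9)] <- 1L
  b <- integer(16); b[c(5, 9, 12)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)  # |{5,9}| / |{1,5,9,12}|
  expect_equal(tanimoto(a, a), 1.0)
  d <- integer(16); d[c(2, 3)] <- 1L
  expect_equal(tanimoto(a, d), 0.0)
  expect_equal(tanimoto(integer(8), integer(8)), 0.0)  # 0/0 convention
  expect_error(tanimoto(a, integer(8)), "length")
})

test_that("tanimoto agrees with an independent oracle on random bit vectors", {
  set.seed(31)
  for (i in 1:50) {
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("pairwise similarity is symmetric, unit-diagonal and brute-force exact", {
  cs <- fixture_set(6)
  s <- pairwise_similarity(cs, kind = "morgan")
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 6))
  expect_true(all(s >= 0 & s <= 1))
  fp <- morgan_fingerprint(cs$smiles)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(unname(s[i, j]), tanimoto(fp[i, ], fp[j, ]))
  }
  expect_equal(colnames(s), cs$id)
})

test_that("mean pairwise similarity averages each unordered pair once", {
  twin <- compound_set(c("CCO", "OCC"))
  expect_equal(mean_pairwise_similarity(pairwise_similarity(twin)), 1.0)
  cs <- fixture_set(5)
  s <- pairwise_similarity(cs)
  acc <- 0
  for (i in 1:4) for (j in (i + 1):5) acc <- acc + s[i, j]
  expect_equal(mean_pairwise_similarity(s), acc / 10)
  one <- compound_set("CCO")
  expect_error(mean_pairwise_similarity(pairwise_similarity(one)), "pair")
})

test_that("maxmin selection is deterministic, duplicate-free and clamps n", {
  lib <- small_planted_library()
  pool <- subset_compounds(lib, 1:20)
  s1 <- maxmin_select(pool, 8, seed = 3)
  s2 <- maxmin_select(pool, 8, seed = 3)
  expect_identical(s1$selected_ids, s2$selected_ids)
  expect_equal(length(unique(s1$selected_ids)), 8L)
  all_sel <- maxmin_select(pool, 20, seed = 1)
  expect_setequal(all_sel$selected_ids, pool$id)
  expect_warning(clamped <- maxmin_select(pool, 50, seed = 1), "pool size")
  expect_equal(length(clamped$selected_ids), 20L)
})

test_that("maxmin beats random subsets on minimum pairwise distance", {
  lib <- small_planted_library()
  pool <- subset_compounds(lib, 1:24)
  d <- 1 - pairwise_similarity(pool)
  sel <- maxmin_select(pool, 6, seed = 5)
  sel_idx <- match(sel$selected_ids, pool$id)
  mm <- min_pairwise_dist(unname(d), sel_idx)
  set.seed(17)
  rand <- replicate(30, min_pairwise_dist(unname(d), sample(24, 6)))
  expect_gte(mm, mean(rand))
})

test_that("balance_dataset selects per class and validates sizes", {
  lib <- small_planted_library()
  pos <- subset_compounds(lib, which(lib$label == 1))
  neg <- subset_compounds(lib, which(lib$label == 0))
  bal <- balance_dataset(pos, neg, n_per_class = 15L, seed = 2)
  expect_equal(nrow(bal$pos$selected), 15L)
  expect_equal(nrow(bal$neg$selected), 15L)
  expect_true(all(bal$pos$selected$label == 1L))
  expect_true(all(bal$neg$selected$label == 0L))
  expect_error(balance_dataset(pos, neg, n_per_class = 1000L), "smaller")
})
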