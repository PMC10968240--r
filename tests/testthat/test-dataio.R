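test_that("SMILES files read into compound sets with canonical forms", {
  path <- write_smi_fixture(c("CCO\teth", "c1ccccc1", "# comment", "",
                              "CC(=O)O\tacid"))
  cs <- read_smiles_file(path)
  expect_s3_class(cs, "compound_set")
  expect_equal(nrow(cs), 3L)
  expect_equal(cs$id, c("eth", "row2", "acid"))
  expect_equal(cs$smiles, c("CCO", "c1ccccc1", "CC(=O)O"))
  expect_equal(cs$canonical_smiles, canonicalize(cs$smiles))
  expect_true(all(is.na(cs$label)))

  labeled <- read_smiles_file(path, label = 1L)
  expect_true(all(labeled$label == 1L))
})

test_that("empty files give empty sets without error", {
  path <- write_smi_fixture(character(0))
  cs <- read_smiles_file(path)
  expect_equal(nrow(cs), 0L)
})

test_that("invalid SMILES error in strict mode and are skipped when lenient", {
  path <- write_smi_fixture(c("CCO", "CCC", "C1CC", "CCN", "CCCl"))
  expect_error(read_smiles_file(path), "line 3")
  expect_warning(cs <- read_smiles_file(path, strict = FALSE), "1 unparseable")
  expect_equal(nrow(cs), 4L)
  expect_false("C1CC" %in% cs$smiles)
})

test_that("canonicalization is idempotent and spelling-independent", {
  can <- canonicalize("OCC")
  expect_equal(canonicalize(can), can)
  expect_equal(canonicalize("CCO"), canonicalize("OCC"))
  expect_equal(canonicalize("C(O)C"), can)
  expect_error(canonicalize("C1CC"), "C1CC")
})

test_that("read -> write -> read is the identity on compound sets", {
  cs <- fixture_set()
  path <- tempfile(fileext = ".smi")
  write_smiles_file(cs, path)
  back <- read_smiles_file(path)
  expect_equal(back$id, cs$id)
  expect_equal(back$smiles, cs$smiles)
  expect_equal(back$canonical_smiles, cs$canonical_smiles)
})

test_that("duplicate ids and bad labels are rejected", {
  expect_error(compound_set(c("C", "CC"), id = c("a", "a")), "duplicate")
  expect_error(compound_set("C", label = 2), "binary")
})

test_that("score tables are written sorted and round-trip to 6 decimals", {
  cs <- fixture_set(4)
  res <- rank_library(c(0.2, 0.9, 0.123456789, 0.5), cs)
  path <- tempfile(fileext = ".csv")
  write_score_table(res, path)
  back <- read_score_table(path)
  expect_equal(back$score, sort(c(0.2, 0.9, 0.123456789, 0.5), decreasing = TRUE),
               tolerance = 1e-9)
  expect_equal(back$id[1], cs$id[2])  # highest score first

  empty <- rank_library(numeric(0), compound_set(character(0)))
  path2 <- tempfile(fileext = ".csv")
  write_score_table(empty, path2)
  expect_equal(nrow(read_score_table(path2)), 0L)
  expect_equal(readLines(path2)[1], "id,smiles,score,active")
})
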