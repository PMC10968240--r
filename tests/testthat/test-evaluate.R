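test_that("confusion counts use a strict threshold and partition the items", {
  scores <- c(rep(1, 50), rep(0, 50))
  labels <- c(rep(1, 50), rep(0, 50))
  cc <- confusion_counts(scores, labels)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 50L, TN = 50L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  # exactly at the threshold counts as inactive
  cc2 <- confusion_counts(c(0.5, 0.500001), c(1, 1))
  expect_equal(cc2$FN, 1)
  expect_equal(cc2$TP, 1)
  expect_error(confusion_counts(c(0.1), c(1, 0)), "length")
})

test_that("confusion counts match a per-item brute-force tally", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    cc <- confusion_counts(scores, labels)
    oc <- oracle_confusion(scores, labels)
    expect_equal(unclass(cc)[names(oc)], oc, ignore_attr = TRUE)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, n)
  }
})

test_that("metric formulas match hand computation and the direct MCC formula", {
  m <- classification_metrics(
    structure(list(TP = 40, FP = 10, FN = 5, TN = 45), class = "confusion_counts"))
  expect_equal(m$acc, 0.85)
  expect_equal(m$pre, 0.80)
  expect_equal(m$recall, 40 / 45)
  expect_equal(m$f_value, 80 / 95)
  mcc_direct <- (40 * 45 - 5 * 10) /
    sqrt((40 + 5) * (45 + 10) * (40 + 10) * (45 + 5))
  expect_equal(m$mcc, mcc_direct)

  perfect <- classification_metrics(
    structure(list(TP = 50, FP = 0, FN = 0, TN = 50), class = "confusion_counts"))
  expect_equal(unlist(perfect),
               c(acc = 1, pre = 1, recall = 1, f_value = 1, mcc = 1))
})

test_that("zero-denominator metrics flag as degenerate instead of failing", {
  m <- classification_metrics(
    structure(list(TP = 0, FP = 0, FN = 0, TN = 20), class = "confusion_counts"))
  expect_equal(m$acc, 1)
  expect_equal(m$pre, 0)
  expect_equal(m$mcc, 0)
  expect_true(all(c("pre", "mcc") %in% attr(m, "degenerate")))
})

test_that("metric ranges hold on random confusion tables", {
  set.seed(77)
  for (i in 1:100) {
    cc <- structure(as.list(setNames(rpois(4, 8), c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
    if (cc$TP + cc$FP + cc$FN + cc$TN == 0) next
    m <- classification_metrics(cc)
    expect_true(all(unlist(m[c("acc", "pre", "recall", "f_value")]) >= 0))
    expect_true(all(unlist(m[c("acc", "pre", "recall", "f_value")]) <= 1))
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
  }
})

test_that("AUROC matches the pair-counting oracle including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(13)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auroc(scores, labels),
                 oracle_auroc_paircount(scores, labels))
  }
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(21)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  base <- auroc(scores, labels)
  expect_equal(auroc(plogis(5 * scores - 2), labels), base)
  expect_equal(auroc(scores^3, labels), base)
})

test_that("AUROC agrees with pROC on random fixtures", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    scores <- runif(40)
    labels <- c(0, 1, rbinom(38, 1, 0.5))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref)
  }
})

test_that("label-permutation null AUROC concentrates near one half", {
  set.seed(37)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.5)
  nulls <- replicate(200, auroc(scores, sample(labels)))
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
})

test_that("AUPRC follows the average-precision convention", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # hand computation: ranks 1,3 are positive -> AP = (1/1 + 2/3) / 2
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)), (1 + 2 / 3) / 2)
  pr <- auprc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0), curve = TRUE)
  expect_true(all(diff(pr$points$recall) >= 0))
})

test_that("evaluating replicate ensembles averages scores before metrics", {
  lib <- small_planted_library()
  tiny <- subset_compounds(lib, c(1:12, 26:45))
  cfg <- train_config(epochs = 2L, replicates = 1L, batch_size = 16L, seed = 6)
  m1 <- activity_model(tiny, arch = "dnn", config = cfg)
  r1 <- evaluate_model(m1, tiny)
  expect_s3_class(r1, "metric_report")
  # a 3-ensemble of identical replicates scores identically to one
  m3 <- m1
  m3$nets <- rep(m1$nets, 3)
  r3 <- evaluate_model(m3, tiny)
  expect_equal(r3$auroc, r1$auroc)
  expect_equal(r3$acc, r1$acc)
  # report serialization round-trips the scalars
  path <- tempfile(fileext = ".json")
  write_metric_report(r1, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$auroc, r1$auroc, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.json$", "_roc.csv", path)))
})
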