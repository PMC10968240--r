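test_that("splits follow the floor convention and are deterministic", {
  sp <- split_dataset(1000, 0.8, seed = 1)
  expect_length(sp$train, 800L)
  expect_length(sp$test, 200L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:1000)

  sp2 <- split_dataset(781, 0.8, seed = 1)
  expect_length(sp2$train, 624L)  # floor(0.8 * 781)
  expect_length(sp2$test, 157L)

  expect_identical(split_dataset(100, 0.8, seed = 9),
                   split_dataset(100, 0.8, seed = 9))
})

test_that("stratified splits preserve the class ratio within one item", {
  labels <- rep(c(0L, 1L), c(350L, 150L))
  sp <- split_dataset(labels = labels, fraction = 0.8, seed = 3)
  expect_length(sp$train, 400L)
  expect_equal(sum(labels[sp$train] == 1L), 120L, tolerance = 1)
  expect_equal(sum(labels[sp$test] == 1L), 30L, tolerance = 1)
  # degenerate: a class with a single member cannot appear in both parts
  expect_error(split_dataset(labels = c(0L, rep(1L, 9)), fraction = 0.8,
                             seed = 1), "degenerate")
})

test_that("architectures have the published layer widths", {
  ns <- asNamespace("mkscreen")
  cnn <- ns$nn_init("cnn", embed_dim = 32L)
  expect_equal(dim(cnn$params$E), c(2L, 32L))
  expect_equal(dim(cnn$params$Wc), c(16L * 32L, 330L))   # window 16, 330 filters
  expect_equal(dim(cnn$params$W1), c(330L, 128L))        # dense 128 after pooling
  expect_equal(dim(cnn$params$Wo), c(128L, 1L))
  dnn <- ns$nn_init("dnn")
  expect_equal(dim(dnn$params$W1), c(2048L, 2048L))
  expect_equal(dim(dnn$params$W2), c(2048L, 64L))
  expect_equal(dim(dnn$params$W3), c(64L, 16L))
  expect_equal(dim(dnn$params$Wo), c(16L, 1L))
  hcd <- ns$nn_init("hcd")
  expect_equal(dim(hcd$params$Wo), c(144L, 1L))          # fused 128 + 16
  # convolution over 167 positions with window 16 gives 152 outputs
  A <- matrix(0, 2 * 167, 8)
  cf <- ns$conv_pool_forward(A, 2L, matrix(0, 16 * 8, 330), numeric(330))
  expect_equal(dim(cf$Z), c(2L * 152L, 330L))
})

test_that("untrained and trained models score in [0, 1] and check input width", {
  lib <- small_planted_library()
  tiny <- subset_compounds(lib, c(1:10, 26:40))
  cfg <- train_config(epochs = 0L, replicates = 1L, seed = 5)
  m <- activity_model(tiny, arch = "cnn", config = cfg)
  sc <- predict(m, tiny)
  expect_length(sc, nrow(tiny))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predict(m, list(maccs = matrix(0, 2, 100))), "167")
  md <- activity_model(tiny, arch = "dnn", config = cfg)
  expect_error(predict(md, list(morgan = matrix(0, 2, 100))), "2048")
})

test_that("zero-epoch training leaves predictions at initialization", {
  lib <- small_planted_library()
  tiny <- subset_compounds(lib, c(1:10, 26:40))
  cfg0 <- train_config(epochs = 0L, replicates = 1L, seed = 5)
  m0a <- activity_model(tiny, arch = "dnn", config = cfg0)
  m0b <- activity_model(tiny, arch = "dnn", config = cfg0)
  expect_equal(predict(m0a, tiny), predict(m0b, tiny))
})

test_that("training reduces the loss and is reproducible under a seed", {
  lib <- small_planted_library()
  idx <- c(1:20, 26:65)
  tiny <- subset_compounds(lib, idx)
  cfg <- train_config(epochs = 5L, replicates = 1L, batch_size = 16L, seed = 8)
  m1 <- activity_model(tiny, arch = "dnn", config = cfg)
  expect_lt(m1$history[5, 1], m1$history[1, 1])
  m2 <- activity_model(tiny, arch = "dnn", config = cfg)
  expect_identical(m1$history, m2$history)
})

test_that("single-class or unlabeled training data is rejected", {
  pos_only <- fixture_set(4, label = 1)
  cfg <- train_config(epochs = 2L, replicates = 1L)
  expect_error(activity_model(pos_only, arch = "dnn", config = cfg),
               "single class")
  expect_error(activity_model(fixture_set(4), arch = "dnn", config = cfg),
               "labeled")
})

test_that("replicates have distinct seeds and average arithmetically", {
  lib <- small_planted_library()
  tiny <- subset_compounds(lib, c(1:12, 26:45))
  cfg <- train_config(epochs = 2L, replicates = 3L, batch_size = 16L, seed = 4)
  m <- activity_model(tiny, arch = "dnn", config = cfg)
  expect_length(m$nets, 3L)
  # distinct replicate weights
  expect_false(identical(m$nets[[1]]$params$W3, m$nets[[2]]$params$W3))
  per_rep <- predict(m, tiny, per_replicate = TRUE)
  expect_equal(dim(per_rep), c(nrow(tiny), 3L))
  expect_equal(predict(m, tiny), rowMeans(per_rep))
})
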