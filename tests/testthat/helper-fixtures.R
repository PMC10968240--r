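# Shared fixtures, built in code. Kept deliberately small; anything heavy
# (trained models, generated libraries) is created inside the test that
# needs it and reuses the package's per-session fingerprint cache.

# A handful of drug-like SMILES with diverse chemistry.
fixture_smiles <- function() {
  c(
    aspirin  = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ethanol  = "CCO",
    phenol   = "Oc1ccccc1",
    naphthyl = "c1ccc2ccccc2c1CCN",
    amide    = "CCC(=O)NC1CCCCC1"
  )
}

fixture_set <- function(n = 6, label = NULL) {
  smi <- fixture_smiles()[seq_len(n)]
  compound_set(unname(smi), id = names(smi),
               label = if (is.null(label)) NULL else rep(label, n))
}

# Write a SMILES file fixture and return its path.
write_smi_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile(fileext = ".smi", tmpdir = dir)
  writeLines(lines, path)
  path
}

# Small planted-motif library shared across tests (memoized per session).
.small_lib_memo <- new.env(parent = emptyenv())
small_planted_library <- function() {
  if (is.null(.small_lib_memo$lib)) {
    .small_lib_memo$lib <- generate_library(n_pos = 25L, n_neg = 50L, seed = 101L)
  }
  .small_lib_memo$lib
}

subset_compounds <- function(x, idx) {
  out <- x[idx, , drop = FALSE]
  attr(out, "name") <- attr(x, "name")
  class(out) <- c("compound_set", "data.frame")
  out
}

# Independent brute-force oracles (kept free of package internals).

oracle_confusion <- function(scores, labels, thr = 0.5) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] > thr
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracle_auroc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_tanimoto <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  un <- length(union(ia, ib))
  if (un == 0) 0 else length(intersect(ia, ib)) / un
}

# Exhaustive MaxMin oracle: best achievable minimum pairwise distance over
# all size-n subsets of the pool (distance = 1 - Tanimoto).
oracle_best_min_dist <- function(dist_mat, n) {
  idx <- utils::combn(nrow(dist_mat), n)
  best <- -Inf
  for (j in seq_len(ncol(idx))) {
    sub <- dist_mat[idx[, j], idx[, j]]
    best <- max(best, min(sub[upper.tri(sub)]))
  }
  best
}

min_pairwise_dist <- function(dist_mat, sel) {
  sub <- dist_mat[sel, sel]
  min(sub[upper.tri(sub)])
}
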