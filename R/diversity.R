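# Tanimoto similarity and MaxMin diversity selection. These balance the
# augmented positive pool against the negative pool: pick the n most
# mutually dissimilar molecules within each class so that redundancy
# introduced by augmentation (or present in the source data) is removed.

#' Tanimoto coefficient between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, the set-overlap similarity of the on-bit sets.
#' Two all-zero vectors have no defined overlap; that 0/0 case is defined
#' as 0 here.
#'
#' @param a,b Binary vectors of equal length (same fingerprint kind).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix of a compound set
#'
#' @param compounds A [compound_set()] (>= 1 molecule).
#' @param kind Fingerprint kind, default `"morgan"`.
#' @return Symmetric matrix in `[0,1]` with unit diagonal; row/col names are
#'   compound ids.
#' @export
pairwise_similarity <- function(compounds, kind = "morgan") {
  fp <- featurize_set(compounds, kind = kind)
  tanimoto_matrix(fp, ids = compounds$id)
}

# Cross-product form: intersections = X X^T, unions = |a| + |b| - inter.
tanimoto_matrix <- function(fp, ids = NULL) {
  x <- matrix(as.numeric(fp), nrow = nrow(fp))
  inter <- tcrossprod(x)
  cnt <- rowSums(x)
  un <- outer(cnt, cnt, "+") - inter
  s <- ifelse(un == 0, 0, inter / un)
  diag(s) <- 1  # unit diagonal by convention (incl. empty fingerprints)
  if (!is.null(ids)) dimnames(s) <- list(ids, ids)
  s
}

#' Mean off-diagonal Tanimoto similarity
#'
#' Mean over each unordered pair once; the redundancy diagnostic reported
#' before and after diversity selection.
#'
#' @param m A similarity matrix from [pairwise_similarity()].
#' @return Mean pairwise similarity in `[0, 1]`.
#' @export
mean_pairwise_similarity <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 compounds to form a pair")
  mean(m[upper.tri(m)])
}

#' MaxMin diversity selection
#'
#' Greedy diversity picking on distance `d = 1 - Tanimoto`: the first pick is
#' uniform-random under `seed`; each subsequent pick maximizes its minimum
#' distance to everything already picked (ties broken by lowest input index).
#' Deterministic under a fixed seed.
#'
#' @param pool A [compound_set()].
#' @param n Number of molecules to select; clamped to the pool size with a
#'   warning if larger.
#' @param kind Fingerprint kind used for the distances, default `"morgan"`.
#' @param seed Integer seed for the initial pick.
#' @return List with `selected_ids` (ordered as picked), `selected` (the
#'   sub-[compound_set()]), `n_requested`, `seed`,
#'   `mean_similarity_before`/`_after` (NA when a side has < 2 molecules).
#' @export
maxmin_select <- function(pool, n, kind = "morgan", seed = 1L) {
  stopifnot(inherits(pool, "compound_set"), n >= 1L)
  np <- nrow(pool)
  if (np == 0L) stop("empty pool")
  if (n > np) {
    warning("requested ", n, " > pool size ", np, "; returning the full pool")
    n <- np
  }
  fp <- featurize_set(pool, kind = kind)
  s <- tanimoto_matrix(fp)
  d <- 1 - s
  first <- with_rng(local_rng(seed), sample.int(np, 1L))
  picked <- integer(n)
  picked[1L] <- first
  if (n > 1L) {
    mind <- d[, first]
    for (t in 2:n) {
      mind[picked[seq_len(t - 1L)]] <- -1  # never repick
      best <- which.max(mind)              # ties -> lowest index
      picked[t] <- best
      mind <- pmin(mind, d[, best])
    }
  }
  sel <- pool[picked, , drop = FALSE]
  attr(sel, "name") <- paste0(attr(pool, "name"), "_maxmin", n)
  class(sel) <- c("compound_set", "data.frame")
  before <- if (np >= 2L) mean(s[upper.tri(s)]) else NA_real_
  after <- if (n >= 2L) {
    ss <- s[picked, picked]
    mean(ss[upper.tri(ss)])
  } else NA_real_
  list(selected_ids = pool$id[picked], selected = sel,
       n_requested = n, seed = seed,
       mean_similarity_before = before, mean_similarity_after = after)
}

#' Balance two classes by per-class MaxMin selection
#'
#' Runs [maxmin_select()] independently within the positive and negative
#' pools, returning `n_per_class` molecules from each (the study default is
#' 500 per class from a 760-strong augmented positive pool and 743
#' negatives).
#'
#' @param pos,neg [compound_set()] pools for each class.
#' @param n_per_class Molecules to keep per class, default 500.
#' @param kind Fingerprint kind for distances.
#' @param seed Integer seed (positives use `seed`, negatives `seed + 1`).
#' @return List with `pos`, `neg` (the selections from [maxmin_select()]).
#' @export
balance_dataset <- function(pos, neg, n_per_class = 500L, kind = "morgan",
                            seed = 1L) {
  if (nrow(pos) < n_per_class || nrow(neg) < n_per_class) {
    stop("class smaller than n_per_class: pos=", nrow(pos),
         ", neg=", nrow(neg), ", requested ", n_per_class)
  }
  list(
    pos = maxmin_select(pos, n_per_class, kind = kind, seed = seed),
    neg = maxmin_select(neg, n_per_class, kind = kind, seed = seed + 1L)
  )
}
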