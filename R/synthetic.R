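# Seeded synthetic compound libraries with a planted substructure rule.
# Molecules are assembled by concatenating curated, chain-compatible SMILES
# fragments (each fragment's first atom bonds to the previous fragment's
# last atom), which guarantees parseability. Actives carry a planted motif
# fragment -- a catechol ester chemotype chosen purely as a fixture -- and
# inactives are verified motif-free by SMARTS matching, so at zero label
# noise the motif is perfectly informative and a substructure lookup is an
# oracle classifier.

# Default planted motif: catechol ester (acyl on one end, ring substitutable).
MOTIF_SMILES <- "C(=O)Oc1ccc(O)c(O)c1"

# Chain-compatible fragments: valid as a SMILES prefix/suffix/segment, ring
# digits closed within each fragment, terminal atom able to take one more
# bond. Includes decoys (bare catechol, simple esters) so the negative class
# shares partial features with the motif.
fragment_pool <- function() {
  c(
    "CC", "CCC", "CC(C)C", "CCO", "CCN", "C=CC", "CCOC",
    "CC(=O)OC", "CC(=O)N", "CC(C)=O",
    "C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CCOCC1",
    "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "Cc1ccccc1",
    "c1ccc(F)cc1", "c1ccc(Cl)cc1",
    "c1ccc(O)c(O)c1", "C=Cc1ccccc1"
  )
}

#' Generate a labeled synthetic compound library
#'
#' Produces `n_pos` actives, each containing the planted motif substructure,
#' and `n_neg` inactives verified not to contain it; all molecules are valid
#' and structurally distinct (by canonical SMILES). With `noise_rate > 0`
#' labels are flipped independently at that rate after construction. The
#' defaults mirror the 38-inducer / 743-noninducer class imbalance of the
#' training data this generator emulates.
#'
#' @param n_pos,n_neg Class sizes (defaults 38 and 743).
#' @param noise_rate Label-flip probability in `[0, 0.5)`, default 0.
#' @param seed Integer seed; the same spec yields an identical library.
#' @param motif Planted motif as a chain-compatible SMILES fragment, also
#'   used as the SMARTS pattern for verification.
#' @param fragments Fragment pool (chain-compatible SMILES strings).
#' @return A labeled [compound_set()] (actives first: ids `pos1..`, `neg1..`).
#' @export
generate_library <- function(n_pos = 38L, n_neg = 743L, noise_rate = 0,
                             seed = 1L, motif = MOTIF_SMILES,
                             fragments = fragment_pool()) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5)
  set.seed(seed)
  pos <- sample_molecules(n_pos, fragments, motif = motif)
  neg <- sample_molecules(n_neg, fragments, motif = NULL,
                          forbid = motif, taken = pos$canonical)
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  if (noise_rate > 0) {
    flip <- stats::runif(length(label)) < noise_rate
    label[flip] <- 1L - label[flip]
  }
  compound_set(
    c(pos$smiles, neg$smiles),
    id = c(paste0("pos", seq_len(n_pos)), paste0("neg", seq_len(n_neg))),
    label = label, name = "synthetic_library",
    canonical = c(pos$canonical, neg$canonical)
  )
}

#' Generate an unlabeled screening library with spiked actives
#'
#' A stand-in for an external screening collection: `n` molecules of which
#' `spiked_actives` contain the planted motif. The returned truth list names
#' the spiked ids so recovery/enrichment can be measured.
#'
#' @param n Library size.
#' @param spiked_actives Number of motif-bearing molecules (<= n).
#' @param seed Integer seed.
#' @inheritParams generate_library
#' @return List with `library` (unlabeled [compound_set()], shuffled order,
#'   ids `lib1..libN`) and `truth` (ids of the spiked actives).
#' @export
generate_screening_library <- function(n = 200L, spiked_actives = 10L,
                                       seed = 1L, motif = MOTIF_SMILES,
                                       fragments = fragment_pool()) {
  stopifnot(spiked_actives >= 0L, spiked_actives <= n)
  set.seed(seed + 1000L)
  act <- sample_molecules(spiked_actives, fragments, motif = motif)
  dec <- sample_molecules(n - spiked_actives, fragments, motif = NULL,
                          forbid = motif, taken = act$canonical)
  smiles <- c(act$smiles, dec$smiles)
  canonical <- c(act$canonical, dec$canonical)
  is_active <- c(rep(TRUE, spiked_actives), rep(FALSE, n - spiked_actives))
  ord <- sample.int(n)
  lib <- compound_set(smiles[ord], id = paste0("lib", seq_len(n)),
                      name = "screening_library", canonical = canonical[ord])
  list(library = lib, truth = lib$id[is_active[ord]])
}

# Draw distinct molecules. With `motif` set, every molecule embeds the motif
# fragment at a random position; with `forbid` set, candidates matching that
# SMARTS are rejected. `taken` canonical forms are excluded.
sample_molecules <- function(n, fragments, motif = NULL, forbid = NULL,
                             taken = character(0)) {
  if (n == 0L) return(list(smiles = character(0), canonical = character(0)))
  seen <- new.env(parent = emptyenv())
  for (t in taken) assign(t, TRUE, envir = seen)
  smiles <- character(0); canonical <- character(0)
  max_rounds <- 60L
  round <- 0L
  while (length(smiles) < n) {
    round <- round + 1L
    if (round > max_rounds) {
      stop("could not assemble ", n, " distinct molecules (achieved ",
           length(smiles), "); enlarge the fragment pool")
    }
    m <- max(16L, 2L * (n - length(smiles)))
    cand <- vapply(seq_len(m), function(i) {
      # actives swap one slot for the motif so both classes share the same
      # overall size distribution (2-4 fragments)
      k <- if (is.null(motif)) sample(2:4, 1L) else sample(1:3, 1L)
      frags <- sample(fragments, k, replace = TRUE)
      if (!is.null(motif)) {
        at <- sample.int(k + 1L, 1L)
        frags <- append(frags, motif, after = at - 1L)
      }
      paste0(frags, collapse = "")
    }, "")
    can <- ob_canonical(cand)
    ok <- !is.na(can)
    if (!is.null(forbid) && any(ok)) {
      hits <- smarts_matches(can[ok], forbid)
      ok[ok] <- hits == 0L
    }
    if (!is.null(motif) && any(ok)) {
      hits <- smarts_matches(can[ok], motif)
      ok[ok] <- hits > 0L
    }
    for (i in which(ok)) {
      if (length(smiles) >= n) break
      if (!exists(can[i], envir = seen, inherits = FALSE)) {
        assign(can[i], TRUE, envir = seen)
        smiles <- c(smiles, cand[i])
        canonical <- c(canonical, can[i])
      }
    }
  }
  list(smiles = smiles, canonical = canonical)
}
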