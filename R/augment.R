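# Minority-class augmentation by SMILES enumeration: each molecule admits many
# valid SMILES spellings; emitting randomized spellings multiplies the
# minority class without changing its chemistry.

#' Enumerate randomized SMILES spellings of one molecule
#'
#' Writes `k` SMILES strings for the molecule: the canonical spelling first,
#' then spellings produced by re-rooting the molecular graph at a random atom
#' and emitting a depth-first traversal with randomized branch order. Every
#' spelling parses back to the same canonical structure (verified). Spellings
#' are kept distinct where possible; when a molecule admits too few distinct
#' spellings (tiny or highly symmetric structures), duplicates pad the list
#' after `max_retries` draws so that exactly `k` strings are returned.
#'
#' @param smiles A single valid SMILES string.
#' @param k Number of spellings to return (>= 1).
#' @param seed Integer seed; same `(smiles, k, seed)` gives identical output.
#' @param max_retries Distinct-spelling retry budget per variant (default 50).
#' @return Character vector of `k` SMILES spellings.
#' @export
enumerate_smiles <- function(smiles, k, seed = 1L, max_retries = 50L) {
  stopifnot(length(smiles) == 1L, k >= 1L)
  can <- canonicalize(smiles)
  if (k == 1L) return(can)
  g <- suppressWarnings(mol_graph(can))
  # a single-atom molecule admits exactly one spelling
  if (g$n < 2L) return(rep(can, k))
  out <- character(k)
  out[1L] <- can
  seen <- new.env(parent = emptyenv())
  assign(can, TRUE, envir = seen)
  rng <- local_rng(seed)
  n_dup <- 0L
  for (j in 2:k) {
    pick <- NA_character_
    for (try in seq_len(max_retries)) {
      cand <- write_random_smiles(g, rng)
      if (is.na(cand)) next
      if (!exists(cand, envir = seen, inherits = FALSE)) {
        pick <- cand
        assign(cand, TRUE, envir = seen)
        break
      }
      if (try == max_retries) pick <- cand  # tolerate a duplicate
    }
    if (is.na(pick)) pick <- can  # exotic valence: fall back to canonical
    out[j] <- pick
  }
  # verify: every spelling maps back to the parent structure
  rt <- ob_canonical(out)
  bad <- is.na(rt) | rt != can
  if (any(bad)) out[bad] <- can
  out
}

#' Augment the positive (minority) class by SMILES enumeration
#'
#' Expands every record `factor`-fold: each parent contributes its spellings
#' as new records with ids `<parent>#1 .. <parent>#factor`, keeping the
#' parent's label. With the defaults of the study design (38 inducers,
#' factor 20) this yields 760 records.
#'
#' @param positives A labeled [compound_set()]; all labels must be 1.
#' @param factor Amplification factor (>= 1), default 20.
#' @param seed Integer master seed. Per-molecule streams are derived from
#'   `(seed, id)` so results do not depend on record order.
#' @param max_retries Per-variant distinct-spelling retry budget.
#' @return A [compound_set()] with `nrow(positives) * factor` records.
#' @export
augment_positives <- function(positives, factor = 20L, seed = 1L,
                              max_retries = 50L) {
  stopifnot(inherits(positives, "compound_set"), factor >= 1L)
  if (anyNA(positives$label) || any(positives$label != 1L)) {
    stop("augmentation applies to the labeled positive class only")
  }
  n <- nrow(positives)
  smi <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- derive_seed(seed, positives$id[i])
    smi[[i]] <- enumerate_smiles(positives$canonical_smiles[i], k = factor,
                                 seed = sub_seed, max_retries = max_retries)
  }
  ids <- unlist(lapply(seq_len(n), function(i) {
    paste0(positives$id[i], "#", seq_len(factor))
  }))
  compound_set(unlist(smi), id = ids, label = rep(1L, n * factor),
               name = paste0(attr(positives, "name"), "_aug"),
               canonical = rep(positives$canonical_smiles, each = factor))
}

#' Map augmented record ids back to their parents
#' @param ids Character vector of `<parent>#<j>` ids.
#' @return Character vector of parent ids.
#' @export
parent_id <- function(ids) sub("#[0-9]+$", "", ids)

# -- internals ---------------------------------------------------------------

# Cheap deterministic stream: an isolated RNG state advanced per call,
# independent of (and not disturbing) the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    get(".Random.seed", globalenv())
  })
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# 32-bit seed derived from a master seed and a string tag (order-independent
# per-molecule streams).
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(seed, ":", tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Emit one randomized SMILES spelling from a molecular graph: random root,
# depth-first traversal with shuffled neighbor order, ring-closure digits for
# non-tree edges, explicit-H bracket atoms (kekulized bond orders). Returns
# NA if the graph contains a bond order it cannot express.
write_random_smiles <- function(g, rng) {
  n <- g$n
  nb <- vector("list", n)       # neighbor atom index
  nbo <- vector("list", n)      # bond order to that neighbor
  nbe <- vector("list", n)      # edge id
  for (e in seq_len(nrow(g$bonds))) {
    a <- g$bonds[e, 1L]; b <- g$bonds[e, 2L]; o <- g$bonds[e, 3L]
    if (!o %in% c(1L, 2L, 3L)) return(NA_character_)
    nb[[a]] <- c(nb[[a]], b); nbo[[a]] <- c(nbo[[a]], o); nbe[[a]] <- c(nbe[[a]], e)
    nb[[b]] <- c(nb[[b]], a); nbo[[b]] <- c(nbo[[b]], o); nbe[[b]] <- c(nbe[[b]], e)
  }
  bondsum <- vapply(seq_len(n), function(i) sum(nbo[[i]]), 0)

  root <- with_rng(rng, sample.int(n, 1L))
  # iterative DFS, randomized neighbor order; classify tree vs ring edges
  parent <- integer(n); parent[] <- 0L
  children <- vector("list", n)
  visited <- logical(n)
  edge_used <- logical(nrow(g$bonds))
  ring_at <- vector("list", n)   # per atom: list of (digit, bond order)
  ring_digit <- 0L
  order_perm <- with_rng(rng, lapply(seq_len(n), function(i) sample.int(length(nb[[i]]))))
  stack <- root
  visited[root] <- TRUE
  dfs_order <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    dfs_order <- c(dfs_order, v)
    perm <- order_perm[[v]]
    for (t in perm) {
      w <- nb[[v]][t]; e <- nbe[[v]][t]; o <- nbo[[v]][t]
      if (edge_used[e]) next
      if (visited[w]) {
        # ring closure: same digit and bond symbol at both endpoints
        edge_used[e] <- TRUE
        ring_digit <- ring_digit + 1L
        ring_at[[v]] <- c(ring_at[[v]], list(c(ring_digit, o)))
        ring_at[[w]] <- c(ring_at[[w]], list(c(ring_digit, o)))
      } else {
        edge_used[e] <- TRUE
        visited[w] <- TRUE
        parent[w] <- v
        children[[v]] <- c(children[[v]], w)
        stack <- c(stack, w)
      }
    }
  }
  if (!all(visited)) return(NA_character_)  # disconnected: not handled

  bsym <- c("", "=", "#")
  h_cnt <- vapply(seq_len(n), function(i) {
    implicit_h(g$elem[i], g$charge[i], as.integer(bondsum[i]))
  }, 0L)

  emit <- function(v) {
    tok <- atom_token(g$elem[v], g$charge[v], h_cnt[v])
    for (rc in ring_at[[v]]) {
      d <- rc[1L]
      tok <- paste0(tok, bsym[rc[2L]],
                    if (d < 10L) d else paste0("%", d))
    }
    ch <- children[[v]]
    if (length(ch)) {
      segs <- vapply(ch, function(w) {
        o <- nbo[[v]][match(w, nb[[v]])]
        paste0(bsym[o], emit(w))
      }, "")
      if (length(segs) > 1L) {
        tok <- paste0(tok,
                      paste0("(", segs[-length(segs)], ")", collapse = ""),
                      segs[length(segs)])
      } else {
        tok <- paste0(tok, segs)
      }
    }
    tok
  }
  emit(root)
}

atom_token <- function(elem, charge, nh) {
  hpart <- if (nh == 0L) "" else if (nh == 1L) "H" else paste0("H", nh)
  cpart <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-"
           else if (charge > 0L) paste0("+", charge) else paste0("-", abs(charge))
  paste0("[", elem, hpart, cpart, "]")
}
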