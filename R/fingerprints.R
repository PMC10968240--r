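# Molecular fingerprints: MACCS keys (167-slot convention) and Morgan /
# circular fingerprints (radius 2, hashed to 2048 bits). Both are binary,
# deterministic functions of the canonical structure, so every SMILES
# spelling of one molecule yields identical bits.

#' MACCS key fingerprint (167-slot convention)
#'
#' The MACCS catalogue defines 166 public substructure keys; by convention
#' they are stored in a 167-slot vector whose leading slot (index 1 here,
#' key 0) is always zero, so that slot `k + 1` holds key `k`.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Binary matrix with one 167-bit row per molecule
#'   (class `fingerprint_matrix`, kind `"maccs"`).
#' @export
maccs_fingerprint <- function(smiles) {
  fp_matrix(smiles, kind = "maccs")
}

#' Morgan (circular) fingerprint
#'
#' Hashed presence bits of atom-centered circular substructures up to
#' `radius` bond steps (default 2), folded to `nbits` positions
#' (default 2048). Bits are presence/absence, not counts.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Circular-environment radius in bonds (0..5), default 2.
#' @param nbits Folded width; must divide 4096 by a power of two. Default 2048.
#' @return Binary matrix with one `nbits`-bit row per molecule
#'   (class `fingerprint_matrix`, kind `"morgan"`).
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, nbits = 2048L) {
  fp_matrix(smiles, kind = "morgan", radius = radius, nbits = nbits)
}

#' Featurize a compound set
#'
#' Computes one fingerprint row per record, aligned to record order, and
#' carries the set's labels.
#'
#' @param compounds A [compound_set()].
#' @param kind `"maccs"` or `"morgan"`.
#' @param ... Passed to the fingerprint function (`radius`, `nbits`).
#' @return A `fingerprint_matrix`: binary matrix with attributes `kind`,
#'   `ids` and `labels`.
#' @export
featurize_set <- function(compounds, kind = c("maccs", "morgan"), ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(compounds, "compound_set"))
  m <- fp_matrix(compounds$canonical_smiles, kind = kind, ...)
  attr(m, "ids") <- compounds$id
  attr(m, "labels") <- compounds$label
  m
}

# -- internals ---------------------------------------------------------------

fp_matrix <- function(smiles, kind, radius = 2L, nbits = 2048L) {
  if (kind == "morgan") {
    stopifnot(radius >= 0L, radius <= 5L)
    if (!(nbits >= 1L && 4096L %% nbits == 0L && bitwAnd(4096L %/% nbits, 4096L %/% nbits - 1L) == 0L)) {
      stop("nbits must be 4096 divided by a power of two (e.g. 2048, 1024)")
    }
  }
  n <- length(smiles)
  ncol <- if (kind == "maccs") 167L else as.integer(nbits)
  if (n == 0L) {
    m <- matrix(integer(0), nrow = 0L, ncol = ncol)
    return(structure(m, kind = kind, class = c("fingerprint_matrix", class(m))))
  }
  can <- canonicalize(smiles)  # spelling invariance + validity check
  key <- if (kind == "maccs") can else paste0(kind, radius, "_", nbits, ":", can)
  cached <- fp_cache_get(kind, key)
  todo <- which(vapply(cached, is.null, TRUE))
  todo <- todo[!duplicated(key[todo])]  # one computation per structure
  if (length(todo)) {
    mols <- ob_mols(can[todo])
    raw <- if (kind == "maccs") {
      ChemmineOB::fingerprint_OB(mols, "MACCS")
    } else {
      ChemmineOB::fingerprint_OB(mols, paste0("ECFP", 2L * radius))
    }
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
    for (j in seq_along(todo)) {
      row <- as.integer(raw[j, ])
      row <- if (kind == "maccs") c(0L, row[1:166]) else fold_bits(row, nbits)
      fp_cache_put(kind, key[todo[j]], row)
    }
    cached <- fp_cache_get(kind, key)
  }
  m <- do.call(rbind, cached)
  dimnames(m) <- NULL
  structure(m, kind = kind, class = c("fingerprint_matrix", class(m)))
}

# OR-fold a binary vector down to `nbits` (halving repeatedly).
fold_bits <- function(bits, nbits) {
  while (length(bits) > nbits) {
    half <- length(bits) %/% 2L
    bits <- as.integer(bits[seq_len(half)] | bits[half + seq_len(half)])
  }
  bits
}

# Per-session fingerprint memo-cache keyed by canonical SMILES: MACCS is a
# 166-pattern SMARTS scan and ECFP a full environment enumeration per call,
# so pipelines that featurize the same molecules repeatedly benefit a lot.
.fp_cache <- new.env(parent = emptyenv())

fp_cache_get <- function(kind, keys) {
  env <- fp_cache_env(kind)
  lapply(keys, function(k) if (exists(k, envir = env, inherits = FALSE))
    get(k, envir = env) else NULL)
}

fp_cache_put <- function(kind, key, row) {
  assign(key, row, envir = fp_cache_env(kind))
}

fp_cache_env <- function(kind) {
  if (!exists(kind, envir = .fp_cache, inherits = FALSE)) {
    assign(kind, new.env(parent = emptyenv()), envir = .fp_cache)
  }
  get(kind, envir = .fp_cache)
}

fp_kind <- function(m) attr(m, "kind")
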