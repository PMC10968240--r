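# Low-level chemistry backend: SMILES parsing, canonicalization and molecular
# graphs, delegated to Open Babel through ChemmineOB/ChemmineR.

#' Canonicalize a SMILES string
#'
#' Converts any valid SMILES spelling of a molecule to its unique canonical
#' form, so that all enumerated spellings of one structure map to a single
#' string. Canonicalization is deterministic and idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), an unparseable SMILES raises an error
#'   naming the offending string; if `FALSE`, it yields `NA`.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize("OCC") # "CCO"
#' @export
canonicalize <- function(smiles, strict = TRUE) {
  if (length(smiles) == 0L) return(character(0))
  stopifnot(is.character(smiles))
  out <- ob_canonical(smiles)
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparseable SMILES: ", paste(sQuote(bad), collapse = ", "))
  }
  out
}

# Vectorized canonical SMILES via Open Babel. Batch conversion aborts at the
# first bad line, so we convert in one pass and realign by injected ids;
# missing ids are retried line by line to localize failures.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  ids <- paste0("m", seq_len(n))
  src <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n")),
    error = function(e) ""
  )
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) p[length(p)], "")
    got_smi <- vapply(parts, function(p) p[1L], "")
    hit <- match(got_id, ids)
    ok <- !is.na(hit)
    res[hit[ok]] <- got_smi[ok]
  }
  # any line after the first failure was dropped from the batch: retry singly
  for (i in which(is.na(res))) {
    one <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[i], "\tx\n")),
      error = function(e) ""
    )
    one <- strsplit(one, "\n", fixed = TRUE)[[1]]
    if (length(one) && nzchar(one[1L])) {
      res[i] <- strsplit(one[1L], "\t", fixed = TRUE)[[1]][1L]
    }
  }
  res
}

# Parse SMILES into a list of Open Babel molecule handles (one per input).
# Input must be pre-validated; Open Babel may still read lenient forms.
ob_mols <- function(smiles, ids = NULL) {
  if (length(smiles) == 0L) return(list())
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  ChemmineOB::forEachMol("SMILES", paste0(src, "\n"), identity)
}

#' Count substructure matches by SMARTS pattern
#'
#' Thin wrapper over Open Babel SMARTS matching; used by the synthetic-library
#' generator to confirm presence/absence of the planted motif.
#'
#' @param smiles Character vector of valid SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of unique match counts per molecule.
#' @export
smarts_matches <- function(smiles, smarts) {
  if (length(smiles) == 0L) return(integer(0))
  mols <- ob_mols(smiles)
  as.integer(ChemmineOB::smartsSearch_OB(mols, smarts))
}

# Molecular graph of one molecule: elements, formal charges and bond list
# (kekulized orders 1/2/3), extracted from the SDF atom/bond blocks.
mol_graph <- function(smiles) {
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(c(mol = smiles)))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  # MDL charge codes: 0 none, 1..3 = +3..+1, 5..7 = -1..-3 (4 = radical)
  code <- if ("C5" %in% colnames(ab)) as.integer(ab[, "C5"]) else integer(nrow(ab))
  charge <- integer(length(code))
  charge[code >= 1 & code <= 3] <- 4L - code[code >= 1 & code <= 3]
  charge[code >= 5 & code <= 7] <- -(code[code >= 5 & code <= 7] - 4L)
  bonds <- if (length(bb) == 0L ||
               (!is.null(dim(bb)) && (nrow(bb) == 0L || ncol(bb) < 3L))) {
    matrix(integer(0), nrow = 0, ncol = 3)  # single-atom molecule
  } else if (is.null(dim(bb))) {
    matrix(as.integer(bb[1:3]), nrow = 1)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  list(n = length(elem), elem = elem, charge = charge, bonds = bonds)
}

# Implicit hydrogen count under the Daylight-style default valence model,
# adjusted for formal charge. Only used when writing explicit-H bracket
# atoms; every emitted spelling is round-trip verified afterwards.
implicit_h <- function(elem, charge, bondsum) {
  val <- switch(elem,
    "C" = 4L - abs(charge),
    "N" = 3L + charge,
    "O" = 2L + charge,
    "P" = if (bondsum > 3L) 5L else 3L + charge,
    "S" = if (bondsum > 4L) 6L else if (bondsum > 2L) 4L else 2L + charge,
    "B" = 3L - charge,
    "F" = , "Cl" = , "Br" = , "I" = if (charge == 0L) 1L else 0L,
    0L
  )
  max(0L, val - bondsum)
}
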