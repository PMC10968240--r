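# Compound containers and plain-text I/O.
#
# A compound_set is a data.frame with columns id, smiles, canonical_smiles and
# label (NA when unlabeled), plus a "name" attribute. The file dialect is one
# molecule per line, `SMILES[<tab>id]`, with `#` comment lines.

#' Construct a compound set
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional identifiers; defaults to `row1..rowN`. Must be unique.
#' @param label Optional binary labels (1 = active/inducer, 0 = inactive).
#' @param name Name of the set.
#' @param canonical Pre-computed canonical SMILES (skips recomputation).
#' @return An object of class `compound_set` (a data.frame with columns
#'   `id`, `smiles`, `canonical_smiles`, `label`).
#' @export
compound_set <- function(smiles, id = NULL, label = NULL, name = "set",
                         canonical = NULL) {
  n <- length(smiles)
  if (is.null(id)) id <- if (n) paste0("row", seq_len(n)) else character(0)
  if (anyDuplicated(id)) {
    stop("duplicate compound ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.null(label)) label <- rep(NA_integer_, n)
  label <- as.integer(label)
  if (any(!is.na(label) & !(label %in% c(0L, 1L)))) {
    stop("labels must be binary (0/1) or NA")
  }
  if (is.null(canonical)) canonical <- canonicalize(smiles)
  df <- data.frame(
    id = as.character(id), smiles = as.character(smiles),
    canonical_smiles = canonical, label = label,
    stringsAsFactors = FALSE
  )
  attr(df, "name") <- name
  class(df) <- c("compound_set", "data.frame")
  df
}

#' @export
print.compound_set <- function(x, ...) {
  lab <- x$label
  cat(sprintf("compound_set '%s': %d molecules (%d active, %d inactive, %d unlabeled)\n",
              attr(x, "name"), nrow(x),
              sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
              sum(is.na(lab))))
  if (nrow(x)) {
    utils::head(as.data.frame(x), 6) |> print()
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

#' Read a SMILES file into a compound set
#'
#' One molecule per line as `SMILES[<tab>id]`; empty and `#`-prefixed lines
#' are ignored. Every record is canonicalized on read.
#'
#' @param path File path.
#' @param label Optional label (0/1) applied to all records, or `NA`.
#' @param strict If `TRUE` (default) an unparseable SMILES is an error naming
#'   its line number; if `FALSE` bad lines are skipped with a warning.
#' @param name Set name; defaults to the file name.
#' @return A [compound_set()].
#' @export
read_smiles_file <- function(path, label = NA, strict = TRUE, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- basename(path)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  lineno <- which(keep)
  lines <- trimws(raw[keep])
  if (!length(lines)) {
    return(compound_set(character(0), name = name, canonical = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  id <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  id[is.na(id)] <- paste0("row", seq_along(id))[is.na(id)]
  can <- canonicalize(smi, strict = FALSE)
  bad <- is.na(can)
  if (any(bad)) {
    if (strict) {
      stop("unparseable SMILES at line ", paste(lineno[bad], collapse = ", "),
           " of ", path)
    }
    warning(sum(bad), " unparseable line(s) skipped in ", path,
            " (lines ", paste(lineno[bad], collapse = ", "), ")")
  }
  lab <- if (is.na(label)) NULL else rep(as.integer(label), sum(!bad))
  compound_set(smi[!bad], id = id[!bad], label = lab, name = name,
               canonical = can[!bad])
}

#' Write a compound set to a SMILES file
#'
#' Inverse of [read_smiles_file()]: writes `SMILES<tab>id` lines in set order,
#' so read-write-read is the identity on ids, order and SMILES.
#'
#' @param x A [compound_set()].
#' @param path Output path.
#' @export
write_smiles_file <- function(x, path) {
  stopifnot(inherits(x, "compound_set"))
  writeLines(paste(x$smiles, x$id, sep = "\t"), path)
  invisible(path)
}

#' Write a ranked screening score table
#'
#' CSV with columns `id,smiles,score,active`, sorted by descending score
#' (stable for ties). Scores are written with enough digits to round-trip
#' to at least six decimals.
#'
#' @param results A `screening_result` data.frame from [rank_library()].
#' @param path Output path.
#' @export
write_score_table <- function(results, path) {
  df <- as.data.frame(results)[, c("id", "smiles", "score", "active")]
  df <- df[order(-df$score), , drop = FALSE]
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a score table written by [write_score_table()]
#' @param path CSV path.
#' @return data.frame with columns id, smiles, score, active.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character", smiles = "character",
                                       score = "numeric", active = "logical"))
  df
}
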