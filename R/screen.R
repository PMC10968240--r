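# Library screening: score unlabeled compounds with the replicate ensemble,
# call actives at the decision threshold, rank by score.

#' Score a compound library
#'
#' Replicate-mean sigmoid score per compound, aligned to library order.
#'
#' @param object An [activity_model()].
#' @param library A [compound_set()] (labels ignored) or feature list.
#' @return Numeric score vector in `[0, 1]`.
#' @export
predict_scores <- function(object, library) {
  predict(object, library, type = "score")
}

#' Rank a scored library
#'
#' Sorts by descending score (ties keep input order), assigns ranks 1..N and
#' flags actives where score is strictly greater than the threshold.
#'
#' @param scores Numeric scores aligned to `library`.
#' @param library The scored [compound_set()].
#' @param threshold Decision threshold, default 0.5.
#' @return A `screening_result` data.frame: `id`, `smiles`, `score`,
#'   `active`, `rank`, sorted by rank.
#' @export
rank_library <- function(scores, library, threshold = 0.5) {
  stopifnot(length(scores) == nrow(library))
  ord <- order(-scores)  # stable: ties by input order
  df <- data.frame(
    id = library$id[ord], smiles = library$smiles[ord],
    score = scores[ord], active = scores[ord] > threshold,
    rank = seq_along(ord), stringsAsFactors = FALSE
  )
  class(df) <- c("screening_result", "data.frame")
  attr(df, "threshold") <- threshold
  df
}

#' Screen a library end to end
#'
#' @inheritParams predict_scores
#' @param threshold Decision threshold.
#' @return A `screening_result` (see [rank_library()]).
#' @export
screen_library <- function(object, library, threshold = 0.5) {
  rank_library(predict_scores(object, library), library, threshold)
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result: %d compounds, %d active at threshold %.2f\n",
              nrow(x), sum(x$active), attr(x, "threshold")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
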