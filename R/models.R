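# User-facing model interface: one fitting function returning a classed
# object with the usual methods. An activity_model bundles `replicates`
# independently trained networks of one architecture; prediction averages
# their sigmoid outputs.

#' Stratified train/test split
#'
#' Randomly partitions `n` items so that `floor(fraction * n)` go to
#' training. When `labels` are supplied the split is stratified: the class
#' ratio is preserved within one item per class.
#'
#' @param n Number of items (>= 2), or ignored when `labels` given.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param labels Optional binary labels for stratification.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(n, fraction = 0.8, seed = 1L, labels = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (!is.null(labels)) n <- length(labels)
  stopifnot(n >= 2L)
  n_train <- floor(fraction * n)
  set.seed(seed)
  if (is.null(labels)) {
    train <- sort(sample.int(n, n_train))
  } else {
    idx_by_class <- split(seq_len(n), labels)
    # per-class counts: floor of the class share, remainder to the largest
    # fractional parts so the total is exactly floor(fraction * n)
    sizes <- vapply(idx_by_class, length, 0L)
    raw <- fraction * sizes
    base <- floor(raw)
    rem <- n_train - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    train <- sort(unlist(Map(function(ii, k) sample(ii, k), idx_by_class, base),
                  use.names = FALSE))
  }
  test <- setdiff(seq_len(n), train)
  if (!is.null(labels)) {
    if (length(unique(labels[train])) < 2L || length(unique(labels[test])) < 2L) {
      stop("degenerate split: a class is absent from train or test")
    }
  }
  list(train = train, test = test)
}

#' Training configuration
#'
#' The study protocol: 20 epochs of minibatch Adam (batch 32, learning rate
#' 0.001, no amsgrad, no decay) on binary cross-entropy, training order
#' shuffled each epoch, 80/20 train/test split, three replicate runs whose
#' outputs are averaged.
#'
#' @param epochs,batch_size,learning_rate,dropout,split_fraction,replicates,seed,shuffle
#'   Self-describing; defaults are the protocol values.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, learning_rate = 1e-3,
                         dropout = 0.2, split_fraction = 0.8, replicates = 3L,
                         seed = 1L, shuffle = TRUE) {
  stopifnot(epochs >= 0L, batch_size >= 1L, learning_rate > 0,
            dropout >= 0, dropout < 1,
            split_fraction > 0, split_fraction < 1, replicates >= 1L)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 split_fraction = split_fraction,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Fit an activity classifier
#'
#' Trains `config$replicates` networks of the chosen architecture on a
#' labeled compound set (or pre-computed feature matrices) and returns a
#' classed model whose predictions are the replicate-mean sigmoid scores.
#'
#' Architectures: `"cnn"` embeds the 167-position MACCS bit sequence and
#' applies a 1-D convolution (330 filters, window 16, stride 1), global max
#' pooling and a 128-unit ReLU layer; `"dnn"` stacks 2048/64/16-unit ReLU
#' layers on the Morgan bits; `"hcd"` removes both sigmoid heads, fuses the
#' 128-d and 16-d penultimate representations (144-d) and trains a single
#' sigmoid head end to end.
#'
#' @param data A labeled [compound_set()], or a list with elements `maccs`
#'   (n x 167) and/or `morgan` (n x 2048) plus `labels`.
#' @param arch `"hcd"` (default), `"cnn"` or `"dnn"`.
#' @param config A [train_config()].
#' @param embed_dim Embedding width for the CNN bit tokens, default 32.
#' @param verbose Print per-epoch losses.
#' @return Object of class `activity_model` with elements `arch`, `nets`
#'   (trained replicates), `history` (epochs x replicates loss matrix),
#'   `config`, `embed_dim`.
#' @seealso [predict.activity_model()], [evaluate_model()], [screen_library()]
#' @export
activity_model <- function(data, arch = c("hcd", "cnn", "dnn"),
                           config = train_config(), embed_dim = 32L,
                           verbose = FALSE) {
  arch <- match.arg(arch)
  feats <- model_features(data, arch)
  y <- feats$labels
  if (anyNA(y)) stop("all training records must be labeled")
  X <- model_input(feats, arch)
  nets <- vector("list", config$replicates)
  history <- matrix(NA_real_, config$epochs, config$replicates)
  for (r in seq_len(config$replicates)) {
    rseed <- derive_seed(config$seed, paste0("replicate", r))
    set.seed(rseed)
    net <- nn_init(arch, embed_dim = embed_dim)
    net <- nn_train(net, X, y,
                    epochs = config$epochs, batch_size = config$batch_size,
                    lr = config$learning_rate, pdrop = config$dropout,
                    shuffle = config$shuffle, seed = rseed,
                    verbose = verbose)
    nets[[r]] <- net
    if (config$epochs > 0L) history[, r] <- net$history
  }
  structure(list(arch = arch, nets = nets, history = history,
                 config = config, embed_dim = embed_dim,
                 n_train = length(y), call = match.call()),
            class = "activity_model")
}

#' Predict activity scores
#'
#' @param object An [activity_model()].
#' @param newdata A [compound_set()] or a feature list (see [activity_model()]).
#' @param type `"score"` for replicate-mean probabilities in `[0,1]`,
#'   `"class"` for the 0/1 call at `threshold` (strictly greater than).
#' @param threshold Decision threshold, default 0.5.
#' @param per_replicate If `TRUE`, return the n x replicates score matrix.
#' @param ... Unused.
#' @return Numeric vector of scores (or 0/1 calls), aligned to `newdata`.
#' @export
predict.activity_model <- function(object, newdata, type = c("score", "class"),
                                   threshold = 0.5, per_replicate = FALSE, ...) {
  type <- match.arg(type)
  feats <- model_features(newdata, object$arch)
  X <- model_input(feats, object$arch)
  mat <- vapply(object$nets, function(net) nn_predict(net, X),
                numeric(nrow_input(X)))
  if (nrow_input(X) == 1L) mat <- matrix(mat, nrow = 1L)
  if (nrow_input(X) == 0L) mat <- matrix(numeric(0), 0L, length(object$nets))
  if (per_replicate) return(mat)
  score <- rowMeans(mat)
  if (type == "class") as.integer(score > threshold) else score
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("activity_model (%s): %d replicate(s), trained on %d molecules\n",
              toupper(x$arch), length(x$nets), x$n_train))
  cat(sprintf("  protocol: %d epochs, batch %d, Adam lr %g, dropout %g\n",
              x$config$epochs, x$config$batch_size, x$config$learning_rate,
              x$config$dropout))
  if (x$config$epochs > 0L) {
    cat(sprintf("  final training loss (mean over replicates): %.4f\n",
                mean(x$history[nrow(x$history), ])))
  }
  invisible(x)
}

#' @export
summary.activity_model <- function(object, ...) {
  print(object)
  if (object$config$epochs > 0L) {
    cat("  per-replicate final loss:",
        paste(sprintf("%.4f", object$history[nrow(object$history), ]),
              collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
plot.activity_model <- function(x, ...) {
  if (x$config$epochs == 0L) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(x$history, type = "l", lty = 1,
                    xlab = "epoch", ylab = "training loss (BCE)",
                    main = sprintf("%s training loss", toupper(x$arch)), ...)
  invisible(x)
}

# -- feature plumbing --------------------------------------------------------

# Normalizes `data` into list(maccs=, morgan=, labels=), computing only what
# the architecture needs.
model_features <- function(data, arch) {
  if (inherits(data, "compound_set")) {
    out <- list(labels = data$label)
    if (arch %in% c("cnn", "hcd")) out$maccs <- featurize_set(data, "maccs")
    if (arch %in% c("dnn", "hcd")) out$morgan <- featurize_set(data, "morgan")
    return(out)
  }
  if (is.list(data)) {
    need <- switch(arch, cnn = "maccs", dnn = "morgan", hcd = c("maccs", "morgan"))
    miss <- setdiff(need, names(data))
    if (length(miss)) stop("missing feature matrices: ", paste(miss, collapse = ", "))
    for (nm in need) {
      want <- if (nm == "maccs") CNN_LEN else DNN_LEN
      if (ncol(data[[nm]]) != want) {
        stop(nm, " features must have ", want, " columns, got ", ncol(data[[nm]]))
      }
    }
    return(data[c(intersect(names(data), c("maccs", "morgan", "labels")))])
  }
  stop("data must be a compound_set or a feature list")
}

model_input <- function(feats, arch) {
  switch(arch,
    cnn = unclass_fp(feats$maccs),
    dnn = unclass_fp(feats$morgan),
    hcd = list(maccs = unclass_fp(feats$maccs), morgan = unclass_fp(feats$morgan)))
}

unclass_fp <- function(m) {
  m <- unclass(m)
  attr(m, "kind") <- NULL; attr(m, "ids") <- NULL; attr(m, "labels") <- NULL
  storage.mode(m) <- "double"
  m
}

nrow_input <- function(X) if (is.list(X)) nrow(X[[1]]) else nrow(X)
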