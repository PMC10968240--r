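# Neural-network engine: forward/backward passes and Adam for the three
# architectures (CNN on the MACCS bit sequence, DNN on Morgan bits, and the
# fused hybrid). Written on base-R matrix algebra; the convolution is a
# single GEMM on the unfolded window matrix, so BLAS carries the cost.
#
# Shapes (B = batch):
#   CNN : bits (B x 167) -> embedding {0,1}->R^e -> dropout -> conv1d
#         (330 filters, kernel 16, stride 1, valid padding -> 152 positions,
#         ReLU) -> global max pool -> dense 128 ReLU -> dropout -> sigmoid
#   DNN : bits (B x 2048) -> dense 2048 ReLU -> dropout -> dense 64 ReLU ->
#         dropout -> dense 16 ReLU -> sigmoid
#   HCD : both trunks without their sigmoid heads, concatenated (128 + 16 =
#         144) -> single sigmoid head, trained end-to-end jointly.

CNN_LEN <- 167L
DNN_LEN <- 2048L
CONV_K <- 16L
CONV_F <- 330L
CONV_P <- CNN_LEN - CONV_K + 1L  # 152 output positions

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# -- parameter initialization ------------------------------------------------

nn_init_cnn_trunk <- function(embed_dim) {
  list(
    E  = matrix(stats::runif(2L * embed_dim, -0.05, 0.05), 2L, embed_dim),
    Wc = glorot(CONV_K * embed_dim, CONV_F),
    bc = numeric(CONV_F),
    W1 = glorot(CONV_F, 128L),
    b1 = numeric(128L)
  )
}

nn_init_dnn_trunk <- function() {
  list(
    W1 = glorot(DNN_LEN, 2048L), b1 = numeric(2048L),
    W2 = glorot(2048L, 64L),     b2 = numeric(64L),
    W3 = glorot(64L, 16L),       b3 = numeric(16L)
  )
}

nn_init <- function(arch, embed_dim = 32L) {
  p <- switch(arch,
    cnn = c(nn_init_cnn_trunk(embed_dim),
            list(Wo = glorot(128L, 1L), bo = numeric(1L))),
    dnn = c(nn_init_dnn_trunk(),
            list(Wo = glorot(16L, 1L), bo = numeric(1L))),
    hcd = c(prefix_names(nn_init_cnn_trunk(embed_dim), "c."),
            prefix_names(nn_init_dnn_trunk(), "d."),
            list(Wo = glorot(144L, 1L), bo = numeric(1L))),
    stop("unknown architecture: ", arch)
  )
  list(arch = arch, embed_dim = embed_dim, params = p)
}

prefix_names <- function(x, pre) stats::setNames(x, paste0(pre, names(x)))

# -- CNN trunk ---------------------------------------------------------------

# The unfold (im2col), convolution GEMM, ReLU and global max pool live in
# compiled code (src/convnet.cpp); dropout masks and the embedding lookup
# stay in R so all randomness draws from R's RNG.

cnn_trunk_forward <- function(par, X, pdrop, train, pre = "") {
  g <- function(nm) par[[paste0(pre, nm)]]
  B <- nrow(X)
  tok <- as.vector(X) + 1L                     # column-major (b, i)
  A <- g("E")[tok, , drop = FALSE]             # (B*167) x e
  Ma <- NULL
  if (train && pdrop > 0) {
    Ma <- matrix(stats::rbinom(length(A), 1L, 1 - pdrop) / (1 - pdrop),
                 nrow(A), ncol(A))
    A <- A * Ma
  }
  cf <- conv_pool_forward(A, B, g("Wc"), g("bc"))
  D1 <- pmax(sweep_add(cf$P %*% g("W1"), g("b1")), 0)  # B x 128
  Md <- NULL
  if (train && pdrop > 0) {
    Md <- matrix(stats::rbinom(length(D1), 1L, 1 - pdrop) / (1 - pdrop),
                 nrow(D1), ncol(D1))
    D1 <- D1 * Md
  }
  list(out = D1, cache = list(B = B, tok = tok, A = A, Ma = Ma,
                              Z = cf$Z, AM = cf$AM, P = cf$P, Md = Md))
}

cnn_trunk_backward <- function(par, cache, dOut, pre = "") {
  g <- function(nm) par[[paste0(pre, nm)]]
  B <- cache$B
  if (!is.null(cache$Md)) dOut <- dOut * cache$Md
  Dpre <- sweep_add(cache$P %*% g("W1"), g("b1"))
  dD1 <- dOut * (Dpre > 0)
  dW1 <- crossprod(cache$P, dD1)
  db1 <- colSums(dD1)
  dP <- dD1 %*% t(g("W1"))                     # B x 330
  cb <- conv_pool_backward(cache$A, B, g("Wc"), cache$Z, dP, cache$AM)
  dA <- cb$dA
  if (!is.null(cache$Ma)) dA <- dA * cache$Ma
  dE <- rowsum(dA, group = cache$tok)          # rows sorted by token value
  dEfull <- matrix(0, 2L, ncol(dA))
  dEfull[as.integer(rownames(dE)), ] <- dE
  grads <- list(E = dEfull, Wc = cb$dWc, bc = cb$dbc, W1 = dW1, b1 = db1)
  stats::setNames(grads, paste0(pre, names(grads)))
}

# -- DNN trunk ---------------------------------------------------------------

dnn_trunk_forward <- function(par, X, pdrop, train, pre = "") {
  g <- function(nm) par[[paste0(pre, nm)]]
  drop_mask <- function(M) {
    if (train && pdrop > 0) {
      matrix(stats::rbinom(length(M), 1L, 1 - pdrop) / (1 - pdrop),
             nrow(M), ncol(M))
    } else NULL
  }
  Z1 <- sweep_add(gemm_float(X, g("W1")), g("b1")); H1 <- pmax(Z1, 0)
  M1 <- drop_mask(H1); if (!is.null(M1)) H1 <- H1 * M1
  Z2 <- sweep_add(H1 %*% g("W2"), g("b2")); H2 <- pmax(Z2, 0)
  M2 <- drop_mask(H2); if (!is.null(M2)) H2 <- H2 * M2
  Z3 <- sweep_add(H2 %*% g("W3"), g("b3")); H3 <- pmax(Z3, 0)
  list(out = H3, cache = list(X = X, Z1 = Z1, H1 = H1, M1 = M1,
                              Z2 = Z2, H2 = H2, M2 = M2, Z3 = Z3))
}

dnn_trunk_backward <- function(par, cache, dOut, pre = "") {
  g <- function(nm) par[[paste0(pre, nm)]]
  dZ3 <- dOut * (cache$Z3 > 0)
  dW3 <- crossprod(cache$H2, dZ3); db3 <- colSums(dZ3)
  dH2 <- dZ3 %*% t(g("W3"))
  if (!is.null(cache$M2)) dH2 <- dH2 * cache$M2
  dZ2 <- dH2 * (cache$Z2 > 0)
  dW2 <- crossprod(cache$H1, dZ2); db2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(g("W2"))
  if (!is.null(cache$M1)) dH1 <- dH1 * cache$M1
  dZ1 <- dH1 * (cache$Z1 > 0)
  dW1 <- gemm_float(cache$X, dZ1, transA = TRUE); db1 <- colSums(dZ1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
  stats::setNames(grads, paste0(pre, names(grads)))
}

# -- full networks -----------------------------------------------------------

# X: for cnn a B x 167 matrix; dnn a B x 2048 matrix; hcd a list
# (maccs = B x 167, morgan = B x 2048).
nn_forward <- function(net, X, pdrop = 0.2, train = FALSE) {
  par <- net$params
  tr <- switch(net$arch,
    cnn = cnn_trunk_forward(par, X, pdrop, train),
    dnn = dnn_trunk_forward(par, X, pdrop, train),
    hcd = {
      fc <- cnn_trunk_forward(par, X$maccs, pdrop, train, pre = "c.")
      fd <- dnn_trunk_forward(par, X$morgan, pdrop, train, pre = "d.")
      list(out = cbind(fc$out, fd$out),
           cache = list(cnn = fc$cache, dnn = fd$cache))
    })
  z <- sweep_add(tr$out %*% par$Wo, par$bo)
  list(score = as.vector(sigmoid(z)), z = as.vector(z),
       feat = tr$out, cache = tr$cache)
}

# Mean binary cross-entropy loss and gradients for one batch.
nn_loss_grads <- function(net, X, y, pdrop = 0.2) {
  fw <- nn_forward(net, X, pdrop = pdrop, train = TRUE)
  par <- net$params
  B <- length(y)
  s <- fw$score
  eps <- 1e-12
  loss <- -mean(y * log(s + eps) + (1 - y) * log(1 - s + eps))
  dz <- matrix((s - y) / B, ncol = 1L)
  dWo <- crossprod(fw$feat, dz)
  dbo <- sum(dz)
  dFeat <- dz %*% t(par$Wo)
  trunk <- switch(net$arch,
    cnn = cnn_trunk_backward(par, fw$cache, dFeat),
    dnn = dnn_trunk_backward(par, fw$cache, dFeat),
    hcd = c(cnn_trunk_backward(par, fw$cache$cnn,
                               dFeat[, 1:128, drop = FALSE], pre = "c."),
            dnn_trunk_backward(par, fw$cache$dnn,
                               dFeat[, 129:144, drop = FALSE], pre = "d.")))
  list(loss = loss, grads = c(trunk, list(Wo = dWo, bo = dbo)))
}

# -- Adam --------------------------------------------------------------------

# Adam keeps its moments (and the parameters) in an environment so the
# fused C++ kernel can update them in place; all three are allocated fresh
# per replicate and never shared outside the training loop.
adam_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$v <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    adam_update_inplace(params[[nm]], state$m[[nm]], state$v[[nm]],
                        grads[[nm]], lr, beta1, beta2, c1, c2, eps)
  }
  params
}

# -- training loop -----------------------------------------------------------

# Trains one network in place; X as in nn_forward, y in {0,1}. Runs exactly
# `epochs` epochs of minibatch Adam on shuffled order, recording the mean
# per-epoch training loss.
nn_train <- function(net, X, y, epochs = 20L, batch_size = 32L, lr = 1e-3,
                     pdrop = 0.2, shuffle = TRUE, seed = 1L,
                     verbose = FALSE) {
  n <- length(y)
  if (n == 0L) stop("empty training set")
  if (length(unique(y)) < 2L && epochs > 0L) {
    stop("training labels contain a single class")
  }
  set.seed(seed)
  state <- adam_init(net$params)
  history <- numeric(epochs)
  take <- function(M, ii) {
    if (is.list(M)) lapply(M, function(m) m[ii, , drop = FALSE])
    else M[ii, , drop = FALSE]
  }
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    starts <- seq(1L, n, by = batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      ii <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      lg <- nn_loss_grads(net, take(X, ii), y[ii], pdrop = pdrop)
      adam_step(net$params, lg$grads, state, lr = lr)  # updates in place
      losses[bi] <- lg$loss
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, history[ep]))
  }
  net$history <- history
  net
}

# Replicate-mean scores, evaluated in chunks to bound memory.
nn_predict <- function(net, X, chunk = 512L) {
  n <- if (is.list(X)) nrow(X[[1]]) else nrow(X)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    ii <- s:min(s + chunk - 1L, n)
    Xi <- if (is.list(X)) lapply(X, function(m) m[ii, , drop = FALSE])
          else X[ii, , drop = FALSE]
    out[ii] <- nn_forward(net, Xi, train = FALSE)$score
  }
  out
}

sweep_add <- function(M, b) M + rep(b, each = nrow(M))
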