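# Backward pass through the network. Gradients are returned in the same
# structure as the parameters (conv W/b, batch-norm gamma/beta, dense W/b);
# batch-norm running statistics are not optimized and get no gradient.

# dzn: dL/d(final pre-sigmoid logit), length-n vector. With the binary
# cross-entropy averaged over the batch this is (p - y) / n.
net_backward <- function(state, cache, dzn) {
  spec <- state$spec
  n <- cache$n
  nd <- length(state$dense)
  grads <- list(conv = vector("list", length(state$conv)),
                bn = vector("list", length(state$bn)),
                dense = vector("list", nd))
  dH <- matrix(dzn, n, 1)
  for (j in rev(seq_len(nd))) {
    dp <- state$dense[[j]]
    inp <- cache$dense[[j]]$inp
    if (j < nd) {
      # through the ReLU of this layer's output
      dH <- dH * (cache$dense[[j]]$out > 0)
    }
    grads$dense[[j]] <- list(W = crossprod(inp, dH), b = colSums(dH))
    dH <- dH %*% t(dp$W)
    if (j == nd && nd > 1L && !is.null(cache$drop_mask)) {
      dH <- dH * cache$drop_mask / (1 - spec$dropout)
    }
  }
  # global average pooling backward: spread each feature gradient uniformly
  dims <- cache$gap_dims
  V <- prod(dims[1:3]); C <- dims[4]
  dxs <- lapply(seq_len(n), function(s) {
    a <- matrix(rep(dH[s, ] / V, each = V), V, C)
    dim(a) <- dims
    a
  })
  for (i in rev(seq_along(spec$blocks))) {
    blk <- spec$blocks[[i]]
    cb <- cache$blocks[[i]]
    bnp <- state$bn[[i]]
    dims <- cb$pool_dims
    V <- prod(dims[1:3]); C <- dims[4]
    G <- do.call(rbind, lapply(dxs, function(d) { dim(d) <- c(V, C); d }))
    G <- G * (cb$act > 0)                      # ReLU backward
    dgamma <- colSums(G * cb$xhat)
    dbeta <- colSums(G)
    grads$bn[[i]] <- list(gamma = dgamma, beta = dbeta)
    dxhat <- sweep(G, 2, bnp$gamma, "*")
    m <- nrow(G)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cb$xhat)
    dA <- sweep(dxhat, 2, s1 / m, "-") - sweep(cb$xhat, 2, s2 / m, "*")
    dA <- sweep(dA, 2, cb$istd, "*")
    dW <- array(0, dim = dim(state$conv[[i]]$W))
    db <- numeric(length(state$conv[[i]]$b))
    dxs_new <- vector("list", n)
    for (s in seq_len(n)) {
      dy <- dA[((s - 1) * V + 1):(s * V), , drop = FALSE]
      dim(dy) <- dims
      dconv <- cpp_maxpool3d_bw(cb$argmax[[s]], dy, cb$conv_dims)
      bw <- cpp_conv3d_bw(cb$x_in[[s]], state$conv[[i]]$W, blk$pad, dconv,
                          i > 1L)  # no input gradient needed at the data
      dW <- dW + bw$dw
      db <- db + bw$db
      dxs_new[[s]] <- bw$dx
    }
    grads$conv[[i]] <- list(W = dW, b = db)
    dxs <- dxs_new
  }
  grads
}

# --- flat parameter plumbing (optimizer + gradient checks) -------------------

# Trainable parameters as one named numeric vector, in a fixed order:
# conv W/b, bn gamma/beta per block, then dense W/b. Running stats excluded.
net_flatten <- function(state, grads = NULL) {
  src <- grads %||% state
  out <- list()
  for (i in seq_along(state$conv)) {
    out[[sprintf("conv%d.W", i)]] <- as.numeric(src$conv[[i]]$W)
    out[[sprintf("conv%d.b", i)]] <- as.numeric(src$conv[[i]]$b)
  }
  for (i in seq_along(state$bn)) {
    out[[sprintf("bn%d.gamma", i)]] <- as.numeric(src$bn[[i]]$gamma)
    out[[sprintf("bn%d.beta", i)]] <- as.numeric(src$bn[[i]]$beta)
  }
  for (j in seq_along(state$dense)) {
    out[[sprintf("dense%d.W", j)]] <- as.numeric(src$dense[[j]]$W)
    out[[sprintf("dense%d.b", j)]] <- as.numeric(src$dense[[j]]$b)
  }
  unlist(out)
}

net_unflatten <- function(state, vec) {
  pos <- 0L
  take <- function(n) {
    v <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  for (i in seq_along(state$conv)) {
    state$conv[[i]]$W <- array(take(length(state$conv[[i]]$W)),
                               dim = dim(state$conv[[i]]$W))
    state$conv[[i]]$b <- take(length(state$conv[[i]]$b))
  }
  for (i in seq_along(state$bn)) {
    state$bn[[i]]$gamma <- take(length(state$bn[[i]]$gamma))
    state$bn[[i]]$beta <- take(length(state$bn[[i]]$beta))
  }
  for (j in seq_along(state$dense)) {
    state$dense[[j]]$W <- matrix(take(length(state$dense[[j]]$W)),
                                 nrow(state$dense[[j]]$W), ncol(state$dense[[j]]$W))
    state$dense[[j]]$b <- take(length(state$dense[[j]]$b))
  }
  state
}
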