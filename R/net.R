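# The compact 3D CNN: six convolution -> max-pool -> batch-norm -> ReLU
# blocks, global average pooling, a dense layer of 8 with dropout, a final
# dense neuron, sigmoid. The default block table is, per block:
#   zero pad   (1,1,1) (1,1,1) (1,1,1) (2,1,1) (1,1,1) (1,1,1)
#   filters     4       4       8       8       4       4
#   kernel     (3,2,2) (2,2,2) (3,3,3) (3,2,2) (3,3,3) (3,3,3)
#   max pool   (3,3,3) (2,2,2) (2,2,2) (2,2,2) (2,2,2) (2,2,2)
# Convolutions use stride 1 with symmetric zero padding; pooling is
# non-overlapping with ceil-mode windows (a partial window at the border is
# pooled), the convention under which the chain reduces both the full
# 165 x 176 x 176 grid and coarser experimental grids cleanly.

#' Default convolutional block table
#' @return List of 6 block descriptions (`pad`, `filters`, `kernel`, `pool`).
#' @export
default_blocks <- function() {
  list(
    list(pad = c(1L, 1L, 1L), filters = 4L, kernel = c(3L, 2L, 2L), pool = c(3L, 3L, 3L)),
    list(pad = c(1L, 1L, 1L), filters = 4L, kernel = c(2L, 2L, 2L), pool = c(2L, 2L, 2L)),
    list(pad = c(1L, 1L, 1L), filters = 8L, kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L)),
    list(pad = c(2L, 1L, 1L), filters = 8L, kernel = c(3L, 2L, 2L), pool = c(2L, 2L, 2L)),
    list(pad = c(1L, 1L, 1L), filters = 4L, kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L)),
    list(pad = c(1L, 1L, 1L), filters = 4L, kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L))
  )
}

#' Describe a network architecture
#'
#' @param input_channels 3 for the full 3-channel input, 1 for mask-only.
#' @param blocks convolutional block table; see [default_blocks()].
#' @param dense widths of the fully connected layers (final width must be 1).
#' @param dropout dropout fraction applied between the two dense layers
#'   during training.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_channels = 3L, blocks = default_blocks(),
                         dense = c(8L, 1L), dropout = 0.1) {
  stopifnot(input_channels >= 1L, dropout >= 0, dropout < 1)
  if (dense[length(dense)] != 1L)
    abort("input_error", "final dense layer must have 1 neuron (sigmoid output)")
  for (b in blocks) {
    stopifnot(length(b$pad) == 3L, length(b$kernel) == 3L, length(b$pool) == 3L,
              b$filters >= 1L)
  }
  structure(list(input_channels = as.integer(input_channels), blocks = blocks,
                 dense = as.integer(dense), dropout = dropout),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d channel(s), %d conv blocks, dense %s, dropout %.2f\n",
              x$input_channels, length(x$blocks),
              paste(x$dense, collapse = "-"), x$dropout))
  invisible(x)
}

# Spatial dimensions through the conv/pool chain; errors if a convolution
# output dimension would be < 1.
net_output_shape <- function(spec, input_shape) {
  s <- as.integer(input_shape[1:3])
  for (b in spec$blocks) {
    s <- s + 2L * b$pad - b$kernel + 1L
    if (any(s < 1L))
      abort("shape_error",
            sprintf("convolution output dimension < 1 (got %s)", paste(s, collapse = "x")))
    s <- as.integer(ceiling(s / b$pool))
  }
  s
}

#' Build (initialize) a network
#'
#' Weights are drawn uniformly with fan-in scaling (limit `sqrt(3 / fan_in)`),
#' biases start at zero, batch-norm at identity (scale 1, shift 0, running
#' mean 0, running variance 1). Initialization is deterministic under `seed`.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the initial weights.
#' @return Object of class `brachy_net` holding all parameters.
#' @export
build_network <- function(spec, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  conv <- list(); bn <- list()
  cin <- spec$input_channels
  for (b in spec$blocks) {
    k <- b$kernel
    fan_in <- prod(k) * cin
    lim <- sqrt(3 / fan_in)
    W <- array(runif(prod(k) * cin * b$filters, -lim, lim),
               dim = c(k, cin, b$filters))
    conv[[length(conv) + 1L]] <- list(W = W, b = numeric(b$filters))
    bn[[length(bn) + 1L]] <- list(gamma = rep(1, b$filters),
                                  beta = numeric(b$filters),
                                  rmean = numeric(b$filters),
                                  rvar = rep(1, b$filters))
    cin <- b$filters
  }
  dense <- list()
  din <- cin
  for (w in spec$dense) {
    lim <- sqrt(3 / din)
    dense[[length(dense) + 1L]] <- list(W = matrix(runif(din * w, -lim, lim), din, w),
                                        b = numeric(w))
    din <- w
  }
  structure(list(spec = spec, conv = conv, bn = bn, dense = dense),
            class = "brachy_net")
}

# restore-the-RNG helper so building a network does not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

#' Count network parameters
#'
#' Counts every convolution kernel weight and bias, every dense weight and
#' bias, and four values per batch-normalized channel (scale, shift, running
#' mean, running variance). Under this convention the default 3-channel
#' architecture has 3409 parameters and the 1-channel mask-only variant 3313.
#'
#' @param state a `brachy_net`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(state) {
  n <- 0L
  for (cv in state$conv) n <- n + length(cv$W) + length(cv$b)
  for (b in state$bn) n <- n + 4L * length(b$gamma)
  for (d in state$dense) n <- n + length(d$W) + length(d$b)
  as.integer(n)
}

#' @export
print.brachy_net <- function(x, ...) {
  cat(sprintf("<brachy_net> %d conv blocks, dense %s, %d parameters\n",
              length(x$conv), paste(x$spec$dense, collapse = "-"),
              count_parameters(x)))
  invisible(x)
}

bn_eps <- 1e-5

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(z) 1 / (1 + exp(-z))

# Batched forward pass. `xs` is a list of (D,H,W,C) arrays sharing a shape.
# In training mode batch-norm uses batch statistics (updated into the running
# estimates when `update_running`) and dropout masks are drawn from the
# current RNG. Returns scores and, when `keep_cache`, everything the backward
# pass needs.
net_forward_batch <- function(state, xs, training = FALSE,
                              update_running = training, keep_cache = FALSE,
                              bn_momentum = 0.1) {
  spec <- state$spec
  nb <- length(spec$blocks)
  n <- length(xs)
  cache <- if (keep_cache) list(blocks = vector("list", nb)) else NULL
  for (i in seq_len(nb)) {
    blk <- spec$blocks[[i]]
    cv <- state$conv[[i]]
    x_in <- xs
    zs <- lapply(xs, function(x) cpp_conv3d_fw(x, cv$W, cv$b, blk$pad))
    pooled <- lapply(zs, function(z) cpp_maxpool3d_fw(z, blk$pool))
    ys <- lapply(pooled, `[[`, "y")
    dims <- dim(ys[[1]])
    C <- dims[4]; V <- prod(dims[1:3])
    A <- do.call(rbind, lapply(ys, function(y) { dim(y) <- c(V, C); y }))
    bnp <- state$bn[[i]]
    if (training) {
      mu <- colMeans(A)
      va <- colMeans(A * A) - mu^2
      va[va < 0] <- 0
      if (update_running) {
        state$bn[[i]]$rmean <- (1 - bn_momentum) * bnp$rmean + bn_momentum * mu
        state$bn[[i]]$rvar <- (1 - bn_momentum) * bnp$rvar + bn_momentum * va
      }
    } else {
      mu <- bnp$rmean
      va <- bnp$rvar
    }
    istd <- 1 / sqrt(va + bn_eps)
    xhat <- sweep(sweep(A, 2, mu, "-"), 2, istd, "*")
    act <- relu(sweep(sweep(xhat, 2, bnp$gamma, "*"), 2, bnp$beta, "+"))
    xs <- lapply(seq_len(n), function(s) {
      a <- act[((s - 1) * V + 1):(s * V), , drop = FALSE]
      dim(a) <- dims
      a
    })
    if (keep_cache) {
      cache$blocks[[i]] <- list(
        x_in = x_in, conv_dims = dim(zs[[1]]),
        argmax = lapply(pooled, `[[`, "argmax"),
        pool_dims = dims, xhat = xhat, istd = istd, act = act)
    }
  }
  # global average pooling
  dims <- dim(xs[[1]])
  C <- dims[4]; V <- prod(dims[1:3])
  H <- do.call(rbind, lapply(xs, function(x) { dim(x) <- c(V, C); colMeans(x) }))
  if (keep_cache) { cache$gap_dims <- dims; cache$H0 <- H }
  nd <- length(state$dense)
  dense_cache <- vector("list", nd)
  drop_mask <- NULL
  for (j in seq_len(nd)) {
    dp <- state$dense[[j]]
    if (j == nd && nd > 1L && training && spec$dropout > 0) {
      drop_mask <- matrix(runif(length(H)) >= spec$dropout, nrow(H), ncol(H))
      H <- H * drop_mask / (1 - spec$dropout)
    }
    if (keep_cache) dense_cache[[j]] <- list(inp = H)
    Z <- H %*% dp$W + matrix(dp$b, n, length(dp$b), byrow = TRUE)
    H <- if (j < nd) relu(Z) else Z
    if (keep_cache) dense_cache[[j]]$out <- H
  }
  p <- as.numeric(sigmoid(H))
  if (keep_cache) {
    cache$dense <- dense_cache
    cache$drop_mask <- drop_mask
    cache$n <- n
  }
  list(p = p, cache = cache, state = state)
}

#' Run the network on one prepared input
#'
#' Inference is deterministic: dropout is inactive and batch normalization
#' uses its running statistics. The output is the sigmoid suitability score,
#' strictly inside (0, 1).
#'
#' @param state a `brachy_net`.
#' @param input a `model_input` or a `(nz, ny, nx, channels)` array.
#' @return Suitability score `p` in (0, 1): the predicted probability that a
#'   Syed applicator is needed.
#' @export
net_forward <- function(state, input) {
  x <- if (inherits(input, "model_input")) input$x else input
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[4] != state$spec$input_channels)
    abort("shape_error", sprintf("input has %d channel(s), network expects %d",
                                 dim(x)[4], state$spec$input_channels))
  net_output_shape(state$spec, dim(x)[1:3])
  net_forward_batch(state, list(x), training = FALSE)$p
}

#' Map a suitability score to an applicator recommendation
#'
#' `"SYED"` iff the score is greater than or equal to the threshold
#' (default 0.5), `"TANDO"` otherwise.
#'
#' @param p numeric vector of scores in `[0, 1]`.
#' @param threshold decision threshold.
#' @return Character vector of `"SYED"` / `"TANDO"`.
#' @export
classify_score <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p >= threshold, "SYED", "TANDO")
}

#' Predict applicator suitability for prepared inputs
#'
#' @param object a `brachy_net`.
#' @param inputs a `model_input` or list of them.
#' @param threshold decision threshold for the label.
#' @param ... unused.
#' @return data.frame with `score` and `label` per input.
#' @export
predict.brachy_net <- function(object, inputs, threshold = 0.5, ...) {
  if (inherits(inputs, "model_input") || is.array(inputs)) inputs <- list(inputs)
  p <- vapply(inputs, function(ip) net_forward(object, ip), numeric(1))
  data.frame(score = p, label = classify_score(p, threshold))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single-file archive holding the architecture spec and
#' all parameters.
#' @param state a `brachy_net`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `brachy_net` (load).
#' @export
save_network <- function(state, path) { saveRDS(state, path); invisible(path) }

#' @rdname save_network
#' @export
load_network <- function(path) readRDS(path)
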