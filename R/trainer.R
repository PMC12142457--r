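# Training: binary cross-entropy + L1 loss, class-balanced patient-level
# batch sampling, anatomically constrained rigid augmentation, staircase
# learning-rate decay, Adam, and grouped (patient-level) k-fold
# cross-validation.

#' Training configuration
#'
#' Defaults are the published training scheme: L1 weight 0.03, learning rate
#' 0.001 decaying by 0.93 every 200 batches (staircase), dropout 10%,
#' 400 epochs of 40 batches of 8 samples, augmentation probability 0.75 with
#' a conditional left-right flip probability of 0.5, rotations up to 10
#' degrees about the superior-inferior axis. The translation bound (not part
#' of the published scheme) defaults to 10 mm per axis.
#'
#' @param lambda_l1 L1 regularization weight.
#' @param lr0,lr_decay,decay_every staircase learning-rate schedule.
#' @param dropout dropout fraction between the dense layers.
#' @param epochs,batch_size,batches_per_epoch training length.
#' @param augment logical; apply rigid augmentation.
#' @param augment_prob probability a sample is augmented at all.
#' @param flip_prob probability of a left-right flip, conditional on the
#'   sample having been augmented (overall flip rate `augment_prob * flip_prob`).
#' @param max_rotation_deg rotation bound about the SI axis, degrees.
#' @param max_translation_mm translation bound per axis, mm.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed integer; controls initialization, sampling, augmentation and
#'   dropout.
#' @return Object of class `training_config`.
#' @export
training_config <- function(lambda_l1 = 0.03, lr0 = 0.001, lr_decay = 0.93,
                            decay_every = 200L, dropout = 0.10, epochs = 400L,
                            batch_size = 8L, batches_per_epoch = 40L,
                            augment = TRUE, augment_prob = 0.75,
                            flip_prob = 0.5, max_rotation_deg = 10,
                            max_translation_mm = 10, optimizer = c("adam", "sgd"),
                            seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lambda_l1 >= 0, lr0 > 0, lr_decay > 0, lr_decay <= 1,
            decay_every >= 1, dropout >= 0, dropout < 1, batch_size > 0,
            augment_prob >= 0, augment_prob <= 1, flip_prob >= 0, flip_prob <= 1)
  structure(list(lambda_l1 = lambda_l1, lr0 = lr0, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), dropout = dropout,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 augment = augment, augment_prob = augment_prob,
                 flip_prob = flip_prob, max_rotation_deg = max_rotation_deg,
                 max_translation_mm = max_translation_mm, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Training configuration for the downscaled recovery experiment
#'
#' The published schedule (400 epochs x 40 batches, L1 weight 0.03) was tuned
#' for a 372-insertion clinical cohort at full 2 mm resolution on a GPU. For
#' the synthetic recovery experiment — 120 insertions on a 48^3 grid at 3 mm,
#' one CPU — the same heuristic tuning led to a lighter schedule: L1 weight
#' 0.003, learning rate 0.002 with the same 0.93/200-batch staircase, and
#' 60 epochs of 20 batches of 8. All other settings keep their defaults.
#'
#' @param seed integer seed.
#' @return A [training_config()].
#' @export
downscale_config <- function(seed = 1L) {
  training_config(lambda_l1 = 0.003, lr0 = 0.002, epochs = 60L,
                  batches_per_epoch = 20L, seed = seed)
}

#' Binary cross-entropy with L1 weight regularization
#'
#' `-(1/N) sum(y log p + (1 - y) log(1 - p)) + lambda * sum(|W_j|)`.
#' Scores at exactly 0 or 1 are clamped to machine epsilon with a warning.
#'
#' @param p predicted suitability scores.
#' @param y true labels (1 Syed, 0 T&O).
#' @param weights network parameters entering the L1 term (vector or nested
#'   list; flattened).
#' @param lambda L1 weight.
#' @return The scalar loss.
#' @export
bce_l1_loss <- function(p, y, weights = numeric(0), lambda = 0) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  eps <- .Machine$double.eps
  if (any(p <= 0 | p >= 1)) {
    if (any(p < 0 | p > 1)) abort("input_error", "scores must lie in [0, 1]")
    warn_log("scores at 0 or 1 clamped to machine epsilon")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  bce + lambda * sum(abs(unlist(weights)))
}

#' Staircase learning rate
#'
#' `lr0 * lr_decay ^ floor(step / decay_every)`; `step` is the 0-based batch
#' index.
#' @param step batch index (0-based).
#' @param config a [training_config()].
#' @return Learning rate at `step`.
#' @export
lr_at <- function(step, config) {
  stopifnot(step >= 0)
  config$lr0 * config$lr_decay^floor(step / config$decay_every)
}

# Patient class: majority vote over the patient's insertion labels
# (ties count as Syed, the minority class clinically).
patient_classes <- function(records) {
  pid <- vapply(records, `[[`, character(1), "patient_id")
  y <- vapply(records, `[[`, numeric(1), "y")
  vapply(split(y, pid), function(v) as.numeric(mean(v) >= 0.5), numeric(1))
}

#' Class-balanced patient-level batch sampling
#'
#' Each batch slot independently draws the class with probability 0.5, then a
#' uniform patient of that class, then a uniform insertion of that patient.
#' Expected class frequency in batches is 0.5 regardless of the cohort's
#' insertion-level imbalance.
#'
#' @param records list of insertion records (each with `patient_id` and `y`).
#' @param n batch size.
#' @return List of `n` records (sampled with replacement).
#' @export
sample_batch <- function(records, n) {
  pcls <- patient_classes(records)
  syed_pat <- names(pcls)[pcls == 1]
  tando_pat <- names(pcls)[pcls == 0]
  if (!length(syed_pat) || !length(tando_pat))
    abort("class_missing", "both applicator classes need at least one patient")
  pid <- vapply(records, `[[`, character(1), "patient_id")
  by_pat <- split(seq_along(records), pid)
  cls <- runif(n) < 0.5
  idx <- vapply(cls, function(is_syed) {
    pool <- if (is_syed) syed_pat else tando_pat
    pat <- pool[sample.int(length(pool), 1L)]
    ins <- by_pat[[pat]]
    ins[sample.int(length(ins), 1L)]
  }, integer(1))
  records[idx]
}

#' Rigid training augmentation
#'
#' With probability `1 - augment_prob` the input is returned unchanged.
#' Otherwise it undergoes, with equal probability, either a translation
#' (uniform within `max_translation_mm` per axis) or a rotation about the
#' superior-inferior axis (uniform within `max_rotation_deg`), followed by an
#' independent left-right flip with probability `flip_prob`. All channels are
#' transported rigidly by nearest-neighbor resampling: label codes stay
#' categorical and distance values move with their voxels unchanged (rigid
#' motion of anatomy and tandem together leaves axis distances invariant).
#' No deformation is ever applied.
#'
#' @param input a `model_input` or a `(nz, ny, nx, c)` array carrying a
#'   `spacing` attribute (mm per voxel, z/y/x).
#' @param config a [training_config()].
#' @return Augmented object of the same type.
#' @export
augment_input <- function(input, config = training_config()) {
  x <- if (inherits(input, "model_input")) input$x else input
  spacing <- attr(x, "spacing") %||% c(2, 2, 2)
  augmented <- runif(1) < config$augment_prob
  flipped <- FALSE
  if (augmented) {
    theta <- 0
    shift <- c(0, 0, 0)
    if (runif(1) < 0.5) {
      shift <- runif(3, -config$max_translation_mm, config$max_translation_mm) / spacing
    } else {
      theta <- runif(1, -config$max_rotation_deg, config$max_rotation_deg) * pi / 180
    }
    x2 <- cpp_rigid_nn(x, c(sin(theta), cos(theta)), shift, 0)
    flipped <- runif(1) < config$flip_prob
    if (flipped) {
      nx <- dim(x2)[3]
      x2 <- x2[, , nx:1, , drop = FALSE]
    }
    attr(x2, "spacing") <- spacing
    x <- x2
  }
  attr(x, "augmented") <- augmented
  attr(x, "flipped") <- flipped
  if (inherits(input, "model_input")) {
    input$x <- x
    input
  } else {
    x
  }
}

#' Patient-level fold assignment
#'
#' Partitions patients (never insertions) into `k` folds, stratified by
#' patient class so each fold sees a similar class mix; fold patient counts
#' differ by at most one.
#'
#' @param records list of insertion records, or a data.frame with
#'   `patient_id` and `y` columns.
#' @param k number of folds.
#' @return Named integer vector `patient_id -> fold` in `1..k`.
#' @export
make_folds <- function(records, k = 5L) {
  if (is.data.frame(records)) {
    pcls <- vapply(split(records$y, records$patient_id),
                   function(v) as.numeric(mean(v) >= 0.5), numeric(1))
  } else {
    pcls <- patient_classes(records)
  }
  if (length(pcls) < k)
    abort("fold_error", sprintf("%d patients cannot fill %d folds", length(pcls), k))
  fold <- setNames(integer(length(pcls)), names(pcls))
  cls_count <- matrix(0L, k, 2)
  for (cl in c(1, 0)) {
    pats <- sample(names(pcls)[pcls == cl])
    for (p in pats) {
      tot <- rowSums(cls_count)
      ccol <- cl + 1L
      cand <- which(cls_count[, ccol] == min(cls_count[, ccol]))
      cand <- cand[tot[cand] == min(tot[cand])]
      f <- cand[sample.int(length(cand), 1L)]
      fold[p] <- f
      cls_count[f, ccol] <- cls_count[f, ccol] + 1L
    }
  }
  fold
}

# One optimization step's loss and gradients for a batch. Returns the state
# with updated batch-norm running statistics.
net_loss_grad <- function(state, xs, ys, lambda, training = TRUE,
                          update_running = training) {
  fw <- net_forward_batch(state, xs, training = training,
                          update_running = update_running, keep_cache = TRUE)
  state <- fw$state
  p <- fw$p
  wvec <- net_flatten(state)
  loss <- bce_l1_loss(pmin(pmax(p, 1e-12), 1 - 1e-12), ys, wvec, lambda)
  dzn <- (p - ys) / length(ys)
  grads <- net_backward(state, fw$cache, dzn)
  gvec <- net_flatten(state, grads) + lambda * sign(wvec)
  list(loss = loss, p = p, grad = gvec, state = state)
}

#' Train the network
#'
#' Runs `epochs * batches_per_epoch` optimization steps of balanced sampling,
#' augmentation, the BCE + L1 loss and the staircase learning rate, with Adam
#' (default) or plain SGD. Fully reproducible under `config$seed`.
#'
#' @param records list of insertion records: each
#'   `list(patient_id =, insertion_id =, x = <(nz,ny,nx,c) array>, y = 0/1)`.
#' @param spec a [network_spec()]; defaults to the standard architecture with
#'   the records' channel count.
#' @param config a [training_config()].
#' @param verbose print per-epoch progress.
#' @return list with the trained `state` and a per-epoch `history`
#'   data.frame (training loss and accuracy).
#' @export
train_network <- function(records, spec = NULL, config = training_config(),
                          verbose = FALSE) {
  y_all <- vapply(records, `[[`, numeric(1), "y")
  if (length(unique(y_all)) < 2L)
    abort("class_missing", "training set must contain both classes")
  nch <- dim(records[[1]]$x)[4]
  if (is.null(spec)) spec <- network_spec(input_channels = nch)
  state <- build_network(spec, seed = config$seed)
  state$spec$dropout <- config$dropout
  net_output_shape(spec, dim(records[[1]]$x)[1:3])
  set.seed(config$seed + 1L)
  theta <- net_flatten(state)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ep_loss <- ep_acc <- numeric(config$batches_per_epoch)
    for (bt in seq_len(config$batches_per_epoch)) {
      batch <- sample_batch(records, config$batch_size)
      xs <- lapply(batch, function(r) {
        if (config$augment) augment_input(r$x, config) else r$x
      })
      ys <- vapply(batch, `[[`, numeric(1), "y")
      fg <- net_loss_grad(state, xs, ys, config$lambda_l1)
      state <- fg$state
      if (!is.finite(fg$loss))
        abort("training_diverged", sprintf("non-finite loss at epoch %d", ep))
      lr <- lr_at(step, config)
      theta <- net_flatten(state)
      if (config$optimizer == "adam") {
        m <- b1 * m + (1 - b1) * fg$grad
        v <- b2 * v + (1 - b2) * fg$grad^2
        t_ <- step + 1
        mhat <- m / (1 - b1^t_)
        vhat <- v / (1 - b2^t_)
        theta <- theta - lr * mhat / (sqrt(vhat) + aeps)
      } else {
        theta <- theta - lr * fg$grad
      }
      state <- net_unflatten(state, theta)
      step <- step + 1L
      ep_loss[bt] <- fg$loss
      ep_acc[bt] <- mean((fg$p >= 0.5) == (ys == 1))
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(ep_loss),
                                         accuracy = mean(ep_acc)))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, mean(ep_loss), mean(ep_acc)))
  }
  list(state = state, history = history)
}

#' Score a set of insertion records with a trained network
#'
#' @param state a trained `brachy_net`.
#' @param records list of insertion records.
#' @param threshold decision threshold.
#' @return list with `scores` (per-insertion data.frame) and overall
#'   per-insertion `accuracy`.
#' @export
evaluate_network <- function(state, records, threshold = 0.5) {
  p <- vapply(records, function(r) net_forward(state, r$x), numeric(1))
  y <- vapply(records, `[[`, numeric(1), "y")
  df <- data.frame(
    patient_id = vapply(records, `[[`, character(1), "patient_id"),
    insertion_id = vapply(records, `[[`, character(1), "insertion_id"),
    y = y, score = p, label = classify_score(p, threshold))
  list(scores = df, accuracy = mean((p >= threshold) == (y == 1)),
       loss = bce_l1_loss(pmin(pmax(p, 1e-12), 1 - 1e-12), y))
}

#' Summarize per-fold accuracies
#'
#' Mean and sample standard deviation, the convention used for reporting
#' cross-validation accuracy.
#' @param values numeric vector of per-fold values.
#' @return Named vector `c(mean =, sd =)`.
#' @export
fold_summary <- function(values) c(mean = mean(values), sd = sd(values))

#' Grouped k-fold cross-validation of the network
#'
#' Patient-level folds: no validation insertion's patient ever appears in its
#' fold's training set (asserted on every run). Validation accuracy is
#' defined per insertion.
#'
#' @inheritParams train_network
#' @param k number of folds (ignored when `folds` is given).
#' @param folds optional precomputed assignment from [make_folds()].
#' @param verbose print progress.
#' @return list with per-fold metrics (`folds` data.frame), the pooled
#'   per-insertion validation `scores`, and `summary` (mean/sd validation
#'   accuracy).
#' @export
cross_validate <- function(records, spec = NULL, config = training_config(),
                           k = 5L, folds = NULL, verbose = FALSE) {
  set.seed(config$seed)
  if (is.null(folds)) folds <- make_folds(records, k = k)
  k <- max(folds)
  pid <- vapply(records, `[[`, character(1), "patient_id")
  res <- NULL
  scores <- NULL
  for (f in seq_len(k)) {
    val_idx <- which(folds[pid] == f)
    train_idx <- setdiff(seq_along(records), val_idx)
    stopifnot(length(intersect(pid[train_idx], pid[val_idx])) == 0L)
    if (verbose) message(sprintf("fold %d/%d: %d train / %d validation insertions",
                                 f, k, length(train_idx), length(val_idx)))
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_network(records[train_idx], spec = spec, config = cfg)
    ev <- evaluate_network(fit$state, records[val_idx])
    last <- tail_row(fit$history)
    res <- rbind(res, data.frame(fold = f, train_loss = last$loss,
                                 train_accuracy = last$accuracy,
                                 val_loss = ev$loss, val_accuracy = ev$accuracy))
    scores <- rbind(scores, cbind(ev$scores, fold = f))
  }
  list(folds = res, scores = scores, summary = fold_summary(res$val_accuracy))
}

tail_row <- function(df) df[nrow(df), , drop = FALSE]
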