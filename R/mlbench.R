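# Classical-ML benchmark: ANOVA-F feature ranking, SMOTE oversampling of the
# minority class, four classifier families (SVM, random forest, k-nearest
# neighbors, decision tree) tuned by grid search with grouped-free 5-fold CV
# on the balanced training set, aggregated by a soft-voting ensemble.

#' Rank features by one-way ANOVA F-score
#'
#' `F = (between-class variance / (g - 1)) / (within-class variance / (n - g))`
#' per feature; features are returned in descending F order. Constant
#' features get `F = 0` with a warning.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels (two or more classes, each with >= 2 samples).
#' @return list with `order` (column indices, best first) and `f_scores`.
#' @export
rank_features <- function(X, y) {
  X <- as.matrix(X)
  g <- unique(y)
  if (length(g) < 2L) abort("class_missing", "need at least two classes")
  n <- nrow(X)
  f <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    gm <- tapply(xj, y, mean)
    gn <- tapply(xj, y, length)
    grand <- mean(xj)
    ssb <- sum(gn * (gm - grand)^2)
    ssw <- sum((xj - gm[as.character(y)])^2)
    if (ssw == 0 && ssb == 0) return(NA_real_)
    if (ssw == 0) return(Inf)
    (ssb / (length(g) - 1)) / (ssw / (n - length(g)))
  }, numeric(1))
  if (anyNA(f)) {
    warn_log(sprintf("%d constant feature(s) ranked last with F = 0", sum(is.na(f))))
    f[is.na(f)] <- 0
  }
  list(order = order(f, decreasing = TRUE), f_scores = f)
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority samples are convex combinations
#' `x + u * (neighbor - x)`, `u ~ U(0, 1)`, with the neighbor drawn among the
#' `k` nearest minority samples of `x`. Classes are exactly balanced on
#' return.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param k number of nearest neighbors (capped at minority size - 1).
#' @return list with balanced `X` and `y`.
#' @export
smote_oversample <- function(X, y, k = 5L) {
  X <- as.matrix(X)
  tab <- table(y)
  if (length(tab) != 2L) abort("class_missing", "SMOTE needs exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < 2L) abort("smote_error", "minority class needs >= 2 samples")
  if (n_min == n_maj) return(list(X = X, y = y))
  Xm <- X[y == minority, , drop = FALSE]
  k <- min(k, n_min - 1L)
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  n_new <- n_maj - n_min
  base <- sample.int(n_min, n_new, replace = TRUE)
  picked <- vapply(base, function(b) nn[b, sample.int(k, 1L)], integer(1))
  u <- runif(n_new)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[picked, , drop = FALSE] - Xm[base, , drop = FALSE])
  yv <- if (is.factor(y)) as.character(y) else y
  list(X = rbind(X, synth),
       y = c(yv, rep(if (is.numeric(y)) as.numeric(minority) else minority, n_new)))
}

# --- the four classifier families -------------------------------------------

# Each family: fit(X, y01, par) -> model; prob(model, X) -> P(Syed).
ml_families <- function() {
  list(
    svm = list(
      grid = expand.grid(cost = c(0.1, 1, 10), gamma_scale = c(0.5, 1, 2)),
      fit = function(X, y, par) {
        e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = par$cost, gamma = par$gamma_scale / ncol(X),
                   probability = TRUE)
      },
      prob = function(fit, X) {
        pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
        unname(pr[, "1"])
      }),
    rf = list(
      grid = expand.grid(mtry = c(1, 2, 3)),
      fit = function(X, y, par) {
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = 300, mtry = min(par$mtry, ncol(X)))
      },
      prob = function(fit, X) unname(predict(fit, X, type = "prob")[, "1"])),
    knn = list(
      grid = expand.grid(k = c(3, 5, 7)),
      fit = function(X, y, par) list(X = X, y = factor(y, levels = c(0, 1)), k = par$k),
      prob = function(fit, X) {
        pred <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == "1", pr, 1 - pr)
      }),
    dt = list(
      grid = expand.grid(cp = c(0.001, 0.01, 0.1)),
      fit = function(X, y, par) {
        df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
        rpart::rpart(.y ~ ., df, method = "class",
                     control = rpart::rpart.control(cp = par$cp, minsplit = 5))
      },
      prob = function(fit, X) unname(predict(fit, data.frame(X), type = "prob")[, "1"]))
  )
}

# plain k-fold CV accuracy of one (family, parameter) combination
cv_accuracy <- function(fam, X, y, par, k = 5L) {
  n <- nrow(X)
  fold <- sample(rep(seq_len(k), length.out = n))
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    fit <- fam$fit(X[tr, , drop = FALSE], y[tr], par)
    p <- fam$prob(fit, X[!tr, , drop = FALSE])
    mean((p >= 0.5) == (y[!tr] == 1))
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

#' Soft-voting ensemble of per-model Syed probabilities
#'
#' The ensemble score is the mean of the per-model probabilities; SYED is
#' recommended iff the mean is >= 0.5.
#'
#' @param prob_matrix samples x models matrix of Syed probabilities.
#' @param threshold decision threshold on the mean.
#' @return list with `score` (mean per sample) and `label`.
#' @export
soft_vote <- function(prob_matrix, threshold = 0.5) {
  score <- rowMeans(as.matrix(prob_matrix))
  list(score = score, label = classify_score(score, threshold))
}

#' Handcrafted-feature classifier benchmark
#'
#' Ranks the training features by ANOVA F, keeps the `n_top` best,
#' standardizes them (training mean/sd), balances the training classes with
#' SMOTE, tunes each of the four families by grid search with `cv_k`-fold
#' cross-validation (SMOTE re-applied inside each fold), refits the winners
#' on the full balanced training set, and soft-votes their test
#' probabilities.
#'
#' @param train_x,train_y training features (data.frame or matrix over the
#'   20-feature schema, or any numeric columns) and binary labels.
#' @param test_x test features with the same columns.
#' @param n_top number of top-ranked features to keep (1..ncol).
#' @param cv_k folds for the hyperparameter grid search.
#' @return list: `prob` (test samples x 4 model probabilities), `vote`
#'   (soft-vote score and label), `selected` (feature names kept),
#'   `tuning` (chosen parameters per family).
#' @export
ml_benchmark <- function(train_x, train_y, test_x, n_top = 8L, cv_k = 5L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (length(unique(train_y)) < 2L)
    abort("class_missing", "training labels contain a single class")
  stopifnot(n_top >= 1L, n_top <= ncol(train_x))
  rk <- rank_features(train_x, train_y)
  keep <- rk$order[seq_len(n_top)]
  mu <- colMeans(train_x[, keep, drop = FALSE])
  sg <- apply(train_x[, keep, drop = FALSE], 2, sd)
  sg[sg == 0] <- 1
  scale_mat <- function(M) sweep(sweep(M[, keep, drop = FALSE], 2, mu, "-"), 2, sg, "/")
  Xtr <- scale_mat(train_x); Xte <- scale_mat(test_x)
  fams <- ml_families()
  tuning <- list()
  probs <- matrix(NA_real_, nrow(Xte), length(fams),
                  dimnames = list(NULL, names(fams)))
  for (nm in names(fams)) {
    fam <- fams[[nm]]
    accs <- vapply(seq_len(nrow(fam$grid)), function(i) {
      # SMOTE inside the CV folds would leak synthetic copies across folds
      # if applied first; so each fold's training part is balanced on its own
      n <- nrow(Xtr)
      fold <- sample(rep(seq_len(cv_k), length.out = n))
      a <- vapply(seq_len(cv_k), function(f) {
        tr <- fold != f
        ytr <- train_y[tr]
        if (length(unique(ytr)) < 2L || min(table(ytr)) < 2L) return(NA_real_)
        sm <- smote_oversample(Xtr[tr, , drop = FALSE], ytr)
        fit <- fam$fit(sm$X, sm$y, fam$grid[i, , drop = FALSE])
        p <- fam$prob(fit, Xtr[!tr, , drop = FALSE])
        mean((p >= 0.5) == (train_y[!tr] == 1))
      }, numeric(1))
      mean(a, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(accs))) abort("fit_error", sprintf("no valid %s fit in the grid", nm))
    best <- fam$grid[which.max(accs), , drop = FALSE]
    tuning[[nm]] <- best
    sm <- smote_oversample(Xtr, train_y)
    fit <- fam$fit(sm$X, sm$y, best)
    probs[, nm] <- fam$prob(fit, Xte)
  }
  list(prob = probs, vote = soft_vote(probs),
       selected = colnames(train_x)[keep], tuning = tuning)
}
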