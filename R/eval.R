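# Evaluation: confusion counts with Syed as the positive class, the derived
# sensitivity/specificity/accuracy, decision-threshold sweeping, and the
# paired FULL vs MASK_ONLY ablation harness.

#' Confusion counts (Syed positive)
#'
#' @param pred,truth vectors of labels, `"SYED"`/`"TANDO"` (or 1/0).
#' @return Object of class `confusion_matrix`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(pred, truth) {
  norm <- function(v) {
    if (is.numeric(v)) v <- ifelse(v == 1, "SYED", "TANDO")
    v <- toupper(as.character(v))
    if (!all(v %in% c("SYED", "TANDO")))
      abort("input_error", "labels must be SYED/TANDO (or 1/0)")
    v
  }
  pred <- norm(pred); truth <- norm(truth)
  if (length(pred) != length(truth))
    abort("input_error", "prediction and truth lengths differ")
  structure(list(TP = sum(pred == "SYED" & truth == "SYED"),
                 FP = sum(pred == "SYED" & truth == "TANDO"),
                 TN = sum(pred == "TANDO" & truth == "TANDO"),
                 FN = sum(pred == "TANDO" & truth == "SYED")),
            class = "confusion_matrix")
}

#' Build a confusion matrix from explicit counts
#' @param TP,FP,TN,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity `TP/(TP+FN)` measures how reliably cases that need the
#' invasive Syed applicator are flagged; specificity `TN/(TN+FP)` how
#' reliably unnecessary Syed use is avoided. Metrics with an empty
#' denominator are `NA`, not 0.
#'
#' @param cm a `confusion_matrix`.
#' @return Named vector `c(sensitivity, specificity, accuracy)` as fractions.
#' @export
classification_metrics <- function(cm) {
  dv <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = dv(cm$TP, cm$TP + cm$FN),
    specificity = dv(cm$TN, cm$TN + cm$FP),
    accuracy = dv(cm$TP + cm$TN, cm$TP + cm$FP + cm$TN + cm$FN))
}

#' Accuracy-maximizing decision threshold
#'
#' Sweeps a threshold grid over the scores, returns the full accuracy curve
#' and the argmax threshold; ties are broken toward 0.5.
#'
#' @param scores numeric suitability scores.
#' @param truth true labels (`"SYED"`/`"TANDO"` or 1/0).
#' @param thresholds candidate grid.
#' @return list with `best` (threshold), `accuracy` (at `best`), and the
#'   full `curve` data.frame.
#' @export
threshold_sweep <- function(scores, truth,
                            thresholds = seq(0, 1, by = 0.001)) {
  y <- if (is.numeric(truth)) truth else as.numeric(toupper(truth) == "SYED")
  if (length(unique(y)) < 2L)
    abort("class_missing", "threshold sweep needs both classes")
  acc <- vapply(thresholds, function(t) mean((scores >= t) == (y == 1)),
                numeric(1))
  best_acc <- max(acc)
  cand <- thresholds[acc == best_acc]
  best <- cand[which.min(abs(cand - 0.5))]
  list(best = best, accuracy = best_acc,
       curve = data.frame(threshold = thresholds, accuracy = acc))
}

#' Paired FULL vs MASK_ONLY ablation
#'
#' Trains and cross-validates the network in both input modes under
#' identical seeds and identical patient-level folds, and reports a paired
#' per-fold metric table (one row per mode x fold plus a summary row per
#' mode).
#'
#' @param records_full,records_mask the same cohort encoded in FULL and
#'   MASK_ONLY modes (insertions in the same order).
#' @param config a [training_config()].
#' @param k number of folds.
#' @return list with `table` (2 x (k + 1) rows) and the two raw
#'   cross-validation results.
#' @export
ablation_run <- function(records_full, records_mask, config = training_config(),
                         k = 3L) {
  stopifnot(length(records_full) == length(records_mask))
  set.seed(config$seed)
  folds <- make_folds(records_full, k = k)
  res <- list()
  for (mode in c("FULL", "MASK_ONLY")) {
    recs <- if (mode == "FULL") records_full else records_mask
    spec <- network_spec(input_channels = dim(recs[[1]]$x)[4])
    res[[mode]] <- cross_validate(recs, spec = spec, config = config,
                                  folds = folds)
  }
  tab <- NULL
  for (mode in names(res)) {
    f <- res[[mode]]$folds
    tab <- rbind(tab,
                 data.frame(mode = mode, fold = as.character(f$fold),
                            val_accuracy = f$val_accuracy),
                 data.frame(mode = mode, fold = "mean",
                            val_accuracy = mean(f$val_accuracy)))
  }
  list(table = tab, full = res$FULL, mask_only = res$MASK_ONLY)
}
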