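#' Confusion matrix over the four AAMI classes
#'
#' Rows are ground truth, columns predictions, both in [aami_classes] order.
#'
#' @param y_true,y_pred Vectors of equal length with values among
#'   [aami_classes] (factors or characters).
#' @return A 4x4 integer matrix of class `hb_confusion`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort(sprintf("y_true has %d elements but y_pred has %d.",
                  length(y_true), length(y_pred)))
  }
  t_f <- factor(as.character(y_true), levels = aami_classes)
  p_f <- factor(as.character(y_pred), levels = aami_classes)
  if (anyNA(t_f) || anyNA(p_f)) {
    abort("labels must be among N, SVEB, VEB, F.")
  }
  m <- unclass(table(truth = t_f, predicted = p_f))
  structure(matrix(as.integer(m), 4, 4,
                   dimnames = list(truth = aami_classes,
                                   predicted = aami_classes)),
            class = c("hb_confusion", "matrix", "array"))
}

as_hb_confusion <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)), all(m >= 0))
  structure(matrix(as.integer(m), 4, 4,
                   dimnames = list(truth = aami_classes,
                                   predicted = aami_classes)),
            class = c("hb_confusion", "matrix", "array"))
}

# round half away from zero (display convention of the result tables)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-class and averaged AAMI metrics from a confusion matrix
#'
#' For each class i: `TP = m[i,i]`, `FP` its column sum minus TP, `FN` its
#' row sum minus TP, `TN` the remainder; `PPV = TP/(TP+FP)`,
#' `SE = TP/(TP+FN)`, one-vs-rest `ACC = (TP+TN)/total` and
#' `F1 = 2*PPV*SE/(PPV+SE)` (defined as 0 when `PPV+SE = 0`). Averages are
#' unweighted means over the four classes; the overall accuracy is the
#' trace over the grand total. The averaged one-vs-rest accuracy and the
#' overall (trace) accuracy are different statistics and are reported as
#' distinct fields.
#'
#' @param m An `hb_confusion` (or any 4x4 count matrix, rows = truth).
#' @return An `hb_metrics` object: list with `per_class` (tibble: `class`,
#'   `ppv_pct`, `se_pct`, `f1_pct`, `acc_pct`), `macro` (one-row tibble of
#'   the four averages), `overall_accuracy_pct`, `n_beats`, `n_correct`.
#'   Values are percentages, unrounded.
#' @export
per_class_metrics <- function(m) {
  if (!inherits(m, "hb_confusion")) m <- as_hb_confusion(m)
  total <- sum(m)
  if (total == 0) abort("confusion matrix is empty (zero total).")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  se <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  acc <- (tp + tn) / total
  f1 <- ifelse(ppv + se > 0, 2 * ppv * se / (ppv + se), 0)
  per_class <- tibble(class = aami_classes,
                      ppv_pct = 100 * unname(ppv), se_pct = 100 * unname(se),
                      f1_pct = 100 * unname(f1), acc_pct = 100 * unname(acc))
  macro <- tibble(ppv_pct = mean(per_class$ppv_pct),
                  se_pct = mean(per_class$se_pct),
                  f1_pct = mean(per_class$f1_pct),
                  acc_pct = mean(per_class$acc_pct))
  structure(list(per_class = per_class, macro = macro,
                 overall_accuracy_pct = 100 * sum(tp) / total,
                 n_beats = total, n_correct = sum(tp)),
            class = "hb_metrics")
}

#' @export
print.hb_metrics <- function(x, ...) {
  df <- bind_rows(x$per_class,
                  dplyr::bind_cols(tibble(class = "Average"), x$macro))
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ round_half_up(.x, 2)))
  cat("AAMI per-class metrics (%)\n")
  print(as.data.frame(df), row.names = FALSE)
  cat(sprintf("overall accuracy: %.2f%%  (%s of %s beats correct)\n",
              round_half_up(x$overall_accuracy_pct, 2),
              format(x$n_correct, big.mark = ","),
              format(x$n_beats, big.mark = ",")))
  invisible(x)
}

#' Evaluate a trained model on held-out beats
#'
#' Predicts every test beat, builds the confusion matrix and the AAMI
#' metric report. Refuses to run if any test record id was seen during
#' training (the inter-patient guarantee).
#'
#' @param model A trained `hb_model`.
#' @param test_beats Beat tibble from records disjoint from training.
#' @return An `hb_eval` object: list with `confusion` (`hb_confusion`),
#'   `metrics` (`hb_metrics`) and `predictions` (tibble of `record_id`,
#'   `truth`, `pred` and the four class probabilities).
#' @export
evaluate <- function(model, test_beats) {
  stopifnot(inherits(model, "hb_model"))
  overlap <- intersect(unique(as.character(test_beats$record_id)),
                       model$train_records)
  if (length(overlap) > 0) {
    abort(paste0("inter-patient violation: record(s) also used in training: ",
                 paste(overlap, collapse = ", ")))
  }
  probs <- predict(model, test_beats, type = "prob")
  pred <- factor(aami_classes[max.col(as.matrix(probs), ties.method = "first")],
                 levels = aami_classes)
  cm <- confusion_matrix(test_beats$label, pred)
  structure(list(confusion = cm, metrics = per_class_metrics(cm),
                 predictions = dplyr::bind_cols(
                   tibble(record_id = test_beats$record_id,
                          truth = test_beats$label, pred = pred),
                   probs)),
            class = "hb_eval")
}

#' @export
print.hb_eval <- function(x, ...) {
  cat("Confusion matrix (rows = ground truth):\n")
  print(unclass(x$confusion))
  cat("\n")
  print(x$metrics)
  invisible(x)
}

#' Published reference confusion matrices on the MIT-BIH DS2 test set
#'
#' The 4x4 ground-truth-by-prediction counts reported for this
#' architecture on the inter-patient MIT-BIH DS2 test set (49,661 beats),
#' one matrix for focal-loss training and one for cross-entropy training.
#' They let the metric pipeline be exercised and checked without any signal
#' data: feeding them to [per_class_metrics()] reproduces the published
#' per-class PPV/SE/F1/accuracy figures.
#'
#' @return Named list of two `hb_confusion` matrices: `focal` and
#'   `cross_entropy`.
#' @export
reference_confusion_matrices <- function() {
  focal <- matrix(c(41420, 671, 206, 1921,
                    282, 1494, 57, 3,
                    141, 21, 3017, 40,
                    336, 0, 31, 21),
                  nrow = 4, byrow = TRUE)
  ce <- matrix(c(40866, 1082, 462, 1808,
                 246, 1482, 95, 13,
                 173, 31, 3008, 7,
                 368, 0, 18, 2),
               nrow = 4, byrow = TRUE)
  list(focal = as_hb_confusion(focal), cross_entropy = as_hb_confusion(ce))
}
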