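#' Confusion matrix
#'
#' @param true_labels,predicted_labels integer labels in `1..C`.
#' @param C number of classes.
#' @return A C x C integer matrix of class `confusion_matrix`; rows index the
#'   true class, columns the predicted class.
#' @export
compute_confusion <- function(true_labels, predicted_labels, C) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_gliofuse("label vectors differ in length", "gliofuse_value_error")
  }
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (any(c(true_labels, predicted_labels) < 1) ||
      any(c(true_labels, predicted_labels) > C)) {
    stop_gliofuse("label out of range 1..C", "gliofuse_value_error")
  }
  cm <- matrix(0L, C, C,
               dimnames = list(true = paste0("c", seq_len(C)),
                               predicted = paste0("c", seq_len(C))))
  for (i in seq_along(true_labels)) {
    cm[true_labels[i], predicted_labels[i]] <-
      cm[true_labels[i], predicted_labels[i]] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

# Rank-statistic (Mann-Whitney) AUC for binary 0/1 labels with tie handling
# by mid-ranks.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Computes accuracy, precision, recall (sensitivity), F1, and specificity
#' from a confusion matrix — with the plain binary definitions for two
#' classes (second class taken as positive) and macro-averaged one-vs-rest
#' values for more — plus natural-log loss and rank-statistic ROC AUC when a
#' probability matrix is supplied. A class absent from the truth has
#' undefined recall; it is reported as `NA` and excluded from the macro mean
#' with a warning. Probabilities are clamped at 1e-8 inside the log loss so
#' the exact zeros emitted by the sparse entmax output stay finite.
#'
#' @param cm a [compute_confusion] matrix.
#' @param probs optional samples x C probability matrix (rows sum to 1).
#' @param labels true labels in `1..C` matching the rows of `probs`.
#' @return An object of class `metrics_report`: a list with overall metrics
#'   and a `per_class` data.frame of one-vs-rest values.
#' @export
compute_metrics <- function(cm, probs = NULL, labels = NULL) {
  C <- nrow(cm)
  n <- sum(cm)
  accuracy <- sum(diag(cm)) / n
  per <- data.frame(class = seq_len(C), precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_,
                    specificity = NA_real_, auc = NA_real_)
  for (c in seq_len(C)) {
    TP <- cm[c, c]
    FN <- sum(cm[c, ]) - TP
    FP <- sum(cm[, c]) - TP
    TN <- n - TP - FN - FP
    per$precision[c] <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    per$recall[c] <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    per$specificity[c] <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    pr <- per$precision[c]; rc <- per$recall[c]
    per$f1[c] <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
      2 * pr * rc / (pr + rc) else NA_real_
  }
  absent <- which(rowSums(cm) == 0)
  if (length(absent) > 0) {
    warning(sprintf(
      "class(es) %s absent from the truth; recall undefined, excluded from macro averages",
      paste(absent, collapse = ", ")))
  }
  if (C == 2) {
    precision <- per$precision[2]
    recall <- per$recall[2]
    f1 <- per$f1[2]
    specificity <- per$specificity[2]
  } else {
    precision <- mean(per$precision, na.rm = TRUE)
    recall <- mean(per$recall, na.rm = TRUE)
    f1 <- mean(per$f1, na.rm = TRUE)
    specificity <- mean(per$specificity, na.rm = TRUE)
  }
  log_loss <- NA_real_
  auc <- NA_real_
  if (!is.null(probs)) {
    assert_that(!is.null(labels) && length(labels) == nrow(probs),
                "labels matching probs rows are required for log loss / AUC")
    assert_that(ncol(probs) == C, "probs columns must equal class count",
                "gliofuse_dimension_error")
    labels <- as.integer(labels)
    p_true <- pmax(probs[cbind(seq_len(nrow(probs)), labels)], 1e-8)
    log_loss <- -mean(log(p_true))
    for (c in seq_len(C)) per$auc[c] <- auc_rank(probs[, c], labels == c)
    auc <- if (C == 2) per$auc[2] else mean(per$auc, na.rm = TRUE)
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, specificity = specificity, log_loss = log_loss,
                 auc = auc, per_class = per, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d  acc=%.4f  prec=%.4f  rec=%.4f",
                     "  f1=%.4f  spec=%.4f  logloss=%s  auc=%s\n"),
              x$n, x$accuracy, x$precision, x$recall, x$f1, x$specificity,
              ifelse(is.na(x$log_loss), "NA", sprintf("%.4f", x$log_loss)),
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Export a metrics report as JSON
#'
#' @param report a [compute_metrics] report.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Export a confusion matrix as CSV
#'
#' @param cm a [compute_confusion] matrix.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' ROC curve points
#'
#' Sweeps every distinct score as a threshold and reports the false/true
#' positive rates, for one-vs-rest binary labelling.
#'
#' @param scores numeric scores for the positive class.
#' @param positive logical vector marking positives.
#' @return A data.frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, positive) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  out <- data.frame(fpr = numeric(length(thr)), tpr = numeric(length(thr)),
                    threshold = thr)
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    out$tpr[i] <- if (n1 > 0) sum(pred & positive) / n1 else NA_real_
    out$fpr[i] <- if (n0 > 0) sum(pred & !positive) / n0 else NA_real_
  }
  out
}

#' Export ROC points as TSV
#'
#' @param roc a [roc_points] data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
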