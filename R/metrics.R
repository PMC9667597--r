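# Six-metric evaluation report: accuracy, micro AUPR, micro AUC, and
# macro-averaged F1 / precision / recall, plus a per-class table.

#' Evaluate multi-class predictions
#'
#' Accuracy is computed from the argmax prediction. F1, precision, and recall
#' are macro-averaged over the classes present in `y_true` (classes with no
#' test support are excluded from the macro means, since their recall is
#' undefined). AUPR and AUC are micro-averaged: the one-vs-rest binarized
#' label matrix and the probability matrix are pooled into a single binary
#' problem. Micro/macro conventions can be swapped via `average`.
#'
#' @param y_true integer labels in 1..C.
#' @param y_prob N x C matrix of class probabilities (rows sum to 1).
#' @param average list with elements `prf` and `curves`, each `"macro"` or
#'   `"micro"`, selecting the averaging for F1/precision/recall and for
#'   AUPR/AUC respectively.
#' @return An object of class `metric_report`: a list with `acc`, `aupr`,
#'   `auc`, `f1`, `precision`, `recall`, and `per_class` (data.frame with
#'   class, support, f1, aupr).
#' @export
compute_metrics <- function(y_true, y_prob,
                            average = list(prf = "macro", curves = "micro")) {
  y_prob <- as.matrix(y_prob)
  n <- nrow(y_prob); k <- ncol(y_prob)
  if (length(y_true) != n) {
    stop_invalid("y_true has length ", length(y_true), " but y_prob has ",
                 n, " rows")
  }
  if (any(y_true < 1L | y_true > k)) {
    stop_invalid("labels present in y_true exceed the probability columns")
  }
  rs <- rowSums(y_prob)
  if (any(abs(rs - 1) > 1e-4)) {
    stop_invalid("probability rows must sum to 1 (max deviation ",
                 format(max(abs(rs - 1))), ")")
  }
  pred <- max.col(y_prob, ties.method = "first")
  acc <- mean(pred == y_true)
  present <- sort(unique(y_true))
  prec <- rec <- f1 <- aupr_c <- rep(NA_real_, length(present))
  for (i in seq_along(present)) {
    cl <- present[i]
    tp <- sum(pred == cl & y_true == cl)
    fp <- sum(pred == cl & y_true != cl)
    fn <- sum(pred != cl & y_true == cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else 0
    aupr_c[i] <- average_precision(y_true == cl, y_prob[, cl])
  }
  support <- vapply(present, function(cl) sum(y_true == cl), integer(1))
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), y_true)] <- 1
  if (identical(average$curves, "micro")) {
    truth <- as.vector(onehot)
    score <- as.vector(y_prob)
    aupr <- average_precision(truth == 1, score)
    auc <- binary_auc(truth == 1, score)
  } else {
    auc_c <- vapply(seq_along(present), function(i) {
      binary_auc(y_true == present[i], y_prob[, present[i]])
    }, numeric(1))
    aupr <- mean(aupr_c)
    auc <- mean(auc_c)
  }
  if (identical(average$prf, "micro")) {
    # pooled one-vs-rest counts collapse to accuracy for single-label data
    p_out <- r_out <- f_out <- acc
  } else {
    p_out <- mean(prec); r_out <- mean(rec); f_out <- mean(f1)
  }
  structure(list(acc = acc, aupr = aupr, auc = auc, f1 = f_out,
                 precision = p_out, recall = r_out,
                 per_class = data.frame(class = present, support = support,
                                        f1 = f1, aupr = aupr_c)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> acc %.4f  aupr %.4f  auc %.4f  ",
                     "f1 %.4f  precision %.4f  recall %.4f\n"),
              x$acc, x$aupr, x$auc, x$f1, x$precision, x$recall))
  invisible(x)
}

# Average precision (step-wise area under the precision-recall curve),
# computed over unique score thresholds so ties are handled consistently.
average_precision <- function(truth, score) {
  pos <- sum(truth)
  if (pos == 0) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]; score <- score[o]
  boundary <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(truth)[boundary]
  fp <- cumsum(!truth)[boundary]
  prec <- tp / (tp + fp)
  recall <- tp / pos
  drecall <- diff(c(0, recall))
  sum(prec * drecall)
}

binary_auc <- function(truth, score) {
  if (!any(truth) || all(truth)) return(NA_real_)
  as.numeric(pROC::auc(response = as.integer(truth), predictor = score,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Flatten a metric report to JSON / a CSV row
#'
#' @param report a `metric_report`.
#' @param path file path.
#' @param task,fold optional identifiers recorded in the CSV row.
#' @export
write_metric_report <- function(report, path, task = NA, fold = NA) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  } else {
    row <- data.frame(task = task, fold = fold, acc = report$acc,
                      aupr = report$aupr, auc = report$auc, f1 = report$f1,
                      precision = report$precision, recall = report$recall)
    utils::write.csv(row, path, row.names = FALSE)
  }
  invisible(path)
}
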