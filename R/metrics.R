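# Binary-classification evaluation: confusion counts, Sn/Sp/Acc/MCC and
# rank-based AUC, with the positive class = TF = 1 throughout.

#' Confusion counts
#'
#' @param labels binary 0/1 vector of true classes.
#' @param preds binary 0/1 vector of predicted classes, same length.
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, preds) {
  if (length(labels) != length(preds))
    stop("labels and predictions differ in length")
  labels <- as.integer(labels); preds <- as.integer(preds)
  if (any(!labels %in% 0:1) || any(!preds %in% 0:1))
    stop("labels and predictions must be 0/1")
  list(TP = sum(labels == 1L & preds == 1L),
       TN = sum(labels == 0L & preds == 0L),
       FP = sum(labels == 0L & preds == 1L),
       FN = sum(labels == 1L & preds == 0L))
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and the Matthews correlation coefficient with the standard
#' denominator `sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero denominator
#' factor yields MCC = 0 with `mcc_degenerate = TRUE`; an empty class yields
#' `NaN` for the affected rate with `rate_undefined = TRUE`.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see [confusion_counts()]).
#' @return list with `Sn`, `Sp`, `Acc`, `MCC`, the `counts`, and the warning
#'   flags above.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("no evaluated samples")
  rate_undefined <- FALSE
  Sn <- if (TP + FN > 0) TP / (TP + FN) else { rate_undefined <- TRUE; NaN }
  Sp <- if (TN + FP > 0) TN / (TN + FP) else { rate_undefined <- TRUE; NaN }
  Acc <- (TP + TN) / total
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc_degenerate <- den == 0
  MCC <- if (mcc_degenerate) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  if (mcc_degenerate)
    warning("MCC denominator has a zero factor; reporting MCC = 0")
  list(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC, counts = counts,
       mcc_degenerate = mcc_degenerate, rate_undefined = rate_undefined)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random positive
#' scores above a random negative, with tied scores contributing 1/2.
#' Equivalent to trapezoidal integration of the ROC curve.
#'
#' @param labels binary 0/1 vector; both classes must be present.
#' @param scores numeric scores (higher = more TF-like).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores differ in length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores)                       # average ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report for scored predictions
#'
#' @param labels binary 0/1 truth.
#' @param scores predicted probabilities.
#' @param threshold classification cut-off; class 1 iff `score >= threshold`.
#' @return list as [compute_metrics()] plus `AUC`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  counts <- confusion_counts(labels, as.integer(scores >= threshold))
  m <- compute_metrics(counts)
  m$AUC <- roc_auc(labels, scores)
  m
}

#' Format metric rows as a report table
#'
#' @param rows named list of metric lists (from [metrics_report()] or
#'   [compute_metrics()]); names become the first column.
#' @param label_col name of the first column (`"Method"` or `"Data"`).
#' @return data.frame with metrics rounded to 4 decimal places.
#' @export
metrics_table <- function(rows, label_col = "Method") {
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    m <- rows[[nm]]
    data.frame(check.names = FALSE,
               stats::setNames(list(nm), label_col),
               Sn = round(m$Sn, 4), Sp = round(m$Sp, 4),
               Acc = round(m$Acc, 4), MCC = round(m$MCC, 4),
               AUC = if (is.null(m$AUC)) NA_real_ else round(m$AUC, 4))
  }))
  rownames(df) <- NULL
  df
}

#' Write a metrics table as TSV
#' @param table data.frame from [metrics_table()].
#' @param path output path.
#' @export
write_metrics_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
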