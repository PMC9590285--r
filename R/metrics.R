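#' Multi-class confusion counts
#'
#' Tallies the 5x5 (or k x k) confusion matrix, rows = true class, columns =
#' predicted class, and the one-vs-rest reductions TP/TN/FP/FN per class.
#'
#' @param true_labels,predicted_labels Equal-length character/factor vectors;
#'   every label must belong to `classes`.
#' @param classes Class universe (default the five AAMI classes).
#' @return Object of class `"confusion_counts"`: list with `matrix` (k x k
#'   integer), `per_class` (data frame with TP, TN, FP, FN) and `n`.
#' @export
confusion <- function(true_labels, predicted_labels, classes = aami_classes()) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(true_labels, levels = classes),
             factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  n <- sum(m)
  per <- data.frame(
    class = classes,
    TP = diag(m),
    FP = colSums(m) - diag(m),
    FN = rowSums(m) - diag(m),
    row.names = classes
  )
  per$TN <- n - per$TP - per$FP - per$FN
  structure(list(matrix = m, per_class = per[, c("class", "TP", "TN", "FP", "FN")],
                 n = n),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: %d samples>\n", x$n))
  print(x$matrix)
  invisible(x)
}

# ratio with the zero-denominator convention: 0, flagged degenerate
.safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Per-class classification metrics
#'
#' From one-vs-rest confusion counts, computes per class: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`, the F1 score and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, plus the overall
#' (multi-class) accuracy `trace/total` and macro averages. Cells with a zero
#' denominator yield 0 and raise the `degenerate` flag rather than NaN, so
#' aggregation stays stable.
#'
#' @param counts A [confusion()] result.
#' @param f1_convention `"standard"` gives `F1 = 2*Ppv*Sen/(Ppv+Sen)`;
#'   `"paper_literal"` gives the halved variant `Ppv*Sen/(Ppv+Sen)`.
#' @return Object of class `"metrics_report"`: list with `per_class` data
#'   frame (Acc, Sen, Spe, Ppv, F1, MCC, degenerate), `overall_accuracy`,
#'   `macro` averages and the convention used.
#' @export
metrics <- function(counts, f1_convention = c("standard", "paper_literal")) {
  f1_convention <- match.arg(f1_convention)
  stopifnot(inherits(counts, "confusion_counts"))
  pc <- counts$per_class
  TP <- as.numeric(pc$TP); TN <- as.numeric(pc$TN)
  FP <- as.numeric(pc$FP); FN <- as.numeric(pc$FN)
  acc <- .safe_ratio(TP + TN, TP + TN + FP + FN)
  sen <- .safe_ratio(TP, TP + FN)
  spe <- .safe_ratio(TN, TN + FP)
  ppv <- .safe_ratio(TP, TP + FP)
  f1 <- .safe_ratio(ppv * sen, ppv + sen) *
    if (f1_convention == "standard") 2 else 1
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- .safe_ratio(TP * TN - FP * FN, mcc_den)
  degenerate <- (TP + FN) == 0 | (TN + FP) == 0 | (TP + FP) == 0 |
    (TN + FN) == 0 | (ppv + sen) == 0
  per <- data.frame(class = pc$class, Acc = acc, Sen = sen, Spe = spe,
                    Ppv = ppv, F1 = f1, MCC = mcc, degenerate = degenerate,
                    row.names = pc$class)
  structure(list(per_class = per,
                 overall_accuracy = sum(diag(counts$matrix)) / counts$n,
                 macro = colMeans(per[, c("Acc", "Sen", "Spe", "Ppv", "F1", "MCC")]),
                 f1_convention = f1_convention),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Overall accuracy: %.*f\n", digits, x$overall_accuracy))
  tab <- x$per_class[, c("Acc", "Sen", "Spe", "Ppv", "F1", "MCC")]
  print(round(tab, digits))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a decision threshold over that class's predicted
#' probability column and traces (FPR, TPR); the AUC is the trapezoidal area,
#' with tied scores grouped (so label-independent scores give AUC 0.5). A
#' class with no positives or no negatives yields `NA` AUC and is flagged.
#'
#' @param scores Numeric matrix of per-class scores in `[0,1]`, columns named
#'   by class.
#' @param true_labels True class labels.
#' @return Object of class `"roc_result"`: per class, a list with `points`
#'   (data frame fpr/tpr), `auc`, `degenerate`.
#' @export
roc_auc <- function(scores, true_labels) {
  true_labels <- as.character(true_labels)
  if (is.null(colnames(scores))) stop("scores must have class column names")
  if (nrow(scores) != length(true_labels)) stop("scores/labels length mismatch")
  out <- lapply(colnames(scores), function(cls) {
    y <- as.integer(true_labels == cls)
    s <- scores[, cls]
    np <- sum(y == 1); nn <- sum(y == 0)
    if (np == 0 || nn == 0) {
      return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                  auc = NA_real_, degenerate = TRUE))
    }
    # sweep thresholds at each distinct score, descending; ties grouped
    ord <- order(s, decreasing = TRUE)
    ys <- y[ord]; ss <- s[ord]
    cum_tp <- cumsum(ys); cum_fp <- cumsum(1 - ys)
    last <- c(ss[-1] != ss[-length(ss)], TRUE) # last index of each tie group
    tpr <- c(0, cum_tp[last] / np)
    fpr <- c(0, cum_fp[last] / nn)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
         degenerate = FALSE)
  })
  names(out) <- colnames(scores)
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  for (cls in names(x)) {
    cat(sprintf("class %s: AUC = %s%s\n", cls,
                formatC(x[[cls]]$auc, digits = 4, format = "f"),
                if (x[[cls]]$degenerate) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Write a metrics report to JSON or CSV
#' @param report A [metrics()] result.
#' @param path Output path; format chosen by `.json` / `.csv` extension.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(overall_accuracy = report$overall_accuracy,
           per_class = report$per_class,
           macro = as.list(report$macro)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$per_class, path, row.names = FALSE)
  }
  invisible(path)
}
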