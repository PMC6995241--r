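#' Two-class confusion matrix (positive class = tumor)
#'
#' @param true,pred equal-length label vectors over `{"normal", "tumor"}`.
#' @return object of class `confusion_matrix` with counts `tn`, `fp`,
#'   `fn`, `tp`.
#' @export
confusion <- function(true, pred) {
  true <- check_labels(true, "true labels")
  pred <- check_labels(pred, "predicted labels")
  if (length(true) != length(pred)) {
    stopf("label vectors differ in length (%d vs %d)", length(true), length(pred))
  }
  structure(
    list(tn = sum(true == "normal" & pred == "normal"),
         fp = sum(true == "normal" & pred == "tumor"),
         fn = sum(true == "tumor" & pred == "normal"),
         tp = sum(true == "tumor" & pred == "tumor")),
    class = "confusion_matrix"
  )
}

#' Build a confusion matrix directly from counts
#'
#' @param tn,fp,fn,tp non-negative counts.
#' @return a `confusion_matrix`.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  stopifnot(all(c(tn, fp, fn, tp) >= 0))
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), nrow = 2, byrow = TRUE,
              dimnames = list(c("actual normal", "actual tumor"),
                              c("pred normal", "pred tumor")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity as percentages
#'
#' `sensitivity = 100 * tp / (tp + fn)` over the tumors,
#' `specificity = 100 * tn / (tn + fp)` over the normals. Values are
#' returned at full precision; presentation rounds to one decimal.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `sensitivity` and `specificity` (percent).
#' @export
sens_spec <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) stopf("no tumor samples; sensitivity undefined")
  if (cm$tn + cm$fp == 0) stopf("no normal samples; specificity undefined")
  ## divide first so 100 * recall from the classification report matches
  ## bit for bit
  list(sensitivity = 100 * (cm$tp / (cm$tp + cm$fn)),
       specificity = 100 * (cm$tn / (cm$tn + cm$fp)))
}

report_from_confusion <- function(cm) {
  per_class <- function(tp, fp, fn, support) {
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (support == 0) 0 else tp / support
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1, support = support)
  }
  normal <- per_class(tp = cm$tn, fp = cm$fn, fn = cm$fp, support = cm$tn + cm$fp)
  tumor <- per_class(tp = cm$tp, fp = cm$fp, fn = cm$fn, support = cm$tp + cm$fn)
  w <- c(normal["support"], tumor["support"])
  weighted <- c(
    precision = sum(c(normal["precision"], tumor["precision"]) * w) / sum(w),
    recall = sum(c(normal["recall"], tumor["recall"]) * w) / sum(w),
    f1 = sum(c(normal["f1"], tumor["f1"]) * w) / sum(w),
    support = sum(w)
  )
  out <- as.data.frame(rbind(normal, tumor, weighted))
  out$class <- c("normal", "tumor", "weighted_avg")
  rownames(out) <- NULL
  out[, c("class", "precision", "recall", "f1", "support")]
}

#' Per-class precision / recall / F1 classification report
#'
#' One row per class plus a support-weighted average row ("avg/total"
#' convention). `f1 = 2 P R / (P + R)`, 0 when `P + R = 0`. Full precision
#' is kept; round to two decimals only for presentation. For the binary
#' case, `100 * recall(tumor)` equals the sensitivity and
#' `100 * recall(normal)` the specificity, exactly.
#'
#' @param true,pred label vectors, or pass a precomputed
#'   `confusion_matrix` as `true` (then `pred` is ignored).
#' @return data.frame `class`, `precision`, `recall`, `f1`, `support`.
#' @export
classification_report <- function(true, pred = NULL) {
  cm <- if (inherits(true, "confusion_matrix")) true else confusion(true, pred)
  report_from_confusion(cm)
}
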