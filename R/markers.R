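#' Rank-statistic ROC AUC for one gene
#'
#' `AUC = P(tumor value > normal value) + 0.5 * P(tie)`, computed from
#' midranks (the Mann-Whitney statistic divided by `n_tumor * n_normal`).
#' This equals the trapezoidal area under the (FPR, TPR) curve swept over
#' all thresholds. Tumor-high expression gives AUC > 0.5.
#'
#' @param values per-sample expression values for one gene.
#' @param labels per-sample classes in `{"normal", "tumor"}`.
#' @return the AUC, a single number in `[0, 1]`.
#' @export
roc_auc <- function(values, labels) {
  labels <- check_labels(labels)
  stopifnot(length(values) == length(labels))
  if (any(!is.finite(values))) stopf("non-finite expression values")
  n1 <- sum(labels == "tumor")
  n0 <- sum(labels == "normal")
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present to compute AUC")
  r <- rank(values)  # midranks half-weight ties
  (sum(r[labels == "tumor"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-gene AUC table over a rescaled matrix
#'
#' @param rescaled a [rescaled_matrix()] (typically the merged discovery set).
#' @param fold if `TRUE`, report `max(AUC, 1 - AUC)` (direction-agnostic);
#'   the default keeps the directed, tumor-high AUC.
#' @return data.frame `gene`, `auc`, `n_tumor`, `n_normal`.
#' @export
auc_table <- function(rescaled, fold = FALSE) {
  stopifnot(inherits(rescaled, "rescaled_matrix"))
  auc <- apply(rescaled$values, 1, roc_auc, labels = rescaled$labels)
  if (fold) auc <- pmax(auc, 1 - auc)
  data.frame(gene = rownames(rescaled$values), auc = unname(auc),
             n_tumor = sum(rescaled$labels == "tumor"),
             n_normal = sum(rescaled$labels == "normal"),
             stringsAsFactors = FALSE)
}

#' Confirm protein expression from IHC staining-category counts
#'
#' A gene is confirmed when `(high + medium) / total >= threshold` over its
#' immunohistochemistry staining images. Genes with zero counted images, or
#' absent from the table when a `genes` universe is supplied, carry no
#' information and are reported separately as `no_data` (they are never
#' confirmed).
#'
#' @param table data.frame with columns `gene`, `high`, `medium`, `low`,
#'   `not_detected` (counts).
#' @param threshold confirmation threshold on the high+medium fraction,
#'   in (0, 1].
#' @param genes optional universe of genes under evaluation; defaults to
#'   the genes present in `table`.
#' @return object of class `ihc_confirmation`: character vectors
#'   `confirmed`, `not_confirmed`, `no_data`, plus the per-gene `table`
#'   with `total`, `high_medium`, `fraction` and `status`.
#' @export
ihc_confirm <- function(table, threshold = 0.75, genes = NULL) {
  stopifnot(is.data.frame(table),
            all(c("gene", "high", "medium", "low", "not_detected") %in% names(table)),
            threshold > 0, threshold <= 1)
  counts <- table[, c("high", "medium", "low", "not_detected")]
  if (any(counts < 0)) stopf("negative IHC counts")
  tab <- data.frame(gene = as.character(table$gene),
                    total = rowSums(counts),
                    high_medium = table$high + table$medium,
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    missing <- setdiff(as.character(genes), tab$gene)
    if (length(missing) > 0L) {
      tab <- rbind(tab, data.frame(gene = missing, total = 0, high_medium = 0,
                                   stringsAsFactors = FALSE))
    }
    tab <- tab[tab$gene %in% as.character(genes), , drop = FALSE]
  }
  tab$fraction <- ifelse(tab$total > 0, tab$high_medium / tab$total, NA_real_)
  tab$status <- ifelse(tab$total == 0, "no_data",
                       ifelse(tab$fraction >= threshold, "confirmed", "not_confirmed"))
  structure(
    list(confirmed = tab$gene[tab$status == "confirmed"],
         not_confirmed = tab$gene[tab$status == "not_confirmed"],
         no_data = tab$gene[tab$status == "no_data"],
         table = tab),
    class = "ihc_confirmation"
  )
}

#' @export
print.ihc_confirmation <- function(x, ...) {
  cat(sprintf("ihc_confirmation: %d confirmed, %d not confirmed, %d without data\n",
              length(x$confirmed), length(x$not_confirmed), length(x$no_data)))
  invisible(x)
}

#' Select the top-k confirmed markers by AUC
#'
#' Orders the IHC-confirmed genes by descending AUC (ties broken toward the
#' lexicographically smaller gene id) and keeps the first `k`.
#'
#' @param auc an [auc_table()] data.frame.
#' @param confirmed character vector of confirmed genes, or an
#'   `ihc_confirmation` object.
#' @param k number of markers to select.
#' @return data.frame of the `k` selected rows of `auc`, AUC non-increasing.
#' @export
select_markers <- function(auc, confirmed, k = 5L) {
  stopifnot(is.data.frame(auc), all(c("gene", "auc") %in% names(auc)),
            is_count(k))
  if (inherits(confirmed, "ihc_confirmation")) confirmed <- confirmed$confirmed
  pool <- auc[auc$gene %in% as.character(confirmed), , drop = FALSE]
  if (nrow(pool) < k) {
    stopf("only %d confirmed gene(s) with an AUC, but k = %d markers requested",
          nrow(pool), k)
  }
  pool <- pool[order(-pool$auc, pool$gene), , drop = FALSE]
  out <- pool[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
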