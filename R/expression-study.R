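#' One study's expression matrix with sample class labels
#'
#' A lightweight container for a single study: a genes-by-samples matrix of
#' log2 intensities plus a per-sample class label in `{"normal", "tumor"}`.
#' Duplicate row identifiers are allowed (probe-level data before collapse).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as gene/sample identifiers.
#' @param labels character vector of per-sample classes, aligned with the
#'   columns of `values`.
#' @param study_id identifier for the study.
#' @param gene_ids optional gene/probe identifiers overriding `rownames(values)`.
#' @return an object of class `expression_study` with elements `values`
#'   (named matrix), `gene_ids`, `labels` and `study_id`.
#' @export
expression_study <- function(values, labels, study_id = "study",
                             gene_ids = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(gene_ids)) stopf("gene identifiers missing (no rownames)")
  if (length(gene_ids) != nrow(values)) {
    stopf("length(gene_ids) = %d does not match nrow(values) = %d",
          length(gene_ids), nrow(values))
  }
  labels <- check_labels(labels, "sample labels")
  if (length(labels) != ncol(values)) {
    stopf("%d labels for %d samples", length(labels), ncol(values))
  }
  rownames(values) <- gene_ids
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample%03d", seq_len(ncol(values)))
  }
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         labels = labels, study_id = as.character(study_id)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s': %d genes x %d samples (%d tumor, %d normal)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

## both classes present and each with >= n members
check_two_classes <- function(study, min_per_class = 2L) {
  n_t <- sum(study$labels == "tumor")
  n_n <- sum(study$labels == "normal")
  if (n_t < min_per_class || n_n < min_per_class) {
    stopf("study '%s' needs >= %d samples per class (tumor: %d, normal: %d)",
          study$study_id, min_per_class, n_t, n_n)
  }
  invisible(TRUE)
}
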