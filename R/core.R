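#' Intersect per-study DEG calls into a core-gene set
#'
#' A gene enters the core set when it is called (up or down) in at least
#' `ceil(min_fraction * n_studies)` studies; with `require_direction`
#' (default) the direction must agree in every study in which the gene is
#' called. The default `min_fraction = 1` keeps exactly the genes shared by
#' all studies.
#'
#' @param deg_tables list of called `deg_table`s (one per study).
#' @param min_fraction minimum fraction of studies a gene must be called in.
#' @param require_direction drop genes called in conflicting directions?
#' @return object of class `core_gene_set`: `genes` (data.frame `gene`,
#'   `direction`, `frequency`, sorted by gene id), `presence` (gene-by-study
#'   call matrix over the union of called genes), `min_fraction`,
#'   `n_studies`. An empty result is a valid (empty) set.
#' @export
intersect_core <- function(deg_tables, min_fraction = 1.0,
                           require_direction = TRUE) {
  stopifnot(length(deg_tables) >= 1,
            min_fraction > 0, min_fraction <= 1)
  for (tab in deg_tables) {
    if (!all(c("gene", "call") %in% names(tab))) {
      stopf("each DEG table needs 'gene' and 'call' columns")
    }
  }
  n_studies <- length(deg_tables)
  study_ids <- names(deg_tables)
  if (is.null(study_ids)) study_ids <- sprintf("study%02d", seq_len(n_studies))

  called <- lapply(deg_tables, function(tab) tab[tab$call != "none", c("gene", "call")])
  all_genes <- sort(unique(unlist(lapply(called, `[[`, "gene"))))
  presence <- matrix("none", nrow = length(all_genes), ncol = n_studies,
                     dimnames = list(all_genes, study_ids))
  for (i in seq_len(n_studies)) {
    presence[called[[i]]$gene, i] <- called[[i]]$call
  }

  freq <- rowSums(presence != "none")
  need <- ceiling(min_fraction * n_studies)
  keep <- freq >= need
  if (require_direction) {
    consistent <- apply(presence, 1, function(cl) {
      cl <- cl[cl != "none"]
      length(unique(cl)) == 1L
    })
    keep <- keep & consistent
  }

  direction <- apply(presence, 1, function(cl) {
    cl <- cl[cl != "none"]
    names(sort(table(cl), decreasing = TRUE))[1]
  })
  genes <- data.frame(gene = all_genes[keep],
                      direction = unname(direction[keep]),
                      frequency = unname(freq[keep]),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL

  structure(list(genes = genes, presence = presence,
                 min_fraction = min_fraction, n_studies = n_studies),
            class = "core_gene_set")
}

#' @export
print.core_gene_set <- function(x, ...) {
  cat(sprintf("core_gene_set: %d genes (%d up, %d down) called in >= %.0f%% of %d studies\n",
              nrow(x$genes), sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down"),
              100 * x$min_fraction, x$n_studies))
  invisible(x)
}

core_gene_ids <- function(genes) {
  if (inherits(genes, "core_gene_set")) genes$genes$gene else as.character(genes)
}

#' Per-gene standardization followed by min-max rescaling
#'
#' For each selected gene within the study: z-score with the sample
#' standard deviation, `X' = (X - mean(X)) / sd(X)`, then a min-max rescale
#' of the z-scores onto `[0, 1]`, so that studies from different platforms
#' share a common range. A zero-variance gene maps to all 0.5 with a
#' warning; genes missing from the study are dropped with a warning.
#'
#' @param study an [expression_study()].
#' @param genes a `core_gene_set` or character vector of gene ids.
#' @return object of class `rescaled_matrix`: `values` (genes x samples in
#'   `[0, 1]`), `labels`, `study` (per-sample source study id).
#' @export
standardize_rescale <- function(study, genes) {
  stopifnot(inherits(study, "expression_study"))
  wanted <- core_gene_ids(genes)
  present <- wanted %in% study$gene_ids
  if (!any(present)) {
    stopf("none of the %d selected genes are present in study '%s'",
          length(wanted), study$study_id)
  }
  if (!all(present)) {
    warnf("study '%s': dropping %d selected gene(s) not present",
          study$study_id, sum(!present))
  }
  idx <- match(wanted[present], study$gene_ids)
  x <- study$values[idx, , drop = FALSE]
  rownames(x) <- wanted[present]

  out <- t(apply(x, 1, function(row) {
    s <- sd(row)
    if (s == 0) return(rep(0.5, length(row)))
    z <- (row - mean(row)) / s
    (z - min(z)) / (max(z) - min(z))
  }))
  if (any(apply(x, 1, sd) == 0)) {
    warnf("study '%s': zero-variance gene(s) rescaled to 0.5", study$study_id)
  }
  dimnames(out) <- list(wanted[present], colnames(study$values))
  rescaled_matrix(out, study$labels, rep(study$study_id, ncol(out)))
}

#' Container for merged rescaled expression
#'
#' @param values numeric genes-by-samples matrix with entries in `[0, 1]`.
#' @param labels per-sample class labels.
#' @param study per-sample source study identifiers.
#' @return object of class `rescaled_matrix`.
#' @export
rescaled_matrix <- function(values, labels, study) {
  stopifnot(is.matrix(values), is.numeric(values))
  labels <- check_labels(labels)
  stopifnot(length(labels) == ncol(values), length(study) == ncol(values))
  if (any(!is.finite(values))) stopf("rescaled values must be finite")
  structure(list(values = values, labels = labels, study = as.character(study)),
            class = "rescaled_matrix")
}

#' @export
print.rescaled_matrix <- function(x, ...) {
  cat(sprintf("rescaled_matrix: %d genes x %d samples from %d study(ies), range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), length(unique(x$study)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Merge per-study rescaled matrices by column concatenation
#'
#' All inputs must cover the same gene set (a common subset is taken with a
#' warning; a disjoint pair is an error). Sample identifiers duplicated
#' across studies are suffixed with their study id.
#'
#' @param rescaled list of [rescaled_matrix()] objects.
#' @return a single merged [rescaled_matrix()] with study provenance kept.
#' @export
merge_studies <- function(rescaled) {
  stopifnot(length(rescaled) >= 1,
            all(vapply(rescaled, inherits, logical(1), "rescaled_matrix")))
  gene_sets <- lapply(rescaled, function(r) rownames(r$values))
  common <- Reduce(intersect, gene_sets)
  if (length(common) == 0L) stopf("studies share no genes; cannot merge")
  if (any(vapply(gene_sets, length, integer(1)) != length(common))) {
    warnf("gene sets differ across studies; merging on the %d shared genes",
          length(common))
  }
  mats <- lapply(rescaled, function(r) r$values[common, , drop = FALSE])
  values <- do.call(cbind, mats)
  labels <- unlist(lapply(rescaled, `[[`, "labels"), use.names = FALSE)
  study <- unlist(lapply(rescaled, `[[`, "study"), use.names = FALSE)
  ids <- colnames(values)
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
    ids[dup] <- paste(ids[dup], study[dup], sep = ".")
    colnames(values) <- ids
  }
  rescaled_matrix(values, labels, study)
}
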