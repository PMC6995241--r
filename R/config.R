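#' Pipeline run configuration
#'
#' Collects every tunable of the discovery-to-classifier pipeline in one
#' validated object. Defaults are the operating point of the analysis the
#' package implements: DEG calls at |log2FC| >= 1 and BH-adjusted p <= 0.05,
#' core genes shared by all studies, markers confirmed when >= 75% of IHC
#' images stain high or medium, top 5 markers by AUC, and a 90-architecture
#' grid (1 or 2 hidden layers, 2..10 nodes each) trained 30 times per
#' architecture with plain SGD (learning rate 0.05, 100 epochs, batch 32).
#'
#' @param lfc_threshold absolute log2 fold-change gate for DEG calls (log2 units).
#' @param fdr_threshold BH-adjusted p-value gate, in (0, 1].
#' @param ihc_threshold minimum fraction of high+medium IHC images for a gene
#'   to count as protein-confirmed, in (0, 1].
#' @param n_markers number of markers selected by descending AUC.
#' @param hidden_node_range inclusive integer range of hidden-layer widths.
#' @param max_hidden_layers maximum number of hidden layers in the grid (1 or 2).
#' @param repetitions independent trainings per architecture.
#' @param learning_rate SGD step size (> 0).
#' @param epochs full passes over the training split (>= 1).
#' @param batch_size mini-batch size.
#' @param split_fraction fraction of merged discovery samples held out as the
#'   internal test set (stratified by class), in (0, 1).
#' @param seed integer seed; every random draw in the pipeline derives from it.
#' @param deg_method two-group statistic: `"moderated"` (empirical-Bayes
#'   shrunken variance) or `"welch"`.
#' @param variance_epsilon variance filter threshold (log2^2 units); 0 removes
#'   exactly the no-variation genes.
#' @param core_min_fraction fraction of studies a gene must be called in to
#'   enter the core set (1 = all studies).
#' @param require_direction must core-gene direction agree across studies?
#' @param rescale_scope `"per_study"` standardizes each gene within each study
#'   before merging; `"merged"` standardizes once on the merged matrix.
#' @param fold_auc if `TRUE`, rank genes by `max(AUC, 1 - AUC)` instead of the
#'   directed (tumor-high) AUC.
#' @param linkage linkage for the two-group hierarchical clustering QC.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(lfc_threshold = 1.0,
                       fdr_threshold = 0.05,
                       ihc_threshold = 0.75,
                       n_markers = 5L,
                       hidden_node_range = 2:10,
                       max_hidden_layers = 2L,
                       repetitions = 30L,
                       learning_rate = 0.05,
                       epochs = 100L,
                       batch_size = 32L,
                       split_fraction = 0.2,
                       seed = 1L,
                       deg_method = c("moderated", "welch"),
                       variance_epsilon = 0,
                       core_min_fraction = 1.0,
                       require_direction = TRUE,
                       rescale_scope = c("per_study", "merged"),
                       fold_auc = FALSE,
                       linkage = "complete") {
  deg_method <- match.arg(deg_method)
  rescale_scope <- match.arg(rescale_scope)
  stopifnot(
    "lfc_threshold must be >= 0" = lfc_threshold >= 0,
    "fdr_threshold must be in (0, 1]" =
      fdr_threshold > 0 && fdr_threshold <= 1,
    "ihc_threshold must be in (0, 1]" =
      ihc_threshold > 0 && ihc_threshold <= 1,
    "core_min_fraction must be in (0, 1]" =
      core_min_fraction > 0 && core_min_fraction <= 1,
    "split_fraction must be in (0, 1)" =
      split_fraction > 0 && split_fraction < 1,
    "n_markers must be a positive count" = is_count(n_markers),
    "hidden_node_range must be non-empty positive integers" =
      length(hidden_node_range) >= 1 && all(hidden_node_range >= 1) &&
        all(hidden_node_range == round(hidden_node_range)),
    "max_hidden_layers must be 1 or 2" = max_hidden_layers %in% 1:2,
    "repetitions must be a positive count" = is_count(repetitions),
    "learning_rate must be > 0 (0 allowed for no-op diagnostics)" =
      learning_rate >= 0,
    "epochs must be >= 1" = is_count(epochs),
    "batch_size must be a positive count" = is_count(batch_size),
    "variance_epsilon must be >= 0" = variance_epsilon >= 0,
    "seed must be a single integer" =
      length(seed) == 1 && is.finite(seed) && seed == round(seed)
  )
  structure(
    list(lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
         ihc_threshold = ihc_threshold, n_markers = as.integer(n_markers),
         hidden_node_range = as.integer(sort(unique(hidden_node_range))),
         max_hidden_layers = as.integer(max_hidden_layers),
         repetitions = as.integer(repetitions),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         split_fraction = split_fraction, seed = as.integer(seed),
         deg_method = deg_method, variance_epsilon = variance_epsilon,
         core_min_fraction = core_min_fraction,
         require_direction = isTRUE(require_direction),
         rescale_scope = rescale_scope, fold_auc = isTRUE(fold_auc),
         linkage = linkage),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) {
    cat(sprintf("  %s: %s\n", k, paste(x[[k]], collapse = " ")))
  }
  invisible(x)
}
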