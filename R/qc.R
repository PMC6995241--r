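#' PCA scores of the samples of a rescaled matrix
#'
#' Scores of the mean-centered samples-by-genes data on the leading
#' right-singular directions. Component signs are fixed by convention: the
#' largest-magnitude loading of each component is made positive, so scores
#' are reproducible across platforms.
#'
#' @param rescaled a [rescaled_matrix()] (or plain genes-by-samples matrix).
#' @param n_components number of components, at most `min(genes, samples)`.
#' @return matrix (samples x n_components) of scores, with the rotation in
#'   attribute `"rotation"`.
#' @export
pca_scores <- function(rescaled, n_components = 2L) {
  values <- if (inherits(rescaled, "rescaled_matrix")) rescaled$values else rescaled
  stopifnot(is.matrix(values), is_count(n_components))
  if (n_components > min(dim(values))) {
    stopf("n_components = %d exceeds min(genes, samples) = %d",
          n_components, min(dim(values)))
  }
  x <- t(values)  # samples x genes
  if (all(apply(x, 2, var) == 0)) stopf("all-constant matrix; PCA undefined")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  attr(scores, "rotation") <- rot
  scores
}

#' Two-group hierarchical clustering with label-agreement ratios
#'
#' Agglomerative clustering of the samples on Euclidean distances
#' (complete linkage by default), tree cut at k = 2. Each cluster is
#' mapped to its majority true label (ties map cluster 1 to "normal");
#' the agreement ratio of a class is
#' `100 * (samples of that class placed in their class's cluster) / (class size)`.
#' Deterministic: there is no randomness in the linkage, and `stats::hclust`
#' breaks distance ties by observation order.
#'
#' @param rescaled a [rescaled_matrix()] with at least 2 samples.
#' @param linkage linkage method for [stats::hclust()].
#' @return object of class `cluster_assignment`: `cluster` (per-sample 1/2),
#'   `mapping` (cluster -> label), `ratio_normal`, `ratio_tumor`
#'   (percent), `tree` (the `hclust` object).
#' @export
hcluster_two <- function(rescaled, linkage = "complete") {
  stopifnot(inherits(rescaled, "rescaled_matrix"))
  n <- ncol(rescaled$values)
  if (n < 2L) stopf("clustering needs at least 2 samples, got %d", n)
  tree <- hclust(dist(t(rescaled$values)), method = linkage)
  cl <- cutree(tree, k = 2L)
  labels <- rescaled$labels

  mapping <- vapply(1:2, function(k) {
    members <- labels[cl == k]
    n_t <- sum(members == "tumor"); n_n <- sum(members == "normal")
    if (n_t > n_n) "tumor"
    else if (n_n > n_t) "normal"
    else if (k == 1L) "normal" else "tumor"  # documented tie rule
  }, character(1))
  names(mapping) <- c("1", "2")

  predicted <- mapping[as.character(cl)]
  ratio <- function(class) {
    size <- sum(labels == class)
    if (size == 0L) return(NA_real_)
    100 * sum(labels == class & predicted == class) / size
  }
  structure(list(cluster = unname(cl), mapping = mapping,
                 ratio_normal = ratio("normal"), ratio_tumor = ratio("tumor"),
                 tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: cluster 1 -> %s, cluster 2 -> %s; normal %.1f%%, tumor %.1f%% correctly co-clustered\n",
              x$mapping[["1"]], x$mapping[["2"]],
              x$ratio_normal, x$ratio_tumor))
  invisible(x)
}
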