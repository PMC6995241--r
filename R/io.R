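## On-disk formats: tab-separated, UTF-8, '.' decimal, gene ids opaque
## strings. Numbers are written with 17 significant digits so every table
## round-trips to full double precision.

read_kv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pos <- regexpr(":", lines, fixed = TRUE)
  if (any(pos < 0)) stopf("malformed key-value line in %s", path)
  keys <- trimws(substr(lines, 1L, pos - 1L))
  vals <- trimws(substr(lines, pos + 1L, nchar(lines)))
  stats::setNames(as.list(vals), keys)
}

write_kv <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    sprintf("%s: %s", k, paste(kv[[k]], collapse = " "))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read one study's expression matrix and sample labels
#'
#' The matrix file is tab-delimited with a header row of sample
#' identifiers and gene/probe identifiers in the first column; the labels
#' file is two tab-separated columns `sample`, `class` (header row) with
#' classes in `{"normal", "tumor"}`. The study keeps the samples present in
#' both files, in matrix column order; unlabeled matrix columns are dropped
#' with a warning. Duplicate gene rows are retained (probe collapse is a
#' separate stage).
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the labels TSV.
#' @param study_id study identifier (defaults to the matrix file name).
#' @return an [expression_study()].
#' @export
read_expression_study <- function(matrix_path, labels_path,
                                  study_id = NULL) {
  for (p in c(matrix_path, labels_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  if (is.null(study_id)) {
    study_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  }
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stopf("matrix %s has no sample columns", matrix_path)
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & raw[[j + 1L]] != "NA")
    if (length(bad) > 0L) {
      stopf("non-numeric value '%s' at row '%s', column '%s' of %s",
            raw[[j + 1L]][bad[1]], gene_ids[bad[1]], sample_ids[j], matrix_path)
    }
    values[, j] <- col
  }

  lab <- read.delim(labels_path, header = TRUE, sep = "\t",
                    colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(lab) < 2L) stopf("labels %s needs columns sample, class", labels_path)
  classes <- check_labels(lab[[2]], sprintf("labels in %s", labels_path))
  label_map <- stats::setNames(classes, lab[[1]])

  keep <- sample_ids %in% names(label_map)
  if (!any(keep)) {
    stopf("no overlap between matrix columns of %s and labelled samples of %s",
          matrix_path, labels_path)
  }
  if (!all(keep)) {
    warnf("dropping %d unlabelled matrix column(s) of %s",
          sum(!keep), matrix_path)
  }
  values <- values[, keep, drop = FALSE]
  expression_study(values, unname(label_map[colnames(values)]),
                   study_id = study_id, gene_ids = gene_ids)
}

#' Write a study's matrix and labels as TSV
#'
#' @param study an [expression_study()].
#' @param matrix_path,labels_path output paths.
#' @return the matrix path, invisibly.
#' @export
write_expression_study <- function(study, matrix_path, labels_path) {
  stopifnot(inherits(study, "expression_study"))
  header <- paste(c("gene_id", colnames(study$values)), collapse = "\t")
  rows <- vapply(seq_len(nrow(study$values)), function(i) {
    paste(c(study$gene_ids[i], fmt_num(study$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), matrix_path, useBytes = TRUE)
  writeLines(c("sample\tclass",
               paste(colnames(study$values), study$labels, sep = "\t")),
             labels_path, useBytes = TRUE)
  invisible(matrix_path)
}

#' Write / read a DEG table as TSV
#'
#' Columns: `gene`, `log2fc`, `t_stat`, `p_value`, `adj_p`, `call`.
#' Numbers round-trip at full double precision.
#'
#' @param table a `deg_table` data.frame.
#' @param path file path.
#' @return `write_deg_table` the path invisibly; `read_deg_table` the table.
#' @export
write_deg_table <- function(table, path) {
  header <- "gene\tlog2fc\tt_stat\tp_value\tadj_p\tcall"
  rows <- paste(table$gene, fmt_num(table$log2fc), fmt_num(table$t_stat),
                fmt_num(table$p_value), fmt_num(table$adj_p), table$call,
                sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", rep("numeric", 4), "character"),
                    fileEncoding = "UTF-8")
  names(tab) <- c("gene", "log2fc", "t_stat", "p_value", "adj_p", "call")
  tab
}

#' Write / read a merged rescaled matrix as TSV
#'
#' Layout: a sample-id header row, then two further header rows `class`
#' and `study`, then one row per gene.
#'
#' @param rescaled a [rescaled_matrix()].
#' @param path file path.
#' @return `write_rescaled_matrix` the path invisibly;
#'   `read_rescaled_matrix` the object.
#' @export
write_rescaled_matrix <- function(rescaled, path) {
  stopifnot(inherits(rescaled, "rescaled_matrix"))
  v <- rescaled$values
  lines <- c(
    paste(c("gene_id", colnames(v)), collapse = "\t"),
    paste(c("class", rescaled$labels), collapse = "\t"),
    paste(c("study", rescaled$study), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_rescaled_matrix
#' @export
read_rescaled_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4L) stopf("%s is not a rescaled-matrix file", path)
  split_row <- function(l) strsplit(l, "\t", fixed = TRUE)[[1]]
  samples <- split_row(lines[1])[-1]
  labels <- split_row(lines[2])[-1]
  study <- split_row(lines[3])[-1]
  body <- lapply(lines[-(1:3)], split_row)
  genes <- vapply(body, `[`, character(1), 1L)
  values <- t(vapply(body, function(r) as.numeric(r[-1]),
                     numeric(length(samples))))
  dimnames(values) <- list(genes, samples)
  rescaled_matrix(values, labels, study)
}

#' Serialize / load a trained network as structured text
#'
#' Human-diffable flat `key: value` dialect: layer sizes, activations,
#' marker order, then per layer a row-major weight list (`w1`, `w2`, ...)
#' and a bias list (`b1`, ...). Weights round-trip at full precision.
#'
#' @param model an `mlp_model`.
#' @param path file path.
#' @return `write_mlp_model` the path invisibly; `read_mlp_model` the model.
#' @export
write_mlp_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  a <- model$architecture
  kv <- list(
    type = "mlp_model",
    input_size = a$input_size,
    hidden_sizes = a$hidden_sizes,
    output_size = a$output_size,
    hidden_activation = unname(model$activation[["hidden"]]),
    output_activation = unname(model$activation[["output"]]),
    markers = if (is.null(model$markers)) "" else model$markers,
    n_layers = length(model$weights)
  )
  for (l in seq_along(model$weights)) {
    kv[[paste0("w", l)]] <- fmt_num(as.vector(t(model$weights[[l]])))  # row-major
    kv[[paste0("b", l)]] <- fmt_num(model$biases[[l]])
  }
  write_kv(kv, path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  kv <- read_kv(path)
  if (!identical(kv$type, "mlp_model")) stopf("%s is not a model file", path)
  nums <- function(key) as.numeric(strsplit(kv[[key]], " ", fixed = TRUE)[[1]])
  hidden <- as.integer(nums("hidden_sizes"))
  arch <- architecture(hidden, as.integer(nums("input_size")),
                       as.integer(nums("output_size")))
  sizes <- c(arch$input_size, arch$hidden_sizes, arch$output_size)
  L <- as.integer(nums("n_layers"))
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    weights[[l]] <- matrix(nums(paste0("w", l)), nrow = sizes[l],
                           ncol = sizes[l + 1L], byrow = TRUE)
    biases[[l]] <- nums(paste0("b", l))
  }
  markers <- strsplit(kv$markers, " ", fixed = TRUE)[[1]]
  structure(list(architecture = arch, weights = weights, biases = biases,
                 activation = c(hidden = kv$hidden_activation,
                                output = kv$output_activation),
                 markers = if (length(markers) > 0L) markers else NULL),
            class = "mlp_model")
}

#' Read / write a run configuration as a flat key-value file
#'
#' One `key: value` line per [run_config()] field;
#' `hidden_node_range` is stored as `min max`.
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_run_config` a [run_config()]; `write_run_config` the path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  kv <- read_kv(path)
  args <- list()
  num_keys <- c("lfc_threshold", "fdr_threshold", "ihc_threshold",
                "n_markers", "max_hidden_layers", "repetitions",
                "learning_rate", "epochs", "batch_size", "split_fraction",
                "seed", "variance_epsilon", "core_min_fraction")
  for (k in intersect(num_keys, names(kv))) args[[k]] <- as.numeric(kv[[k]])
  if ("hidden_node_range" %in% names(kv)) {
    r <- as.integer(strsplit(kv$hidden_node_range, " ", fixed = TRUE)[[1]])
    if (length(r) != 2L) stopf("hidden_node_range must be 'min max'")
    args$hidden_node_range <- r[1]:r[2]
  }
  for (k in intersect(c("deg_method", "rescale_scope", "linkage"), names(kv))) {
    args[[k]] <- kv[[k]]
  }
  for (k in intersect(c("require_direction", "fold_auc"), names(kv))) {
    args[[k]] <- toupper(kv[[k]]) %in% c("TRUE", "YES", "1")
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  kv <- unclass(config)
  kv$hidden_node_range <- range(config$hidden_node_range)
  write_kv(kv, path)
}
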