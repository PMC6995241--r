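## Orchestration of the full discovery-to-classifier run.

as_study_list <- function(paths_or_studies, what = "study") {
  lapply(seq_along(paths_or_studies), function(i) {
    x <- paths_or_studies[[i]]
    if (inherits(x, "expression_study")) return(x)
    if (is.character(x) && length(x) == 2L) {
      return(read_expression_study(x[[1]], x[[2]]))
    }
    if (is.list(x) && all(c("matrix", "labels") %in% names(x))) {
      return(read_expression_study(x$matrix, x$labels))
    }
    stopf("%s %d must be an expression_study or a (matrix, labels) path pair",
          what, i)
  })
}

## Standardize+rescale a collection on a gene set under the configured
## scope: per gene within each study (then merge), or once on the merged
## raw matrix.
rescale_collection <- function(studies, genes, scope = c("per_study", "merged")) {
  scope <- match.arg(scope)
  if (scope == "per_study") {
    return(merge_studies(lapply(studies, standardize_rescale, genes = genes)))
  }
  wanted <- core_gene_ids(genes)
  common <- Reduce(intersect, c(list(wanted), lapply(studies, `[[`, "gene_ids")))
  if (length(common) == 0L) stopf("no selected gene present in every study")
  mats <- lapply(studies, function(s) {
    s$values[match(common, s$gene_ids), , drop = FALSE]
  })
  merged <- expression_study(
    do.call(cbind, mats),
    unlist(lapply(studies, `[[`, "labels"), use.names = FALSE),
    study_id = "merged", gene_ids = common
  )
  out <- standardize_rescale(merged, common)
  out$study <- unlist(lapply(studies, function(s) {
    rep(s$study_id, ncol(s$values))
  }), use.names = FALSE)
  out
}

#' Run the full pipeline: DEG, core genes, rescaling, markers, training,
#' evaluation
#'
#' Executes per-study differential expression, intersects calls into the
#' core-gene set, standardizes and merges expression, selects markers by
#' AUC under the IHC confirmation rule, runs the architecture search, and
#' evaluates the best network on the internal split and on the validation
#' studies. All intermediate artifacts are written under `out_dir`; the
#' returned report records their paths and the seed. Re-running with the
#' same inputs, config and seed reproduces every artifact byte for byte.
#'
#' @param config a [run_config()].
#' @param study_paths discovery studies: list of `(matrix, labels)` path
#'   pairs or [expression_study()] objects (at least one).
#' @param validation_paths validation studies, same forms; may be empty.
#' @param ihc_path path to an IHC count TSV (`gene`, `high`, `medium`,
#'   `low`, `not_detected`) or such a data.frame; `NULL` treats every core
#'   gene as expression-confirmed (with a warning).
#' @param out_dir output directory, created if needed.
#' @param probe_maps optional per-study probe-to-gene maps for
#'   [collapse_probes()].
#' @param verbose log one line per stage.
#' @return object of class `pipeline_report` (also written to
#'   `report.txt`): artifact paths, seed, core-gene set, markers, search
#'   summary, metrics for train / internal test / validation.
#' @export
run_pipeline <- function(config, study_paths, validation_paths = list(),
                         ihc_path = NULL, out_dir = tempfile("coremarker_run_"),
                         probe_maps = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"), length(study_paths) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  studies <- as_study_list(study_paths, "discovery study")
  validation <- as_study_list(validation_paths, "validation study")

  ## per-study differential expression
  deg_tables <- lapply(seq_along(studies), function(i) {
    deg_analysis(studies[[i]], config,
                 probe_to_gene = if (is.null(probe_maps)) NULL else probe_maps[[i]],
                 verbose = verbose)
  })
  names(deg_tables) <- vapply(studies, `[[`, character(1), "study_id")
  for (i in seq_along(deg_tables)) {
    p <- file.path(out_dir, sprintf("deg_%s.tsv", names(deg_tables)[i]))
    write_deg_table(deg_tables[[i]], p)
    paths[[sprintf("deg_%s", names(deg_tables)[i])]] <- p
  }

  ## core-gene intersection
  core <- intersect_core(deg_tables, config$core_min_fraction,
                         config$require_direction)
  if (nrow(core$genes) == 0L) {
    stopf(paste("core-gene set is empty: no gene is called consistently in",
                "%.0f%% of the studies; relax lfc_threshold/fdr_threshold",
                "or lower core_min_fraction"), 100 * config$core_min_fraction)
  }
  paths$core_genes <- file.path(out_dir, "core_genes.tsv")
  writeLines(c("gene\tdirection\tfrequency",
               paste(core$genes$gene, core$genes$direction,
                     core$genes$frequency, sep = "\t")),
             paths$core_genes, useBytes = TRUE)
  log_stage(verbose, "core", "%d core genes from %d studies",
            nrow(core$genes), length(studies))

  ## standardize + rescale + merge
  merged <- rescale_collection(studies, core, config$rescale_scope)
  paths$merged_matrix <- file.path(out_dir, "merged_rescaled.tsv")
  write_rescaled_matrix(merged, paths$merged_matrix)
  log_stage(verbose, "rescale", "%d genes x %d samples merged",
            nrow(merged$values), ncol(merged$values))

  ## marker selection: AUC ranking under the IHC confirmation rule
  aucs <- auc_table(merged, fold = config$fold_auc)
  if (is.null(ihc_path)) {
    warnf("no IHC count table supplied; treating all core genes as confirmed")
    confirmed <- core$genes$gene
  } else {
    ihc_tab <- if (is.data.frame(ihc_path)) ihc_path else {
      read.delim(ihc_path, header = TRUE, sep = "\t", fileEncoding = "UTF-8")
    }
    conf <- ihc_confirm(ihc_tab, config$ihc_threshold, genes = core$genes$gene)
    confirmed <- conf$confirmed
  }
  markers <- select_markers(aucs, confirmed, config$n_markers)
  paths$markers <- file.path(out_dir, "markers.tsv")
  writeLines(c("gene\tauc\tconfirmed",
               paste(aucs$gene, fmt_num(aucs$auc),
                     ifelse(aucs$gene %in% markers$gene, "selected",
                            ifelse(aucs$gene %in% confirmed, "confirmed", "no")),
                     sep = "\t")),
             paths$markers, useBytes = TRUE)
  log_stage(verbose, "select", "markers: %s", paste(markers$gene, collapse = ", "))

  ## architecture search on the merged marker matrix
  marker_matrix <- rescaled_matrix(
    merged$values[markers$gene, , drop = FALSE], merged$labels, merged$study)
  search <- architecture_search(marker_matrix, config, verbose = verbose)
  paths$model <- file.path(out_dir, "model.txt")
  write_mlp_model(search$best_model, paths$model)
  paths$search_table <- file.path(out_dir, "search_table.tsv")
  st <- search$table
  writeLines(c("arch\tn_layers\tnodes1\tnodes2\tmean_train_acc\tsd_train_acc\tbest_train_acc",
               paste(st$arch, st$n_layers, st$nodes1, st$nodes2,
                     fmt_num(st$mean_train_acc), fmt_num(st$sd_train_acc),
                     fmt_num(st$best_train_acc), sep = "\t")),
             paths$search_table, useBytes = TRUE)

  ## evaluation on the internal split
  x_all <- t(marker_matrix$values)
  evaluate_split <- function(idx) {
    pred <- predict(search$best_model, x_all[idx, , drop = FALSE])
    cm <- confusion(marker_matrix$labels[idx], pred$label)
    list(confusion = cm, sens_spec = sens_spec(cm),
         report = classification_report(cm),
         accuracy = (cm$tn + cm$tp) / (cm$tn + cm$fp + cm$fn + cm$tp))
  }
  train_eval <- evaluate_split(search$split$train)
  test_eval <- evaluate_split(search$split$test)

  ## validation studies: rescale on the marker genes, merge, predict
  validation_eval <- NULL
  if (length(validation) > 0L) {
    vmerged <- rescale_collection(validation, markers$gene, config$rescale_scope)
    vpred <- predict(search$best_model, vmerged)
    vcm <- confusion(vmerged$labels, vpred$label)
    validation_eval <- list(
      confusion = vcm, sens_spec = sens_spec(vcm),
      report = classification_report(vcm),
      accuracy = (vcm$tn + vcm$tp) / (vcm$tn + vcm$fp + vcm$fn + vcm$tp)
    )
    log_stage(verbose, "evaluate", "validation accuracy %.3f",
              validation_eval$accuracy)
  }

  report <- structure(
    list(seed = config$seed, paths = paths,
         n_studies = length(studies), n_validation = length(validation),
         core = core, markers = markers,
         winning_architecture = search$table$arch[search$winner_index],
         search = search,
         train = train_eval, test = test_eval, validation = validation_eval),
    class = "pipeline_report"
  )
  paths$report <- file.path(out_dir, "report.txt")
  write_pipeline_report(report, paths$report)
  report$paths <- paths
  report
}

## flat, deterministic text rendering of the report (no timestamps)
write_pipeline_report <- function(report, path) {
  kv <- list(seed = report$seed,
             n_discovery_studies = report$n_studies,
             n_validation_studies = report$n_validation,
             n_core_genes = nrow(report$core$genes),
             core_genes = report$core$genes$gene,
             markers = report$markers$gene,
             marker_aucs = fmt_num(report$markers$auc),
             winning_architecture = report$winning_architecture)
  add_eval <- function(kv, ev, prefix) {
    cm <- ev$confusion
    kv[[paste0(prefix, "_confusion_tn_fp_fn_tp")]] <- c(cm$tn, cm$fp, cm$fn, cm$tp)
    kv[[paste0(prefix, "_accuracy")]] <- fmt_num(ev$accuracy)
    kv[[paste0(prefix, "_sensitivity_pct")]] <- fmt_num(ev$sens_spec$sensitivity)
    kv[[paste0(prefix, "_specificity_pct")]] <- fmt_num(ev$sens_spec$specificity)
    kv[[paste0(prefix, "_f1_weighted")]] <- fmt_num(ev$report$f1[3])
    kv
  }
  kv <- add_eval(kv, report$train, "train")
  kv <- add_eval(kv, report$test, "test")
  if (!is.null(report$validation)) kv <- add_eval(kv, report$validation, "validation")
  ## artifact names only, so reports from different output directories of
  ## the same run are byte-identical
  for (k in names(report$paths)) {
    kv[[paste0("artifact_", k)]] <- basename(report$paths[[k]])
  }
  write_kv(kv, path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d): %d studies, %d core genes, markers %s\n",
              x$seed, x$n_studies, nrow(x$core$genes),
              paste(x$markers$gene, collapse = ", ")))
  cat(sprintf("  winning architecture %s; train acc %.3f, internal test acc %.3f\n",
              x$winning_architecture, x$train$accuracy, x$test$accuracy))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation: accuracy %.3f, sensitivity %.1f, specificity %.1f\n",
                x$validation$accuracy, x$validation$sens_spec$sensitivity,
                x$validation$sens_spec$specificity))
  }
  invisible(x)
}
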