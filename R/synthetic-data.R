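#' Parameters for the synthetic multi-study expression generator
#'
#' The generator emulates a collection of tumor-versus-normal microarray
#' studies with a planted, direction-consistent core of differentially
#' expressed genes shared by every study, disjoint study-specific DEG sets,
#' per-study baseline shifts (platform differences) and Gaussian noise on the
#' log2 scale. Defaults emulate the shape of a ten-study discovery
#' collection: 40 core genes (39 up, 1 down) and 40 tumor / 20 normal
#' samples per study.
#'
#' @param n_studies number of studies in the collection.
#' @param genes_total total genes simulated per study.
#' @param core_up,core_down planted core genes up-/downregulated in tumors
#'   (`core_down` may be 0).
#' @param study_specific_degs additional planted DEGs private to each study.
#' @param effect_size tumor-minus-normal shift of planted DEGs (log2 units).
#' @param noise_sd sd of the per-cell Gaussian noise (log2 units).
#' @param baseline_mean grand mean log2 intensity.
#' @param study_shift_sd sd of the per-study additive shift (log2 units).
#' @param gene_offset_sd sd of the per-gene baseline offset, drawn once and
#'   shared across studies so a gene is comparable between studies.
#' @param tumor_per_study,normal_per_study samples per class per study.
#' @param seed integer seed; studies are individually re-generable from it.
#' @return a validated list of class `sim_params`.
#' @export
simulation_params <- function(n_studies = 10L, genes_total = 2000L,
                              core_up = 39L, core_down = 1L,
                              study_specific_degs = 50L,
                              effect_size = 2.0, noise_sd = 0.7,
                              baseline_mean = 7.0, study_shift_sd = 0.5,
                              gene_offset_sd = 1.0,
                              tumor_per_study = 40L, normal_per_study = 20L,
                              seed = 1L) {
  stopifnot(
    "n_studies must be >= 1" = is_count(n_studies),
    "genes_total must be >= 1" = is_count(genes_total),
    "core_up must be >= 1" = is_count(core_up),
    "core_down must be >= 0" = is_count(core_down, min = 0L),
    "study_specific_degs must be >= 0" = is_count(study_specific_degs, min = 0L),
    "effect_size must be >= 0" = effect_size >= 0,
    "noise_sd must be >= 0" = noise_sd >= 0,
    "study_shift_sd must be >= 0" = study_shift_sd >= 0,
    "gene_offset_sd must be >= 0" = gene_offset_sd >= 0,
    "tumor_per_study must be >= 1" = is_count(tumor_per_study),
    "normal_per_study must be >= 1" = is_count(normal_per_study),
    "seed must be a single integer" =
      length(seed) == 1 && is.finite(seed) && seed == round(seed)
  )
  if (core_up + core_down + n_studies * study_specific_degs > genes_total) {
    stopf("planted genes (%d core + %d study-specific) exceed genes_total = %d",
          core_up + core_down, n_studies * study_specific_degs, genes_total)
  }
  structure(
    list(n_studies = as.integer(n_studies),
         genes_total = as.integer(genes_total),
         core_up = as.integer(core_up), core_down = as.integer(core_down),
         study_specific_degs = as.integer(study_specific_degs),
         effect_size = effect_size, noise_sd = noise_sd,
         baseline_mean = baseline_mean, study_shift_sd = study_shift_sd,
         gene_offset_sd = gene_offset_sd,
         tumor_per_study = as.integer(tumor_per_study),
         normal_per_study = as.integer(normal_per_study),
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Draw the ground truth shared by all studies of a collection
#'
#' Chooses the core gene identities and directions, the disjoint per-study
#' specific DEG sets (random sign), per-gene baseline offsets (drawn once,
#' shared by all studies) and per-study additive shifts. Deterministic given
#' `params$seed`.
#'
#' @param params a [simulation_params()] object.
#' @return a list of class `ground_truth` with elements `gene_ids`, `core`
#'   (data.frame gene/direction), `core_sign` (named +1/-1), `specific`
#'   (per-study list of named sign vectors), `offsets`, `shifts`.
#' @export
make_ground_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  G <- params$genes_total
  gene_ids <- paste0("g", formatC(seq_len(G), width = nchar(G), flag = "0"))

  n_core <- params$core_up + params$core_down
  core_idx <- sample.int(G, n_core)
  core_sign <- rep(c(1, -1), c(params$core_up, params$core_down))
  names(core_sign) <- gene_ids[core_idx]

  remaining <- setdiff(seq_len(G), core_idx)
  specific <- vector("list", params$n_studies)
  k <- params$study_specific_degs
  if (k > 0L) {
    picked <- sample(remaining, params$n_studies * k)
    for (i in seq_len(params$n_studies)) {
      idx <- picked[((i - 1L) * k + 1L):(i * k)]
      sgn <- sample(c(1, -1), k, replace = TRUE)
      names(sgn) <- gene_ids[idx]
      specific[[i]] <- sgn
    }
  } else {
    specific <- rep(list(stats::setNames(numeric(0), character(0))),
                    params$n_studies)
  }

  offsets <- stats::setNames(rnorm(G, 0, params$gene_offset_sd), gene_ids)
  shifts <- rnorm(params$n_studies, 0, params$study_shift_sd)

  structure(
    list(gene_ids = gene_ids,
         core = data.frame(gene = names(core_sign),
                           direction = ifelse(core_sign > 0, "up", "down"),
                           stringsAsFactors = FALSE),
         core_sign = core_sign, specific = specific,
         offsets = offsets, shifts = shifts),
    class = "ground_truth"
  )
}

#' Generate one synthetic study of a collection
#'
#' Each cell is `baseline_mean + study_shift + gene_offset +
#' sign * effect_size * is_tumor + N(0, noise_sd)`, where the signed effect
#' applies to the planted core genes (same sign in every study) and to that
#' study's private DEG set. Deterministic given the params seed and the
#' study index (each study draws from its own derived seed, so a single
#' study can be regenerated without the rest of the collection).
#'
#' @param params a [simulation_params()] object.
#' @param study_index which study to generate, in `1..n_studies`.
#' @param truth the collection's [make_ground_truth()] output.
#' @return an [expression_study()].
#' @export
generate_study <- function(params, study_index, truth) {
  stopifnot(inherits(params, "sim_params"), inherits(truth, "ground_truth"))
  if (!is_count(study_index) || study_index > params$n_studies) {
    stopf("study_index must be in 1..%d", params$n_studies)
  }
  set.seed(seed_hash(params$seed, study_index, 1L))
  G <- params$genes_total
  n_t <- params$tumor_per_study
  n_n <- params$normal_per_study
  n <- n_t + n_n
  labels <- rep(c("tumor", "normal"), c(n_t, n_n))

  deg_sign <- stats::setNames(numeric(G), truth$gene_ids)
  deg_sign[names(truth$core_sign)] <- truth$core_sign
  spec <- truth$specific[[study_index]]
  deg_sign[names(spec)] <- spec

  base <- params$baseline_mean + truth$shifts[study_index] + truth$offsets
  m <- matrix(base, nrow = G, ncol = n)
  m <- m + outer(deg_sign * params$effect_size, as.numeric(labels == "tumor"))
  m <- m + matrix(rnorm(G * n, 0, params$noise_sd), nrow = G)

  study_id <- sprintf("S%02d", study_index)
  colnames(m) <- sprintf("%s_%s%02d", study_id,
                         ifelse(labels == "tumor", "T", "N"),
                         c(seq_len(n_t), seq_len(n_n)))
  rownames(m) <- truth$gene_ids
  expression_study(m, labels, study_id = study_id)
}

#' Generate a full synthetic study collection plus its ground truth
#'
#' @param params a [simulation_params()] object.
#' @return list with `studies` (list of [expression_study()]) and `truth`
#'   (the [make_ground_truth()] object).
#' @export
generate_collection <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  truth <- make_ground_truth(params)
  studies <- lapply(seq_len(params$n_studies), function(i) {
    generate_study(params, i, truth)
  })
  list(studies = studies, truth = truth)
}

#' Synthetic immunohistochemistry staining-category counts
#'
#' Emulates a per-gene count table of IHC staining images over the
#' categories high / medium / low / not detected. A `confirm_fraction`
#' share of genes (rounded to the nearest count) is constructed to pass the
#' confirmation rule `high + medium >= threshold * images`; the rest fall
#' below it. Category counts always sum to `images_per_gene`.
#'
#' @param gene_ids genes to tabulate.
#' @param confirm_fraction share of genes built to pass the rule.
#' @param images_per_gene images per gene (>= 1).
#' @param seed integer seed.
#' @param threshold confirmation threshold on the high+medium fraction.
#' @return data.frame with columns `gene`, `high`, `medium`, `low`,
#'   `not_detected`.
#' @export
generate_ihc_counts <- function(gene_ids, confirm_fraction = 0.35,
                                images_per_gene = 12L, seed = 1L,
                                threshold = 0.75) {
  stopifnot(
    "images_per_gene must be >= 1" = is_count(images_per_gene),
    "confirm_fraction must be in [0, 1]" =
      confirm_fraction >= 0 && confirm_fraction <= 1,
    "threshold must be in (0, 1]" = threshold > 0 && threshold <= 1
  )
  gene_ids <- as.character(gene_ids)
  n <- length(gene_ids)
  m <- as.integer(images_per_gene)
  set.seed(seed)
  n_pass <- round(confirm_fraction * n)
  pass <- rep(FALSE, n)
  if (n_pass > 0L) pass[sample.int(n, n_pass)] <- TRUE

  hm_min <- as.integer(ceiling(threshold * m))  # smallest passing count
  hm <- integer(n)
  for (i in seq_len(n)) {
    hm[i] <- if (pass[i]) {
      if (hm_min >= m) m else sample(hm_min:m, 1L)
    } else {
      if (hm_min <= 1L) 0L else sample(0:(hm_min - 1L), 1L)
    }
  }
  high <- vapply(hm, function(h) if (h > 0L) sample(0:h, 1L) else 0L, integer(1))
  rest <- m - hm
  low <- vapply(rest, function(r) if (r > 0L) sample(0:r, 1L) else 0L, integer(1))
  data.frame(gene = gene_ids, high = high, medium = hm - high,
             low = low, not_detected = rest - low,
             stringsAsFactors = FALSE)
}

#' Expand a study to probe level by duplicating rows
#'
#' Utility to exercise probe collapse: a fraction of genes gets a second
#' probe row (original values plus small Gaussian jitter). Probe identifiers
#' are `<gene>_p1`, `<gene>_p2`; the returned map links probes to genes.
#'
#' @param study an [expression_study()].
#' @param dup_fraction fraction of genes receiving a duplicate probe.
#' @param jitter_sd sd of the jitter added to duplicated rows (log2 units).
#' @param seed integer seed.
#' @return list with `study` (probe-level [expression_study()]) and
#'   `probe_to_gene` (named character vector, probe -> gene).
#' @export
probe_level_study <- function(study, dup_fraction = 0.2, jitter_sd = 0.1,
                              seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  set.seed(seed)
  G <- nrow(study$values)
  dup <- sort(sample.int(G, round(dup_fraction * G)))
  v1 <- study$values
  rownames(v1) <- paste0(study$gene_ids, "_p1")
  v2 <- study$values[dup, , drop = FALSE] +
    matrix(rnorm(length(dup) * ncol(v1), 0, jitter_sd), nrow = length(dup))
  rownames(v2) <- paste0(study$gene_ids[dup], "_p2")
  values <- rbind(v1, v2)
  map <- stats::setNames(c(study$gene_ids, study$gene_ids[dup]),
                         rownames(values))
  list(
    study = expression_study(values, study$labels,
                             study_id = paste0(study$study_id, "_probes")),
    probe_to_gene = map
  )
}
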