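#' Remove genes with (near-)zero expression variation
#'
#' Non-specific filtering step: keeps genes whose sample variance exceeds
#' `epsilon`. The default `epsilon = 0` removes exactly the genes with no
#' expression variation among samples.
#'
#' @param study an [expression_study()].
#' @param epsilon variance threshold (log2-squared units), `>= 0`.
#' @return the filtered [expression_study()], gene order preserved.
#' @export
variance_filter <- function(study, epsilon = 0) {
  stopifnot(inherits(study, "expression_study"), epsilon >= 0)
  v <- row_var(study$values)
  keep <- v > epsilon
  if (!any(keep)) stopf("variance filter removed all %d genes", length(keep))
  expression_study(study$values[keep, , drop = FALSE], study$labels,
                   study_id = study$study_id,
                   gene_ids = study$gene_ids[keep])
}

#' Collapse multiple probes per gene to a single representative row
#'
#' The representative probe for each gene is the one with the maximum mean
#' expression over all samples (the MaxMean rule); its row is carried over
#' verbatim. Ties are broken toward the lexicographically smallest probe
#' identifier. Probes without a mapping entry are dropped with a warning.
#'
#' @param study probe-level [expression_study()].
#' @param probe_to_gene named character vector (names = probe ids) or a
#'   two-column data.frame (probe, gene).
#' @return gene-level [expression_study()], one row per mapped gene, in
#'   order of first appearance of each gene among the retained probes.
#' @export
collapse_probes <- function(study, probe_to_gene) {
  stopifnot(inherits(study, "expression_study"))
  if (is.data.frame(probe_to_gene)) {
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2]]),
                                     as.character(probe_to_gene[[1]]))
  }
  if (length(probe_to_gene) == 0L) stopf("probe-to-gene mapping is empty")

  probes <- study$gene_ids
  mapped <- probes %in% names(probe_to_gene)
  if (!any(mapped)) stopf("no probe of study '%s' has a mapping entry", study$study_id)
  if (!all(mapped)) {
    warnf("dropping %d unmapped probe(s) in study '%s'",
          sum(!mapped), study$study_id)
  }
  values <- study$values[mapped, , drop = FALSE]
  probes <- probes[mapped]
  genes <- unname(probe_to_gene[probes])

  means <- rowMeans(values)
  ## per gene: max mean, tie -> smallest probe id
  ord <- order(genes, -means, probes)
  first <- !duplicated(genes[ord])
  pick <- ord[first]
  pick <- pick[order(match(genes[pick], unique(genes)))]  # first-appearance order

  out <- values[pick, , drop = FALSE]
  expression_study(out, study$labels, study_id = study$study_id,
                   gene_ids = genes[pick])
}

#' Two-group differential-expression statistics per gene
#'
#' Computes per-gene `log2fc = mean(tumor) - mean(normal)` and a two-sided
#' t-test, either Welch (Satterthwaite degrees of freedom, unequal
#' variances) or an empirical-Bayes moderated t: the pooled per-gene
#' variance `s_g^2` (df `d_g = n - 2`) is shrunk toward a prior
#' `s_tilde_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, with `(d0, s0^2)`
#' fitted by moment-matching on `log s_g^2` (the Newton-based trigamma
#' inversion of the standard scaled-F fit), and the t-statistic referred to
#' `d0 + d_g` degrees of freedom.
#'
#' @param study an [expression_study()] with `>= 2` samples per class.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return a `deg_table` data.frame: `gene`, `log2fc`, `t_stat`, `p_value`,
#'   `adj_p` (NA until [benjamini_hochberg()] is applied), `call` ("none").
#' @export
two_group_stat <- function(study, method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(study, "expression_study"))
  check_two_classes(study, 2L)
  if (!all(is.finite(study$values))) stopf("non-finite expression values")

  tum <- study$values[, study$labels == "tumor", drop = FALSE]
  nor <- study$values[, study$labels == "normal", drop = FALSE]
  n1 <- ncol(tum); n0 <- ncol(nor)
  m1 <- rowMeans(tum); m0 <- rowMeans(nor)
  v1 <- row_var(tum); v0 <- row_var(nor)
  lfc <- m1 - m0

  if (method == "welch") {
    se2 <- v1 / n1 + v0 / n0
    t_stat <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * pt(-abs(t_stat), df)
    degen <- se2 == 0
    if (any(degen)) {
      warnf("%d gene(s) with zero within-group variance; p set to 0/1 by mean difference",
            sum(degen))
      t_stat[degen] <- sign(lfc[degen]) * Inf
      t_stat[degen & lfc == 0] <- 0
      p[degen] <- ifelse(lfc[degen] != 0, 0, 1)
    }
  } else {
    dg <- n1 + n0 - 2
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / dg
    fit <- fit_variance_prior(s2, dg)
    s2_tilde <- (fit$d0 * fit$s0 + dg * fit$s2) / (fit$d0 + dg)
    if (!is.finite(fit$d0)) s2_tilde <- rep(fit$s0, length(s2))
    t_stat <- lfc / sqrt(s2_tilde * (1 / n1 + 1 / n0))
    ## total df capped at the pooled residual df over all genes
    df_total <- min(fit$d0 + dg, length(s2) * dg)
    p <- if (is.finite(df_total)) 2 * pt(-abs(t_stat), df_total)
         else 2 * stats::pnorm(-abs(t_stat))
  }

  data.frame(gene = study$gene_ids, log2fc = unname(lfc),
             t_stat = unname(t_stat), p_value = unname(p),
             adj_p = NA_real_, call = "none", stringsAsFactors = FALSE)
}

## Moment-matching fit of the inverse-chi-square variance prior on
## z = log s^2: E z and Var z identities for log chi-square give
##   e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2),
##   Var e = trigamma(d_g/2) + trigamma(d0/2),
## solved for d0 by Newton inversion of the trigamma function.
## Degenerate inputs: sample variances are floored at 1e-5 * median; if the
## excess variance of e is <= 0 the prior df is infinite and s0^2 = mean(s^2).
fit_variance_prior <- function(s2, dg) {
  n <- length(s2)
  if (n < 2L) return(list(d0 = 0, s0 = s2[1], s2 = s2))
  med <- median(s2)
  if (med == 0) {
    warnf("more than half of the per-gene variances are exactly zero")
    med <- 1
  }
  s2 <- pmax(s2, 1e-5 * med)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- mean(s2)
  }
  list(d0 = d0, s0 = s0, s2 = s2)
}

## Newton solve of trigamma(y) = x for y > 0, vectorized.
trigamma_inverse <- function(x) {
  if (any(x < 0)) stopf("trigamma_inverse needs non-negative input")
  y <- 0.5 + 1 / x
  big <- x > 1e7;  y[big] <- 1 / sqrt(x[big])
  small <- x < 1e-6; y[small] <- 1 / x[small]
  solve_idx <- which(!big & !small)
  for (iter in 1:50) {
    if (length(solve_idx) == 0L) break
    tri <- trigamma(y[solve_idx])
    dif <- tri * (1 - tri / x[solve_idx]) / psigamma(y[solve_idx], deriv = 2)
    y[solve_idx] <- y[solve_idx] + dif
    done <- -dif / y[solve_idx] < 1e-8
    solve_idx <- solve_idx[!done]
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' On the sorted scale, `adj_(i) = min(1, min_{j >= i} p_(j) * m / j)`,
#' mapped back to the input order. Monotone non-decreasing on sorted
#' p-values; ties receive equal adjusted values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; exact zeros are
#'   floored at the smallest positive double before adjusting so ordering
#'   stays well defined.
#' @return adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values))) stopf("NA/NaN p-values are not allowed")
  if (any(p_values < 0 | p_values > 1)) stopf("p-values must lie in [0, 1]")
  p <- pmax(p_values, .Machine$double.xmin)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Assign up/down/none DEG calls
#'
#' `call = "up"` iff `log2fc >= lfc_threshold` and `adj_p <= fdr_threshold`;
#' `"down"` symmetrically at `log2fc <= -lfc_threshold`. The fold-change
#' gate is on the absolute value; the sign gives the direction.
#'
#' @param table a `deg_table` with `adj_p` populated.
#' @param lfc_threshold absolute log2 fold-change gate.
#' @param fdr_threshold adjusted-p gate.
#' @return the table with `call` filled in.
#' @export
call_degs <- function(table, lfc_threshold = 1.0, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("log2fc", "adj_p") %in% names(table)))
  if (any(is.na(table$adj_p))) stopf("adj_p not populated; run benjamini_hochberg first")
  call <- rep("none", nrow(table))
  sig <- table$adj_p <= fdr_threshold
  call[sig & table$log2fc >= lfc_threshold] <- "up"
  call[sig & table$log2fc <= -lfc_threshold] <- "down"
  table$call <- call
  table
}

#' Full single-study DEG analysis
#'
#' Variance filter, optional probe collapse, two-group statistic, BH
#' adjustment and threshold calls, in that order.
#'
#' @param study an [expression_study()].
#' @param config a [run_config()].
#' @param probe_to_gene optional probe map passed to [collapse_probes()].
#' @param verbose log one line with dimensions and timing.
#' @return a called `deg_table`.
#' @export
deg_analysis <- function(study, config = run_config(), probe_to_gene = NULL,
                         verbose = FALSE) {
  t0 <- as.numeric(proc.time()[["elapsed"]])
  filtered <- variance_filter(study, config$variance_epsilon)
  if (!is.null(probe_to_gene)) filtered <- collapse_probes(filtered, probe_to_gene)
  tab <- two_group_stat(filtered, config$deg_method)
  tab$adj_p <- benjamini_hochberg(tab$p_value)
  tab <- call_degs(tab, config$lfc_threshold, config$fdr_threshold)
  log_stage(verbose, "deg", "study %s: %d -> %d genes, %d up / %d down",
            study$study_id, nrow(study$values), nrow(tab),
            sum(tab$call == "up"), sum(tab$call == "down"), t0 = t0)
  tab
}
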