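test_that("variance filter removes exactly the no-variation genes", {
  s <- tiny_study(c(1, 1, 1, 1,
                    1, 2, 3, 4,
                    5, 5, 6, 6),
                  rep(c("tumor", "normal"), each = 2),
                  genes = c("flat", "g1", "g2"))
  out <- variance_filter(s, 0)
  expect_equal(out$gene_ids, c("g1", "g2"))

  noisy <- random_study(50, 3, 3, seed = 1)
  expect_equal(nrow(variance_filter(noisy, 0)$values), 50L)

  ## epsilon at the max row variance: only strictly larger rows survive
  v <- apply(noisy$values, 1, var)
  eps <- sort(v)[25]
  expect_equal(variance_filter(noisy, eps)$gene_ids,
               noisy$gene_ids[v > eps])
  expect_error(variance_filter(noisy, max(v)), "removed all")
})

test_that("probe collapse applies the MaxMean rule with a lexicographic tie-break", {
  s <- tiny_study(c(5, 5, 5, 5,
                    7, 7, 7, 7,
                    1, 2, 3, 4),
                  rep(c("tumor", "normal"), each = 2),
                  genes = c("pA", "pB", "pC"))
  map <- c(pA = "G", pB = "G", pC = "H")
  out <- collapse_probes(s, map)
  expect_equal(out$gene_ids, c("G", "H"))
  expect_equal(unname(out$values["G", ]), rep(7, 4))  # higher-mean probe, verbatim

  ## tie in means -> smallest probe id wins
  tie <- tiny_study(c(1, 2, 3, 4,
                      4, 3, 2, 1),
                    rep(c("tumor", "normal"), each = 2),
                    genes = c("p2", "p1"))
  out_tie <- collapse_probes(tie, c(p1 = "G", p2 = "G"))
  expect_equal(unname(out_tie$values["G", ]), c(4, 3, 2, 1))

  ## all-distinct mapping is identity up to renaming
  distinct <- collapse_probes(s, c(pA = "a", pB = "b", pC = "c"))
  expect_equal(unname(distinct$values), unname(s$values))

  expect_warning(collapse_probes(s, c(pA = "G", pB = "G")), "unmapped")
  expect_error(collapse_probes(s, character(0)), "empty")
})

test_that("Welch statistics match the reference routine to 1e-9", {
  s <- tiny_study(c(1, 2, 3, 4, 5, 6), rep(c("tumor", "normal"), each = 3))
  tab <- two_group_stat(s, "welch")
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tab$t_stat, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(tab$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(tab$log2fc, -3)

  for (seed in 1:20) {
    rs <- random_study(1, n_tumor = 3 + seed %% 4, n_normal = 5, seed = seed)
    got <- two_group_stat(rs, "welch")
    want <- t.test(rs$values[1, rs$labels == "tumor"],
                   rs$values[1, rs$labels == "normal"])
    expect_equal(got$t_stat, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
  }
})

test_that("identical class distributions give t = 0, p = 1", {
  vals <- c(1.3, 2.1, 0.7, 1.3, 2.1, 0.7)
  s <- tiny_study(rep(vals, 3), rep(c("tumor", "normal"), each = 3),
                  genes = c("a", "b", "c"))
  tab <- two_group_stat(s, "welch")
  expect_equal(tab$t_stat, rep(0, 3))
  expect_equal(tab$p_value, rep(1, 3))
})

test_that("equal per-gene variances make the moderated t the pooled t", {
  offsets <- c(-1, 0, 1, -1, 0, 1)  # same within-group spread for every gene
  base <- matrix(rep(offsets, each = 10), nrow = 10, byrow = FALSE)
  shift <- seq(0.1, 1, length.out = 10)
  m <- base + outer(shift, c(1, 1, 1, 0, 0, 0))
  rownames(m) <- sprintf("g%02d", 1:10)
  colnames(m) <- sprintf("s%d", 1:6)
  s <- expression_study(m, rep(c("tumor", "normal"), each = 3))
  tab <- two_group_stat(s, "moderated")
  pooled_t <- vapply(seq_len(10), function(i) {
    x <- m[i, 1:3]; y <- m[i, 4:6]
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
    (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  }, numeric(1))
  expect_equal(tab$t_stat, pooled_t, tolerance = 1e-10)
})

test_that("moderated statistics agree with the empirical-Bayes reference (limma)", {
  skip_if_not_installed("limma")
  s <- random_study(200, 8, 6, seed = 13)
  s$values <- s$values + outer(rnorm(200, 0, 0.5), rep(1, 14))  # vary baselines
  tab <- two_group_stat(s, "moderated")
  design <- cbind(intercept = 1, tumor = as.integer(s$labels == "tumor"))
  fit <- limma::eBayes(limma::lmFit(s$values, design))
  expect_equal(tab$t_stat, unname(fit$t[, "tumor"]), tolerance = 1e-8)
  expect_equal(tab$p_value, unname(fit$p.value[, "tumor"]), tolerance = 1e-8)
})

test_that("moderated and Welch t always share a sign", {
  s <- random_study(300, 6, 5, seed = 4)
  tm <- two_group_stat(s, "moderated")$t_stat
  tw <- two_group_stat(s, "welch")$t_stat
  expect_true(all(sign(tm) == sign(tw)))
})

test_that("Benjamini-Hochberg equals its definition and the stats reference", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.02)),
               rep(0.04, 4))
  ## ties get equal adjusted values
  adj <- benjamini_hochberg(c(0.02, 0.05, 0.02, 0.9))
  expect_equal(adj[1], adj[3])

  set.seed(7)
  for (n in 1:8) {
    for (rep in 1:25) {
      p <- round(runif(n), 3)  # rounding forces ties
      expect_equal(benjamini_hochberg(p), bh_brute(p))
      expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
    }
  }
  expect_error(benjamini_hochberg(c(0.1, NaN)), "NA/NaN")
  ## adjusted never below raw
  set.seed(8)
  p <- runif(100)
  expect_true(all(benjamini_hochberg(p) >= p))
})

test_that("DEG calls gate on |log2FC| and adjusted p simultaneously", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.2, -1.5, 0.99, 1.7),
                    t_stat = 0,
                    p_value = c(0.001, 0.001, 1e-9, 0.2),
                    adj_p = c(0.01, 0.04, 1e-9, 0.3),
                    call = "none", stringsAsFactors = FALSE)
  out <- call_degs(tab, lfc_threshold = 1, fdr_threshold = 0.05)
  expect_equal(out$call, c("up", "down", "none", "none"))
})
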