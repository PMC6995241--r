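test_that("a generated study honours the dimension and composition contract", {
  params <- simulation_params()
  truth <- make_ground_truth(params)
  s <- generate_study(params, 1, truth)
  expect_equal(dim(s), c(2000L, 60L))
  expect_equal(sum(s$labels == "tumor"), 40L)
  expect_equal(sum(s$labels == "normal"), 20L)
  expect_error(generate_study(params, 11, truth), "study_index")
})

test_that("a collection shares core genes, keeps specific sets disjoint, and is seed-deterministic", {
  params <- simulation_params(n_studies = 4, genes_total = 400,
                              study_specific_degs = 20, seed = 42)
  coll <- generate_collection(params)
  expect_length(coll$studies, 4L)
  expect_equal(sum(vapply(coll$studies, function(s) sum(s$labels == "tumor"),
                          numeric(1))), 4 * 40)
  expect_equal(sum(vapply(coll$studies, function(s) sum(s$labels == "normal"),
                          numeric(1))), 4 * 20)
  expect_equal(nrow(coll$truth$core), 40L)
  spec_ids <- lapply(coll$truth$specific, names)
  expect_equal(anyDuplicated(unlist(spec_ids)), 0L)
  expect_length(intersect(unlist(spec_ids), coll$truth$core$gene), 0L)

  again <- generate_collection(params)
  expect_identical(coll$studies[[3]]$values, again$studies[[3]]$values)

  ## a single study is regenerable without the rest of the collection
  expect_identical(generate_study(params, 2, coll$truth)$values,
                   coll$studies[[2]]$values)
})

test_that("the noiseless limit plants the effect exactly", {
  params <- simulation_params(n_studies = 2, genes_total = 100, core_up = 5,
                              core_down = 2, study_specific_degs = 5,
                              noise_sd = 0, effect_size = 2, seed = 3)
  coll <- generate_collection(params)
  s <- coll$studies[[1]]
  tum <- s$values[, s$labels == "tumor", drop = FALSE]
  nor <- s$values[, s$labels == "normal", drop = FALSE]
  diff <- rowMeans(tum) - rowMeans(nor)
  core <- coll$truth$core
  expect_equal(unname(diff[core$gene[core$direction == "up"]]),
               rep(2, 5), tolerance = 1e-12)
  expect_equal(unname(diff[core$gene[core$direction == "down"]]),
               rep(-2, 2), tolerance = 1e-12)
  bystanders <- setdiff(rownames(s$values),
                        c(core$gene, names(coll$truth$specific[[1]])))
  expect_equal(max(abs(diff[bystanders])), 0)
})

test_that("planted effects are recovered within sampling error under noise", {
  params <- simulation_params(n_studies = 2, genes_total = 500, seed = 9)
  coll <- generate_collection(params)
  se <- params$noise_sd * sqrt(1 / params$tumor_per_study +
                               1 / params$normal_per_study)
  for (s in coll$studies) {
    tum <- s$values[, s$labels == "tumor", drop = FALSE]
    nor <- s$values[, s$labels == "normal", drop = FALSE]
    diff <- rowMeans(tum) - rowMeans(nor)
    up <- coll$truth$core$gene[coll$truth$core$direction == "up"]
    ## 3.3-sigma bound per gene; 39 up-genes x 2 studies checked
    expect_true(all(abs(diff[up] - params$effect_size) < 3.3 * se))
  }
})

test_that("a null collection (no effect) yields FDR-controlled DEG calls", {
  params <- simulation_params(n_studies = 1, genes_total = 2000,
                              effect_size = 0, study_specific_degs = 0,
                              seed = 21)
  s <- generate_collection(params)$studies[[1]]
  tab <- deg_analysis(s, run_config())
  ## fold-change + FDR gates: essentially nothing survives
  expect_lte(sum(tab$call != "none"), 2L)
  ## raw p-values are uniform: ~5% below 0.05 (binomial 3.3-sigma band)
  frac <- mean(tab$p_value <= 0.05)
  expect_lt(abs(frac - 0.05), 3.3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("synthetic IHC counts hit the requested confirmation composition", {
  genes <- sprintf("g%02d", 1:40)
  tab <- generate_ihc_counts(genes, confirm_fraction = 0.35,
                             images_per_gene = 12, seed = 5)
  expect_equal(nrow(tab), 40L)
  expect_true(all(rowSums(tab[, -1]) == 12))
  conf <- ihc_confirm(tab, 0.75)
  expect_length(conf$confirmed, 14L)

  all_pass <- generate_ihc_counts(genes, confirm_fraction = 1,
                                  images_per_gene = 10, seed = 5)
  expect_length(ihc_confirm(all_pass, 0.75)$confirmed, 40L)

  ## the smallest passing count sits exactly on the >= boundary
  few <- generate_ihc_counts(genes, confirm_fraction = 1,
                             images_per_gene = 12, seed = 7)
  expect_true(all((few$high + few$medium) >= 9))
})

test_that("probe-level duplication plus collapse recovers one row per gene", {
  s <- random_study(30, 4, 4, seed = 11)
  pl <- probe_level_study(s, dup_fraction = 0.5, seed = 2)
  expect_gt(nrow(pl$study$values), nrow(s$values))
  collapsed <- collapse_probes(pl$study, pl$probe_to_gene)
  expect_setequal(collapsed$gene_ids, s$gene_ids)
  expect_equal(anyDuplicated(collapsed$gene_ids), 0L)
})
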