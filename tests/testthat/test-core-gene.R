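test_that("core intersection applies frequency and direction rules", {
  t1 <- fake_deg_table(c("a", "b", "c"), c("up", "up", "down"))
  t2 <- fake_deg_table(c("a", "b", "d"), c("up", "down", "up"))
  t3 <- fake_deg_table(c("a", "b"), c("up", "up"))

  single <- intersect_core(list(t1))
  expect_equal(single$genes$gene, c("a", "b", "c"))

  ## 'a' in 3/3, 'b' direction-conflicted, others below threshold
  all3 <- intersect_core(list(t1, t2, t3), min_fraction = 1)
  expect_equal(all3$genes$gene, "a")
  expect_equal(all3$genes$direction, "up")

  ## without direction requirement 'b' (3/3 studies) enters too
  nodir <- intersect_core(list(t1, t2, t3), min_fraction = 1,
                          require_direction = FALSE)
  expect_setequal(nodir$genes$gene, c("a", "b"))

  ## gene called in 9/10 studies: excluded at 1.0, included at 0.9
  tabs <- c(replicate(9, fake_deg_table("g", "up"), simplify = FALSE),
            list(fake_deg_table("h", "up")))
  expect_false("g" %in% intersect_core(tabs, 1.0)$genes$gene)
  expect_true("g" %in% intersect_core(tabs, 0.9)$genes$gene)

  ## empty result is a valid empty set
  empty <- intersect_core(list(fake_deg_table("x", "up"),
                               fake_deg_table("y", "up")), 1.0)
  expect_equal(nrow(empty$genes), 0L)
})

test_that("core set size is non-increasing in min_fraction", {
  set.seed(31)
  tabs <- lapply(1:6, function(i) {
    genes <- sample(sprintf("g%02d", 1:30), 15)
    fake_deg_table(genes, sample(c("up", "down"), 15, replace = TRUE))
  })
  sizes <- vapply(seq(0.1, 1, by = 0.1), function(f) {
    nrow(intersect_core(tabs, f)$genes)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("standardize + min-max rescale maps rows onto [0, 1]", {
  s <- tiny_study(c(1, 2, 3), c("tumor", "tumor", "normal"))
  out <- standardize_rescale(s, "g1")
  expect_equal(unname(out$values[1, ]), c(0, 0.5, 1))

  const <- tiny_study(c(4, 4, 4), c("tumor", "tumor", "normal"))
  expect_warning(out_c <- standardize_rescale(const, "g1"), "zero-variance")
  expect_equal(unname(out_c$values[1, ]), rep(0.5, 3))

  ## invariance under positive affine transforms of the input row
  set.seed(5)
  row <- rnorm(12)
  a <- tiny_study(row, rep(c("tumor", "normal"), 6))
  b <- tiny_study(3.7 * row + 11, rep(c("tumor", "normal"), 6))
  expect_equal(standardize_rescale(a, "g1")$values,
               standardize_rescale(b, "g1")$values, tolerance = 1e-12)

  ## idempotence up to floating tolerance
  s2 <- random_study(5, 4, 4, seed = 2)
  once <- standardize_rescale(s2, s2$gene_ids)
  study_once <- expression_study(once$values, once$labels, "again")
  twice <- standardize_rescale(study_once, s2$gene_ids)
  expect_equal(twice$values, once$values, tolerance = 1e-12)

  expect_warning(standardize_rescale(s2, c(s2$gene_ids, "absent")), "not present")
  expect_error(standardize_rescale(s2, "absent"), "none of the")
})

test_that("merging concatenates columns and keeps values in [0, 1]", {
  s1 <- random_study(5, 3, 3, seed = 1, id = "A")
  s2 <- random_study(5, 2, 3, seed = 2, id = "B")
  r1 <- standardize_rescale(s1, s1$gene_ids)
  r2 <- standardize_rescale(s2, s2$gene_ids)
  merged <- merge_studies(list(r1, r2))
  expect_equal(dim(merged$values), c(5L, 11L))
  expect_equal(merged$study, rep(c("A", "B"), c(6, 5)))
  expect_true(all(merged$values >= 0 & merged$values <= 1))

  ## duplicate sample ids get suffixed with the study id
  expect_equal(anyDuplicated(colnames(merged$values)), 0L)
  expect_true(any(grepl("\\.A$", colnames(merged$values))))

  ## disjoint gene sets cannot merge
  s3 <- random_study(5, 2, 2, seed = 3)
  s3$gene_ids <- paste0("other_", s3$gene_ids)
  rownames(s3$values) <- s3$gene_ids
  r3 <- standardize_rescale(s3, s3$gene_ids)
  expect_error(merge_studies(list(r1, r3)), "no genes")
})

test_that("the planted core is recovered from a synthetic collection", {
  params <- simulation_params(n_studies = 5, genes_total = 800,
                              study_specific_degs = 30, seed = 17)
  coll <- generate_collection(params)
  cfg <- run_config()
  tabs <- lapply(coll$studies, deg_analysis, config = cfg)
  core <- intersect_core(tabs, cfg$core_min_fraction)
  planted <- coll$truth$core$gene
  expect_gte(length(intersect(core$genes$gene, planted)) / length(planted), 0.95)
  specific <- unlist(lapply(coll$truth$specific, names))
  expect_length(intersect(core$genes$gene, specific), 0L)
  ## symmetric difference within 5% of the planted core size
  expect_lte(length(union(setdiff(core$genes$gene, planted),
                          setdiff(planted, core$genes$gene))) / length(planted),
             0.05)
  ## directions recovered
  rec <- merge(core$genes, coll$truth$core, by = "gene")
  expect_true(all(rec$direction.x == rec$direction.y))
})
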