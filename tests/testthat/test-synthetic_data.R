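test_that("simulate_genome plants what the truth record says it plants", {
  sim <- simulate_genome(n_family_genes = 60L, n_background_genes = 400L,
                         n_unanchored = 3L,
                         tandem_spec = data.frame(size = 2L, count = 1L),
                         seed = 21)
  tg <- sim$truth$genes
  expect_equal(nrow(tg), 60L)
  # emitted label counts match the recorded multinomial draw
  expect_equal(unname(table(factor(tg$subfamily,
                                   levels = names(sim$truth$subfamily_counts)))),
               unname(sim$truth$subfamily_counts), ignore_attr = TRUE)
  # exactly one planted pair, recovered with <= 3 intervening genes
  arr <- detect_tandem_arrays(sim$genes, tg$gene_id)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$size, 2L)
  expect_equal(arr$members, sim$truth$arrays$members)
  # every planted label refers to an emitted gene
  expect_true(all(tg$gene_id %in% sim$genes$gene_id))
  expect_true(all(na.omit(tg$ortholog_ref) %in% sim$references$gene_id))
  expect_equal(sum(!tg$anchored), 3L)
})

test_that("the generator is byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(d1, seed = 4)
  simulate_dataset(d2, seed = 4)
  for (f in c("proteins.fasta", "genes.gff3", "tissues.tsv", "qpcr.tsv",
              "truth.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = f)
})

test_that("generator guards its budgets and inputs", {
  expect_error(simulate_genome(n_family_genes = 5L,
                               tandem_spec = data.frame(size = 4L,
                                                        count = 10L)),
               "exceed")
  expect_error(simulate_genome(subfamily_mix = c("1R" = 0.5)), "sum to 1")
  expect_error(simulate_genome(tandem_spec = data.frame(size = 7L,
                                                        count = 1L)),
               "2..4")
  sim <- simulate_genome(n_family_genes = 40L, seed = 2,
                         n_background_genes = 300L, n_unanchored = 2L,
                         tandem_spec = data.frame(size = 2L, count = 1L))
  spec <- default_tissue_spec()
  spec$specific <- c(brain = 1L)
  expect_error(simulate_expression(sim$truth, tissue_spec = spec),
               "unknown tissue|allocates")
  expect_error(simulate_qpcr("g1", -2), "positive")
})

test_that("planted expression patterns survive the stated noise", {
  sim <- simulate_genome(seed = 31)
  expr <- simulate_expression(sim$truth, noise_sd = 0.2, seed = 31)
  tg <- expr$truth$genes
  # genes planted in all five tissues exceed RPKM 1 everywhere
  common <- tg$gene_id[tg$tissue_pattern ==
                         paste(genefam:::TISSUES, collapse = ",")]
  expect_gt(length(common), 0)
  expect_true(all(expr$tissues[common, ] > 1))
  # waterlogging group I: fold change vs control > 2 at 9 h
  gI <- tg$gene_id[!is.na(tg$waterlogging_group) &
                     tg$waterlogging_group == "I"]
  fc9 <- expr$waterlogging[gI, "wl_9h"] / expr$waterlogging[gI, "control"]
  expect_true(all(fc9 > 2))
  # noiseless world: planted cluster sizes come back exactly
  expr0 <- simulate_expression(sim$truth, noise_sd = 0, seed = 8)
  cl <- cluster_patterns(call_degs(expr0$waterlogging))$clusters
  expect_setequal(cl$n_genes, c(39L, 29L, 22L, 12L, 12L))
  cld <- cluster_patterns(call_degs(expr0$drought))$clusters
  expect_setequal(cld$n_genes, c(27L, 8L, 6L, 5L))
})

test_that("qPCR simulation recovers planted fold changes", {
  ct <- simulate_qpcr(c("g22", "g1"), c(22, 1), seed = 5)
  r22 <- ddct(ct, "g22", "ACTIN")
  expect_gte(r22$fold, 18)
  expect_lte(r22$fold, 27)
  expect_equal(nrow(r22$per_replicate), 3L)
  r1 <- ddct(ct, "g1", "ACTIN")
  expect_equal(unname(classify_induction(r1$fold)), "NS")
  expect_identical(simulate_qpcr("g", 2, seed = 9),
                   simulate_qpcr("g", 2, seed = 9))
})

test_that("generator/detector closure holds under motif noise levels", {
  prof <- default_repeat_profile()
  # noiseless: 100% of planted subfamily labels recovered
  sim0 <- simulate_genome(n_family_genes = 80L, n_background_genes = 500L,
                          n_unanchored = 4L, motif_noise = 0,
                          tandem_spec = data.frame(size = 2L, count = 3L),
                          seed = 77)
  fam0 <- sim0$proteins[sim0$proteins$gene_id %in% sim0$truth$genes$gene_id, ]
  calls0 <- classify_proteome(scan_proteome(fam0, prof))
  expect_equal(mean(calls0$subfamily[match(sim0$truth$genes$gene_id,
                                           calls0$gene_id)] ==
                      sim0$truth$genes$subfamily), 1)
  # 10% per-position substitutions: recovery stays >= 95%
  sim1 <- simulate_genome(n_family_genes = 80L, n_background_genes = 500L,
                          n_unanchored = 4L, motif_noise = 0.10,
                          tandem_spec = data.frame(size = 2L, count = 3L),
                          seed = 78)
  fam1 <- sim1$proteins[sim1$proteins$gene_id %in% sim1$truth$genes$gene_id, ]
  calls1 <- classify_proteome(scan_proteome(fam1, prof))
  expect_gte(mean(calls1$subfamily[match(sim1$truth$genes$gene_id,
                                         calls1$gene_id)] ==
                    sim1$truth$genes$subfamily), 0.95)
  # background proteins never read as family members
  bg <- sim0$proteins[!(sim0$proteins$gene_id %in%
                          sim0$truth$genes$gene_id), ][1:100, ]
  expect_true(all(classify_proteome(scan_proteome(bg, prof))$subfamily ==
                    "NOT_FAMILY"))
})
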