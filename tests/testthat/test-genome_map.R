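test_that("assign_and_name orders by LG then start, unanchored last", {
  g <- gene_models(c("a", "b", "c", "d", "e"),
                   c("LG01", "LG01", "LG01", "Scaffold007", "LG02"),
                   c(10L, 5L, 20L, 1L, 3L), c(12L, 7L, 22L, 2L, 4L))
  nm <- assign_and_name(g, c("a", "b", "c", "d", "e"), prefix = "FAM")
  expect_equal(nm$gene_id, c("b", "a", "c", "e", "d"))
  expect_equal(nm$name, paste0("FAM", 1:5))
  expect_false(nm$anchored[nm$gene_id == "d"])
  # bijection
  expect_equal(sort(nm$gene_id), sort(g$gene_id))
  expect_equal(anyDuplicated(nm$name), 0L)
  # natural LG order: LG02 before LG10
  g2 <- gene_models(c("p", "q"), c("LG10", "LG02"), c(1L, 1L), c(2L, 2L))
  expect_equal(assign_and_name(g2, c("p", "q"))$gene_id, c("q", "p"))
  # tie on (seqid, start) broken by gene id
  g3 <- gene_models(c("z", "y"), c("LG01", "LG01"), c(5L, 5L), c(6L, 6L))
  expect_equal(assign_and_name(g3, c("z", "y"))$gene_id, c("y", "z"))
  expect_error(assign_and_name(g, "nope"), "absent")
})

test_that("tandem detection follows the <=3 intervening rule transitively", {
  mk <- function(fam_pos, n = 12L) {
    ids <- sprintf("G%02d", seq_len(n))
    g <- gene_models(ids, "LG01", seq_len(n) * 100L, seq_len(n) * 100L + 10L)
    list(genes = g, family = ids[fam_pos])
  }
  # positions 5 and 8: two intervening -> one pair
  inst <- mk(c(5L, 8L))
  arr <- detect_tandem_arrays(inst$genes, inst$family)
  expect_equal(arr$size, 2L)
  expect_equal(arr$members, "G05,G08")
  # positions 5 and 10: four intervening -> nothing
  inst <- mk(c(5L, 10L))
  expect_equal(nrow(detect_tandem_arrays(inst$genes, inst$family)), 0L)
  # chain 1,4,7: one array of three, not two arrays
  inst <- mk(c(1L, 4L, 7L))
  arr <- detect_tandem_arrays(inst$genes, inst$family)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$size, 3L)
  expect_equal(arr$members, "G01,G04,G07")
  expect_error(detect_tandem_arrays(inst$genes, "ghost"), "absent")
})

test_that("tandem detection equals the union-find oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    inst <- random_gene_instance(sample(10:200, 1), sample(2:25, 1),
                                 n_lg = sample(1:4, 1))
    got <- detect_tandem_arrays(inst$genes, inst$family)
    want <- oracle_tandem(inst$genes, inst$family)
    expect_equal(got[c("seqid", "size", "members")], want,
                 ignore_attr = TRUE)
  }
})

test_that("per_lg_summary reproduces the headline percentages and margins", {
  set.seed(12)
  sim <- simulate_genome(seed = 12)
  fam <- sim$truth$genes$gene_id
  calls <- data.frame(gene_id = fam, subfamily = sim$truth$genes$subfamily)
  nm <- assign_and_name(sim$genes, fam, "FAM")
  arr <- detect_tandem_arrays(sim$genes, fam)
  s <- per_lg_summary(nm, calls, arr)
  expect_equal(s$anchored_pct, 95)     # 273 of 287
  expect_equal(s$tandem_pct, 20)       # 55 of 273
  # marginal consistency: row sums == column sums == family total
  tab <- s$table
  inner <- tab[rownames(tab) != "Total", colnames(tab) != "Total",
               drop = FALSE]
  expect_equal(unname(rowSums(inner)), unname(tab[rownames(tab) != "Total",
                                                  "Total"]))
  expect_equal(unname(colSums(inner)), unname(tab["Total",
                                                  colnames(tab) != "Total"]))
  expect_equal(unname(tab["Total", "Total"]), s$family_total)
  expect_equal(s$family_total, length(fam))
  # naming is deterministic under re-run
  expect_identical(nm, assign_and_name(sim$genes, fam, "FAM"))
})

test_that("exon/intron profiling flags intronless genes and the range", {
  g <- gene_models(c("a", "b"), "LG01", c(1L, 100L), c(30L, 200L),
                   exons = list(cbind(1L, 30L),
                                cbind(c(100L, 150L), c(120L, 200L))))
  prof <- exon_intron_profile(g, c("a", "b"))
  expect_true(prof$per_gene$intronless[prof$per_gene$gene_id == "a"])
  expect_false(prof$per_gene$intronless[prof$per_gene$gene_id == "b"])
  expect_equal(prof$per_gene$exon_count, c(1L, 2L))
  expect_equal(unname(prof$range), c(1L, 2L))
  # family-wide range matches the generator's planted exon counts
  sim <- simulate_genome(seed = 5)
  fam <- sim$truth$genes$gene_id
  prof <- exon_intron_profile(sim$genes, fam)
  planted <- sim$truth$genes$exon_count[match(prof$per_gene$gene_id,
                                              sim$truth$genes$gene_id)]
  expect_equal(prof$per_gene$exon_count, planted)
  expect_equal(unname(prof$range), range(planted))
})
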