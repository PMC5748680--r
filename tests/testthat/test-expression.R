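test_that("log2 transform honours the pseudocount", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  lm <- log2_matrix(m)
  expect_equal(lm["g1", "a"], 0)
  expect_equal(lm["g2", "a"], 1)
  expect_equal(lm["g1", "b"], 3)   # log2(7 + 1)
  expect_equal(dimnames(lm), dimnames(m))
  expect_error(log2_matrix(m - 5), "negative")
})

test_that("tissue grouping matches a set-comprehension oracle", {
  tis <- c("root", "stem", "leaf", "capsule", "seed")
  m <- rbind(g1 = c(5, 3, 2, 9, 1.5),
             g2 = c(2, 0, 0, 0, 0),
             g3 = c(0.2, 0.9, 0.5, 0, 1))
  colnames(m) <- tis
  tg <- tissue_groups(m)
  expect_equal(tg$per_gene$pattern[1], paste(tis, collapse = ","))
  expect_equal(tg$per_gene$pattern[2], "root")
  expect_equal(tg$per_gene$pattern[3], "NOT_EXPRESSED")
  expect_equal(tg$n_expressed, 2L)
  expect_equal(tg$n_common, 1L)

  set.seed(47)
  m <- matrix(rexp(60 * 5, 1 / 2), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), tis))
  tg <- tissue_groups(m)
  # oracle: tally the distinct presence subsets directly
  pats <- apply(m > 1, 1, function(x)
    if (!any(x)) "NOT_EXPRESSED" else paste(tis[x], collapse = ","))
  want <- table(pats[pats != "NOT_EXPRESSED"])
  expect_equal(sort(unname(tg$venn)), sort(unname(as.integer(want))))
  expect_setequal(names(tg$venn), names(want))
  # conservation of genes: groups partition the expressed set
  expect_equal(sum(tg$venn), tg$n_expressed)
  expect_equal(sum(tg$per_gene$pattern == "NOT_EXPRESSED") + tg$n_expressed,
               nrow(m))
})

test_that("DEG calls apply the fold-change rule with the zero guard", {
  m <- rbind(gU = c(4, 10), gD = c(4, 1), gN = c(4, 6), gZ = c(0, 5))
  colnames(m) <- c("control", "t1")
  calls <- call_degs(m, "control")
  v <- setNames(calls$verdict, calls$gene_id)
  expect_equal(unname(v[c("gU", "gD", "gN")]), c("UP", "DOWN", "NS"))
  expect_equal(v[["gZ"]], "UP")  # guard keeps zero controls finite
  expect_error(call_degs(m, "nope"), "control column")
  expect_error(call_degs(m, "control", fc_up = 0.5), "fc_down < 1 < fc_up")
  # verdicts invariant to common positive scaling (both sides >= 1 RPKM)
  set.seed(59)
  base <- matrix(runif(40, 1, 50), 10, 4,
                 dimnames = list(paste0("g", 1:10),
                                 c("control", "a", "b", "c")))
  c1 <- call_degs(base, "control")
  c2 <- call_degs(base * 7.3, "control")
  expect_equal(c1$verdict, c2$verdict)
})

test_that("pattern clustering groups exact trajectories, DEGs only", {
  m <- rbind(g1 = c(1, 1, 8, 1), g2 = c(1, 1, 9, 1.2),
             g3 = c(1, 1, 1, 1), g4 = c(2, 0.2, 2, 2))
  colnames(m) <- c("control", "h3", "h9", "h15")
  cl <- cluster_patterns(call_degs(m, "control"))
  expect_setequal(cl$per_gene$gene_id, c("g1", "g2", "g4"))  # g3 all-NS
  expect_equal(cl$per_gene$cluster[cl$per_gene$gene_id == "g1"],
               cl$per_gene$cluster[cl$per_gene$gene_id == "g2"])
  # descending size, roman labels
  expect_equal(cl$clusters$cluster, c("I", "II"))
  expect_equal(cl$clusters$n_genes, c(2L, 1L))
})

test_that("stress Venn arithmetic and its identities hold", {
  A <- paste0("g", 1:114)
  B <- paste0("g", c(87:114, 300:317))   # 28 shared + 18 drought-only
  v <- compare_stresses(A, B, 287)
  expect_equal(v$both, 28L)
  expect_equal(v$union, 132L)
  expect_equal(v$pct_of_family, 46)
  expect_equal(v$A_only + v$B_only + v$both, v$union)
  # disjoint sets: union is the plain sum
  d <- compare_stresses(paste0("a", 1:5), paste0("b", 1:7), 100)
  expect_equal(d$union, 12L)
  expect_equal(d$both, 0L)
  expect_error(compare_stresses(A, B, 100), "family_total")
})

test_that("ddct follows the 2^-ddCt closed forms", {
  mk <- function(tg_s, tg_c, rf_s = 20, rf_c = 20)
    data.frame(gene_id = rep(c("tg", "ref"), each = 2),
               condition = rep(c("stress", "control"), 2),
               replicate = 1L, ct = c(tg_s, tg_c, rf_s, rf_c))
  expect_equal(ddct(mk(20, 20), "tg", "ref")$fold, 1.0)
  expect_equal(ddct(mk(19, 20), "tg", "ref")$fold, 2.0)   # ddCt = -1
  expect_equal(ddct(mk(22, 20), "tg", "ref")$fold, 0.25)  # ddCt = +2
  # reference against itself is identically 1
  expect_equal(ddct(mk(20, 20), "ref", "ref")$fold, 1.0)
  expect_error(ddct(mk(20, 20), "tg", "ghost"), "no Ct")
  # replicates pair by id; geometric mean over replicates
  ct <- rbind(mk(19, 20), mk(21, 20))
  ct$replicate <- rep(c(1L, 2L), each = 4)
  r <- ddct(ct, "tg", "ref")
  expect_equal(nrow(r$per_replicate), 2L)
  expect_equal(r$fold, sqrt(2 * 0.5))
})

test_that("induction classification mirrors the DEG rule", {
  expect_equal(classify_induction(22), "UP")
  expect_equal(classify_induction(0.3), "DOWN")
  expect_equal(classify_induction(1.0), "NS")
  expect_equal(classify_induction(2.0), "NS")   # strict inequality
  expect_error(classify_induction(0), "positive")
})
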