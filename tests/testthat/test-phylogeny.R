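S62 <- substitution_matrix("BLOSUM62")

test_that("global alignment: identity, empty input, enumeration oracle", {
  al <- global_align("AAA", "AAA")
  expect_equal(al$score, 3 * S62["A", "A"])
  expect_equal(al$a, "AAA")
  expect_error(global_align("A", ""), "non-empty")

  # the plain-R Gotoh oracle itself agrees with full path enumeration
  set.seed(41)
  for (i in 1:8) {
    a <- rand_protein(sample(1:4, 1)); b <- rand_protein(sample(1:4, 1))
    expect_equal(oracle_gotoh_global(a, b, S62),
                 oracle_enum_global(a, b, S62))
  }
  # and the C++ implementation agrees with the enumeration oracle
  for (i in 1:10) {
    a <- rand_protein(sample(2:6, 1)); b <- rand_protein(sample(2:6, 1))
    expect_equal(global_align(a, b)$score, oracle_enum_global(a, b, S62))
  }
})

test_that("p-distances behave: identity, hand count, symmetry, range", {
  recs <- protein_records(c("a", "b", "c"),
                          c("AAAA", "AAAT", "AAAA"))
  D <- distance_matrix(recs)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 0.25)   # 1 mismatch over 4 columns
  expect_equal(D, t(D))
  set.seed(17)
  recs <- protein_records(paste0("s", 1:6),
                          replicate(6, rand_protein(sample(20:60, 1))))
  D <- distance_matrix(recs)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(diag(D), setNames(rep(0, 6), recs$gene_id))
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(53)
  for (n in c(4, 6, 9, 12)) {
    for (rep in 1:3) {
      case <- random_additive_case(n)
      phy <- neighbor_joining(case$D)
      got <- tree_distances(phy)[rownames(case$D), colnames(case$D)]
      expect_lt(max(abs(got - case$D)), 1e-9)
      expect_equal(ape::dist.topo(ape::unroot(phy), case$tree), 0,
                   ignore_attr = TRUE)
      # edge count 2n-3 for an unrooted binary tree
      expect_equal(nrow(phy$edge), 2 * n - 3)
    }
  }
})

test_that("neighbor joining small cases follow the closed forms", {
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  phy <- neighbor_joining(D3)
  d <- tree_distances(phy)
  expect_equal(d["x", "y"], 3)
  expect_equal(d["x", "z"], 4)
  expect_equal(d["y", "z"], 5)
  D2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("p", "q"),
                                                    c("p", "q")))
  expect_equal(tree_distances(neighbor_joining(D2))["p", "q"], 7)
  expect_error(neighbor_joining(D2[1, 1, drop = FALSE]), "at least 2")
})

test_that("bootstrap supports are deterministic, bounded, order-invariant", {
  set.seed(61)
  clades <- replicate(4, rand_protein(150))
  recs <- protein_records(paste0("T", 1:8),
                          unlist(lapply(clades, function(s)
                            c(mutate_seq(s, 0.04), mutate_seq(s, 0.04)))))
  b1 <- bootstrap_support(recs, n_reps = 30, seed = 9)
  b2 <- bootstrap_support(recs, n_reps = 30, seed = 9)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  # taxon input order does not change supports (same seed)
  perm <- recs[c(3, 1, 8, 5, 2, 7, 4, 6), ]
  b3 <- bootstrap_support(protein_records(perm$gene_id, perm$sequence),
                          n_reps = 30, seed = 9)
  expect_equal(b1$supports[sort(names(b1$supports))],
               b3$supports[sort(names(b3$supports))])
  # n_reps = 1 gives all-or-nothing supports
  b4 <- bootstrap_support(recs, n_reps = 1, seed = 2)
  expect_true(all(b4$supports %in% c(0, 100)))
  expect_error(bootstrap_support(recs, n_reps = 0), "n_reps")
})

test_that("divergent clades get strong support for their bipartitions", {
  set.seed(71)
  clades <- replicate(4, rand_protein(200))
  recs <- protein_records(
    sprintf("C%d_%d", rep(1:4, each = 3), rep(1:3, 4)),
    unlist(lapply(clades, function(s) replicate(3, mutate_seq(s, 0.03)))))
  bs <- bootstrap_support(recs, n_reps = 100, seed = 13)
  for (k in 1:4) {
    tipset <- sprintf("C%d_%d", k, 1:3)
    key <- paste(sort(tipset), collapse = "|")
    if (!(key %in% names(bs$supports)))  # clade may be stored as complement
      key <- paste(sort(setdiff(recs$gene_id, tipset)), collapse = "|")
    expect_gte(bs$supports[[key]], 95)
  }
})

test_that("subgroup assignment transfers labels and leaves outliers alone", {
  set.seed(83)
  cents <- replicate(5, rand_protein(120))
  refs <- protein_records(paste0("R", 1:5), cents)
  labs <- data.frame(gene_id = refs$gene_id, label = paste0("C", 1:5))
  # query identical to a reference inherits its label
  q0 <- protein_records("q0", cents[2])
  expect_equal(assign_subgroups(q0, refs, labs)$subgroup, "C2")
  # queries sampled around the centroids recover their labels
  qid <- sprintf("q%d_%d", rep(1:5, each = 5), rep(1:5, 5))
  qs <- unlist(lapply(cents, function(s) replicate(5, mutate_seq(s, 0.12))))
  sg <- assign_subgroups(protein_records(qid, qs), refs, labs)
  truth <- paste0("C", rep(1:5, each = 5))
  expect_gte(mean(sg$subgroup == truth), 0.95)
  # a shuffled sequence is far from every reference
  shuf <- protein_records("shuf", paste(sample(strsplit(cents[1], "")[[1]]),
                                        collapse = ""))
  expect_equal(assign_subgroups(shuf, refs, labs)$subgroup, "UNASSIGNED")
  # no references: everything unassigned
  none <- assign_subgroups(q0, refs[0, ], labs[0, ])
  expect_equal(none$subgroup, "UNASSIGNED")
})
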