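# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation of a contract, kept
# structurally different from the implementation it checks.

AA <- genefam:::AA20

rand_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1L]]
  hit <- runif(length(ch)) < rate
  for (i in which(hit)) ch[i] <- sample(setdiff(AA, ch[i]), 1L)
  paste(ch, collapse = "")
}

# ---- scanner oracle: enumerate every window, then greedy non-overlap ----
oracle_scan <- function(seqstr, profile) {
  ch <- strsplit(toupper(seqstr), "")[[1L]]
  L <- profile$length
  n <- length(ch)
  if (n < L) return(data.frame(start = integer(), end = integer(),
                               score = numeric()))
  score_at <- function(o) {
    s <- 0
    for (p in seq_len(L)) {
      r <- ch[o + p - 1L]
      s <- s + if (r %in% AA) profile$weights[p, r]
      else if (r == "X") 0 else min(profile$weights[p, ])
    }
    s
  }
  sc <- vapply(seq_len(n - L + 1L), score_at, numeric(1L))
  cand <- which(sc >= profile$threshold)
  cand <- cand[order(-sc[cand], cand)]
  kept <- integer()
  for (s in cand)
    if (all(s + L - 1L < kept | s > kept + L - 1L)) kept <- c(kept, s)
  kept <- sort(kept)
  data.frame(start = kept, end = kept + L - 1L, score = sc[kept])
}

# ---- tandem oracle: all-pairs chaining + union-find components ----
oracle_tandem <- function(genes, family_ids, max_intervening = 3L) {
  g <- genes[genefam::is_anchored(genes$seqid), , drop = FALSE]
  parent <- seq_len(nrow(g))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  fam <- which(g$gene_id %in% family_ids)
  for (a in fam) for (b in fam) {
    if (a >= b || g$seqid[a] != g$seqid[b]) next
    lo <- min(g$start[a], g$start[b]); hi <- max(g$start[a], g$start[b])
    between <- sum(g$seqid == g$seqid[a] & g$start > lo & g$start < hi)
    if (between <= max_intervening) parent[find(b)] <- find(a)
  }
  comps <- split(fam, vapply(fam, find, integer(1L)))
  comps <- Filter(function(m) length(m) >= 2L, comps)
  out <- lapply(comps, function(m) {
    m <- m[order(g$start[m])]
    data.frame(seqid = g$seqid[m[1L]], size = length(m),
               members = paste(g$gene_id[m], collapse = ","),
               first = g$start[m[1L]], stringsAsFactors = FALSE)
  })
  if (!length(out)) return(data.frame(seqid = character(), size = integer(),
                                      members = character()))
  arr <- do.call(rbind, out)
  arr <- arr[order(genefam:::seqid_rank(arr$seqid), arr$first), , drop = FALSE]
  rownames(arr) <- NULL
  arr[c("seqid", "size", "members")]
}

# ---- pI oracle: dense grid scan for the |charge| minimum ----
oracle_pI <- function(sequence, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  chars <- chars[chars != "X"]
  pka <- genefam:::PKA_DEFAULT
  cnt <- table(factor(chars, levels = AA))
  charge <- 1 / (1 + 10^(grid - pka[["Nterm"]])) -
    1 / (1 + 10^(pka[["Cterm"]] - grid))
  for (r in c("K", "R", "H"))
    charge <- charge + cnt[[r]] / (1 + 10^(grid - pka[[r]]))
  for (r in c("D", "E", "C", "Y"))
    charge <- charge - cnt[[r]] / (1 + 10^(pka[[r]] - grid))
  grid[which.min(abs(charge))]
}

# ---- alignment oracles ----
# enumeration of every monotone alignment path, scored with affine gaps
# (gap of length L costs open + L * ext); exponential, tiny inputs only
oracle_enum_global <- function(a, b, S, open = 10, ext = 0.2) {
  ca <- strsplit(toupper(a), "")[[1L]]; cb <- strsplit(toupper(b), "")[[1L]]
  m <- length(ca); n <- length(cb)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == m && j == n) { best <<- max(best, acc); return(invisible()) }
    if (i < m && j < n)
      rec(i + 1L, j + 1L, "M", acc + S[ca[i + 1L], cb[j + 1L]])
    if (i < m)
      rec(i + 1L, j, "U", acc - ext - if (last != "U") open else 0)
    if (j < n)
      rec(i, j + 1L, "L", acc - ext - if (last != "L") open else 0)
  }
  rec(0L, 0L, "S", 0)
  best
}

# plain-R Gotoh global score (independent re-implementation of the DP;
# itself validated against oracle_enum_global on tiny cases)
oracle_gotoh_global <- function(a, b, S, open = 10, ext = 0.2) {
  ca <- strsplit(toupper(a), "")[[1L]]; cb <- strsplit(toupper(b), "")[[1L]]
  m <- length(ca); n <- length(cb)
  M <- X <- Y <- matrix(-Inf, m + 1L, n + 1L)
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1L, 1L] <- -(open + i * ext)
  for (j in seq_len(n)) Y[1L, j + 1L] <- -(open + j * ext)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    M[i + 1L, j + 1L] <- S[ca[i], cb[j]] + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext,
                             Y[i, j + 1L] - open - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                             X[i + 1L, j] - open - ext, Y[i + 1L, j] - ext)
  }
  max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])
}

# exhaustive local score: best global score over all substring pairs, or 0
oracle_local <- function(a, b, S, open = 10, ext = 0.2) {
  m <- nchar(a); n <- nchar(b)
  best <- 0
  for (i1 in 1:m) for (i2 in i1:m) for (j1 in 1:n) for (j2 in j1:n)
    best <- max(best, oracle_gotoh_global(substr(a, i1, i2),
                                          substr(b, j1, j2), S, open, ext))
  best
}

# ---- random additive tree -> distance matrix (via ape, independent of
# the NJ implementation under test) ----
random_additive_case <- function(n) {
  t0 <- ape::rtree(n)
  t0$edge.length <- runif(nrow(t0$edge), 0.05, 1)
  t0 <- ape::unroot(t0)
  list(tree = t0, D = stats::cophenetic(t0)[t0$tip.label, t0$tip.label])
}

# ---- small gene-model fixture on a handful of LGs ----
random_gene_instance <- function(n_genes, n_family, n_lg = 3L) {
  lg <- sample(sprintf("LG%02d", seq_len(n_lg)), n_genes, replace = TRUE)
  start <- integer(n_genes)
  for (l in unique(lg)) {
    idx <- which(lg == l)
    start[idx] <- sort(sample.int(10000L, length(idx)))
  }
  g <- genefam::gene_models(sprintf("G%03d", seq_len(n_genes)), lg,
                            start, start + 10L)
  list(genes = g,
       family = sample(g$gene_id, min(n_family, n_genes)))
}
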