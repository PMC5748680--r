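#' Pairwise p-distance matrix
#'
#' Aligns every pair globally (affine gaps) and computes the p-distance:
#' mismatched columns / counted columns, where a gap against a residue
#' counts as a mismatch and gap-gap columns are excluded (these cannot occur
#' in a pairwise alignment but the rule matters for profile rows).
#'
#' @param records a [protein_records] data frame
#' @param matrix,gap_open,gap_extend alignment parameters, see
#'   [global_align()]
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames
#' @export
distance_matrix <- function(records, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.2) {
  S <- substitution_matrix(matrix)
  n <- nrow(records)
  D <- base::matrix(0, n, n, dimnames = list(records$gene_id, records$gene_id))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- global_align(records$sequence[i], records$sequence[j], S,
                       gap_open, gap_extend)
    D[i, j] <- D[j, i] <- aligned_pdist(al$a, al$b)
  }
  D
}

# p-distance of two aligned strings (gap-gap columns excluded,
# gap-vs-residue counts as mismatch)
aligned_pdist <- function(aa, bb) {
  ca <- strsplit(aa, "")[[1L]]
  cb <- strsplit(bb, "")[[1L]]
  valid <- !(ca == "-" & cb == "-")
  if (!sum(valid)) stop_genefam("alignment has no counted columns")
  sum(ca[valid] != cb[valid]) / sum(valid)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined (ties broken by the
#' lexicographically smallest pair of representative taxon labels), with the
#' standard branch-length and distance-update formulas. Negative branch
#' estimates are clamped to zero with the deficit moved to the sibling
#' branch, preserving path lengths. For an additive matrix the tree's path
#' metric reproduces the input exactly (up to floating point).
#'
#' @param D symmetric distance matrix with taxa dimnames (n >= 2)
#' @return an [ape::phylo] object; unrooted (the root trifurcation is the
#'   final join); with n = 2 the single edge is represented as two half
#'   edges through a degree-2 root so that the path length equals d(1,2)
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  taxa <- rownames(D)
  n <- length(taxa)
  if (n < 2L) stop_genefam("need at least 2 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop_genefam("distance matrix must be symmetric")
  if (any(!is.finite(D)) || any(D < 0))
    stop_genefam("distances must be finite and non-negative")
  key <- taxa            # active node keys
  rep_lab <- taxa        # representative (lexicographically smallest) taxon
  edges <- list()        # list of c(parent_key, child_key, length)
  n_int <- 0L
  add_edge <- function(p, c, l) edges[[length(edges) + 1L]] <<- list(p, c, l)
  while (length(key) > 3L) {
    m <- length(key)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pr <- cbind(pmin(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]]),
                pmax(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]]))
    pick <- order(pr[, 1L], pr[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    n_int <- n_int + 1L
    u <- paste0(".I", n_int)
    add_edge(u, key[i], li)
    add_edge(u, key[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    key <- c(key[keep], u)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    rownames(D) <- colnames(D) <- key
  }
  n_int <- n_int + 1L
  root <- paste0(".I", n_int)
  if (length(key) == 2L) {
    add_edge(root, key[1L], D[1L, 2L] / 2)
    add_edge(root, key[2L], D[1L, 2L] / 2)
  } else {
    l1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
    l2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
    l3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
    for (k in 1:3) add_edge(root, key[k], max(0, c(l1, l2, l3)[k]))
  }
  build_phylo(edges, taxa, root)
}

# assemble an ape phylo from (parent_key, child_key, length) triples
build_phylo <- function(edges, taxa, root) {
  par_k <- vapply(edges, `[[`, character(1L), 1L)
  chi_k <- vapply(edges, `[[`, character(1L), 2L)
  len <- vapply(edges, `[[`, numeric(1L), 3L)
  n <- length(taxa)
  ids <- new.env()
  for (i in seq_along(taxa)) assign(taxa[i], i, envir = ids)
  next_id <- n + 1L
  kids <- split(seq_along(par_k), par_k)
  edge <- base::matrix(0L, length(edges), 2L)
  elen <- numeric(length(edges))
  row <- 0L
  # pass 1: assign ids in preorder (root gets n+1)
  id_map <- new.env()
  assign_ids <- function(k) {
    if (k %in% taxa) assign(k, get(k, envir = ids), envir = id_map)
    else { assign(k, next_id, envir = id_map); next_id <<- next_id + 1L }
    for (e in kids[[k]] %||% integer()) assign_ids(chi_k[e])
  }
  assign_ids(root)
  # pass 2: emit edges in preorder
  emit <- function(k) {
    for (e in kids[[k]] %||% integer()) {
      row <<- row + 1L
      edge[row, ] <<- c(get(k, envir = id_map), get(chi_k[e], envir = id_map))
      elen[row] <<- len[e]
      emit(chi_k[e])
    }
  }
  emit(root)
  phy <- list(edge = edge, edge.length = elen, tip.label = taxa,
              Nnode = next_id - 1L - n)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Path-length distances between tips of a tree
#'
#' @param phy an [ape::phylo]
#' @return symmetric matrix of patristic distances, tip labels as dimnames
#' @export
tree_distances <- function(phy) {
  d <- ape::dist.nodes(phy)[seq_along(phy$tip.label), seq_along(phy$tip.label)]
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

# canonical keys for the non-trivial bipartitions of a tree: for each
# internal edge, the tip set on the child side, flipped so the key never
# contains the alphabetically first taxon
tree_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  n <- length(phy$tip.label)
  internal_child <- phy$edge[, 2L] > n
  out <- character()
  if (!any(internal_child)) return(out)
  for (e in which(internal_child)) {
    desc <- ape::extract.clade(phy, phy$edge[e, 2L])$tip.label
    if (length(desc) < 2L || length(desc) > n - 2L) next
    side <- if (tips[1L] %in% desc) setdiff(phy$tip.label, desc) else desc
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Star (center-anchored) multiple alignment
#'
#' Builds a pseudo-reference alignment by globally aligning every sequence
#' to the longest one (ties: lexicographically smallest id); the center's
#' positions define the columns and insertions relative to the center are
#' dropped. This is the fixed column space that bootstrap resampling
#' operates on.
#'
#' @inheritParams distance_matrix
#' @return character matrix (sequences x center columns) with `-` gaps
#' @export
star_alignment <- function(records, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.2) {
  lens <- nchar(records$sequence)
  center <- order(-lens, records$gene_id)[1L]
  cseq <- records$sequence[center]
  L <- nchar(cseq)
  msa <- base::matrix("-", nrow(records), L,
                      dimnames = list(records$gene_id, NULL))
  msa[center, ] <- strsplit(cseq, "")[[1L]]
  S <- substitution_matrix(matrix)
  for (i in seq_len(nrow(records))) {
    if (i == center) next
    al <- global_align(records$sequence[i], cseq, S, gap_open, gap_extend)
    ca <- strsplit(al$a, "")[[1L]]
    cb <- strsplit(al$b, "")[[1L]]
    keep <- cb != "-"            # columns that exist in the center
    msa[i, ] <- ca[keep]
  }
  msa
}

# p-distance matrix over the rows of a character alignment matrix
msa_pdist <- function(msa) {
  n <- nrow(msa)
  D <- base::matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    valid <- !(msa[i, ] == "-" & msa[j, ] == "-")
    nv <- sum(valid)
    D[i, j] <- D[j, i] <-
      if (nv == 0L) 1 else sum(msa[i, valid] != msa[j, valid]) / nv
  }
  D
}

#' Bootstrap support for the internal edges of the NJ tree
#'
#' The reference tree is the NJ tree of the pairwise p-distances. Each
#' replicate resamples the columns of the star alignment with replacement,
#' recomputes p-distances and the NJ tree, and a reference bipartition is
#' supported when it appears in the replicate. Supports are percentages.
#' Rows of the star alignment are canonicalized by taxon id before
#' resampling, so supports do not depend on input order.
#'
#' @inheritParams distance_matrix
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed RNG seed
#' @return list with `tree` (reference [ape::phylo] whose `node.label`
#'   carries the support of the edge above each internal node, `""` for the
#'   root) and `supports` (named vector, one entry per non-trivial split)
#' @export
bootstrap_support <- function(records, n_reps = 100L, seed = 1L,
                              matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.2) {
  if (n_reps < 1L) stop_genefam("n_reps must be >= 1")
  ref <- neighbor_joining(distance_matrix(records, matrix, gap_open, gap_extend))
  msa <- star_alignment(records, matrix, gap_open, gap_extend)
  msa <- msa[order(rownames(msa)), , drop = FALSE]
  splits <- tree_splits(ref)
  counts <- setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
    rep_tree <- neighbor_joining(msa_pdist(msa[, cols, drop = FALSE]))
    hit <- splits %in% tree_splits(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_reps
  # annotate node labels: support of the edge above each internal node
  n <- length(ref$tip.label)
  node_lab <- rep("", ref$Nnode)
  tips1 <- sort(ref$tip.label)[1L]
  for (e in which(ref$edge[, 2L] > n)) {
    desc <- ape::extract.clade(ref, ref$edge[e, 2L])$tip.label
    if (length(desc) < 2L || length(desc) > n - 2L) next
    side <- if (tips1 %in% desc) setdiff(ref$tip.label, desc) else desc
    k <- paste(sort(side), collapse = "|")
    node_lab[ref$edge[e, 2L] - n] <- format(supports[[k]])
  }
  ref$node.label <- node_lab
  list(tree = ref, supports = supports)
}

#' Assign queries to reference-anchored subgroups
#'
#' Builds a joint NJ tree over queries and labeled references; each query
#' takes the label of its nearest reference by path length on the tree.
#' Queries whose nearest reference is farther than `ceiling` are
#' `UNASSIGNED` (lineage-specific subgroups).
#'
#' @param queries,references [protein_records] data frames (ids must not
#'   collide)
#' @param reference_labels named character vector (reference id -> label),
#'   or a data frame with columns `gene_id`, `label`
#' @param ceiling path-length cutoff beyond which a query stays unassigned
#' @inheritParams distance_matrix
#' @return data frame `gene_id`, `subgroup`, `nearest_reference`, `distance`
#' @export
assign_subgroups <- function(queries, references, reference_labels,
                             ceiling = 0.75, matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.2) {
  if (is.data.frame(reference_labels))
    reference_labels <- setNames(reference_labels$label,
                                 reference_labels$gene_id)
  if (nrow(references) == 0L)
    return(data.frame(gene_id = queries$gene_id, subgroup = "UNASSIGNED",
                      nearest_reference = NA_character_,
                      distance = NA_real_, stringsAsFactors = FALSE))
  if (length(intersect(queries$gene_id, references$gene_id)))
    stop_genefam("query and reference ids collide")
  all_rec <- protein_records(c(queries$gene_id, references$gene_id),
                             c(queries$sequence, references$sequence))
  D <- distance_matrix(all_rec, matrix, gap_open, gap_extend)
  pd <- if (nrow(all_rec) >= 3L) tree_distances(neighbor_joining(D)) else D
  out <- data.frame(gene_id = queries$gene_id, subgroup = "UNASSIGNED",
                    nearest_reference = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  refs <- sort(references$gene_id)
  for (i in seq_len(nrow(out))) {
    d <- pd[out$gene_id[i], refs]
    best <- refs[order(d, refs)][1L]
    out$nearest_reference[i] <- best
    out$distance[i] <- d[[best]]
    lab <- unname(reference_labels[best])
    if (d[[best]] <= ceiling && !is.na(lab)) out$subgroup[i] <- lab
  }
  out
}
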