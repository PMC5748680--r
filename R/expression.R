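#' Log2-transform an expression matrix
#'
#' @param table numeric matrix of non-negative RPKM values
#' @param pseudocount added before taking log2 (default 1)
#' @return matrix of `log2(value + pseudocount)`, same shape and dimnames
#' @export
log2_matrix <- function(table, pseudocount = 1) {
  if (any(table < 0)) stop_genefam("negative expression values")
  log2(table + pseudocount)
}

#' Tissue-presence grouping and Venn counts
#'
#' A gene's presence pattern is the subset of tissues where its RPKM
#' exceeds `expressed_threshold`. Genes sharing a non-empty pattern form a
#' group; groups are numbered canonically by descending size, ties broken by
#' the pattern's bit string, and labeled with Roman numerals. All-absent
#' genes are `NOT_EXPRESSED`.
#'
#' @param table genes x tissues RPKM matrix
#' @param expressed_threshold RPKM above which a gene counts as expressed
#'   (default 1, i.e. "RPKM > 1")
#' @return list with `per_gene` (`gene_id`, `pattern` — comma-joined tissue
#'   ids or `NOT_EXPRESSED` — `n_tissues`, `group`), `groups` (`group`,
#'   `pattern`, `n_genes`), `venn` (named counts per observed pattern),
#'   `n_expressed`, `n_common` (expressed in every tissue), `common_pct`
#'   (headline integer, of expressed genes)
#' @export
tissue_groups <- function(table, expressed_threshold = 1) {
  tissues <- colnames(table)
  pres <- table > expressed_threshold
  bits <- apply(pres, 1L, function(x) paste(as.integer(x), collapse = ""))
  pattern <- apply(pres, 1L, function(x)
    if (!any(x)) "NOT_EXPRESSED" else paste(tissues[x], collapse = ","))
  expressed <- pattern != "NOT_EXPRESSED"
  tab <- table(bits[expressed])
  ord <- order(-as.integer(tab), names(tab), decreasing = FALSE)
  canon <- names(tab)[ord]
  groups <- data.frame(
    group = as.character(utils::as.roman(seq_along(canon))),
    pattern = vapply(canon, function(b) {
      paste(tissues[strsplit(b, "")[[1L]] == "1"], collapse = ",")
    }, character(1L)),
    n_genes = as.integer(tab[canon]),
    row.names = NULL, stringsAsFactors = FALSE)
  per_gene <- data.frame(
    gene_id = rownames(table),
    pattern = pattern,
    n_tissues = rowSums(pres),
    group = ifelse(expressed,
                   groups$group[match(bits, canon)], "NOT_EXPRESSED"),
    row.names = NULL, stringsAsFactors = FALSE)
  n_expressed <- sum(expressed)
  n_common <- sum(rowSums(pres) == length(tissues))
  venn <- setNames(as.integer(tab[canon]), groups$pattern)
  list(per_gene = per_gene, groups = groups, venn = venn,
       n_expressed = n_expressed, n_common = n_common,
       common_pct = if (n_expressed)
         round_half_up(100 * n_common / n_expressed) else 0)
}

#' Call differentially expressed genes by fold change
#'
#' One verdict per gene per stress time point: `UP` when
#' `fold_change > fc_up`, `DOWN` when `fold_change < fc_down`, else `NS`.
#' Fold change is `(stress + eps) / (control + eps)` with a small RPKM
#' guard `eps` against zeros.
#'
#' @param stress_table genes x conditions RPKM matrix containing the control
#'   column and the stress time points
#' @param control_column name of the control column
#' @param fc_up,fc_down thresholds (must satisfy `fc_down < 1 < fc_up`)
#' @param eps RPKM zero guard (default 0.01)
#' @return data frame `gene_id`, `time_point`, `fold_change`, `verdict`
#' @export
call_degs <- function(stress_table, control_column = "control",
                      fc_up = 2, fc_down = 0.5, eps = 0.01) {
  if (!(fc_down < 1 && 1 < fc_up))
    stop_genefam("thresholds must satisfy fc_down < 1 < fc_up")
  if (!(control_column %in% colnames(stress_table)))
    stop_genefam("control column '", control_column, "' not found")
  tps <- setdiff(colnames(stress_table), control_column)
  ctrl <- stress_table[, control_column]
  out <- do.call(rbind, lapply(tps, function(tp) {
    fc <- (stress_table[, tp] + eps) / (ctrl + eps)
    data.frame(gene_id = rownames(stress_table), time_point = tp,
               fold_change = fc,
               verdict = ifelse(fc > fc_up, "UP",
                                ifelse(fc < fc_down, "DOWN", "NS")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cluster DEGs by their verdict trajectory
#'
#' Genes with at least one non-NS verdict are grouped by their exact verdict
#' signature across time points; clusters are reported in descending size,
#' ties broken by the signature string, and labeled with Roman numerals.
#'
#' @param calls output of [call_degs()] (time points keep their column
#'   order of first appearance)
#' @return list with `per_gene` (`gene_id`, `signature`, `cluster`) covering
#'   DEGs only, and `clusters` (`cluster`, `signature`, `n_genes`)
#' @export
cluster_patterns <- function(calls) {
  tps <- unique(calls$time_point)
  wide <- tapply(calls$verdict, list(calls$gene_id, calls$time_point),
                 identity)[, tps, drop = FALSE]
  sig <- apply(wide, 1L, paste, collapse = ",")
  deg <- vapply(strsplit(sig, ","), function(v) any(v != "NS"), logical(1L))
  sig <- sig[deg]
  if (!length(sig))
    return(list(per_gene = data.frame(gene_id = character(),
                                      signature = character(),
                                      cluster = character(),
                                      stringsAsFactors = FALSE),
                clusters = data.frame(cluster = character(),
                                      signature = character(),
                                      n_genes = integer(),
                                      stringsAsFactors = FALSE)))
  tab <- table(sig)
  ord <- order(-as.integer(tab), names(tab))
  canon <- names(tab)[ord]
  clusters <- data.frame(cluster = as.character(utils::as.roman(seq_along(canon))),
                         signature = canon,
                         n_genes = as.integer(tab[canon]),
                         row.names = NULL, stringsAsFactors = FALSE)
  per_gene <- data.frame(gene_id = names(sig), signature = unname(sig),
                         cluster = clusters$cluster[match(sig, canon)],
                         row.names = NULL, stringsAsFactors = FALSE)
  list(per_gene = per_gene, clusters = clusters)
}

#' DEG gene ids from a call set
#'
#' @param calls output of [call_degs()]
#' @return character vector of genes with at least one non-NS verdict
#' @export
deg_genes <- function(calls) {
  sort(unique(calls$gene_id[calls$verdict != "NS"]))
}

#' Venn comparison of two stress DEG sets
#'
#' @param deg_set_A,deg_set_B character vectors of DEG gene ids
#' @param family_total total family size for the percentage
#' @return list `A_only`, `B_only`, `both`, `union`, `pct_of_family`
#'   (rounded half-up to an integer)
#' @export
compare_stresses <- function(deg_set_A, deg_set_B, family_total) {
  A <- unique(deg_set_A); B <- unique(deg_set_B)
  u <- union(A, B)
  if (family_total < length(u))
    stop_genefam("family_total smaller than the DEG union")
  list(A_only = length(setdiff(A, B)),
       B_only = length(setdiff(B, A)),
       both = length(intersect(A, B)),
       union = length(u),
       pct_of_family = round_half_up(100 * length(u) / family_total))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate: `dCt_cond = Ct_target,cond - Ct_reference,cond`,
#' `ddCt = dCt_stress - dCt_control`, fold change `2^-ddCt`. Replicates are
#' paired by replicate id; the summary fold change is the geometric mean
#' (the arithmetic mean of the ddCt values, back-transformed).
#'
#' @param ct_table long data frame `gene_id`, `condition`
#'   (`stress`/`control`), `replicate`, `ct` (see [read_ct_tsv()])
#' @param target_gene,reference_gene gene ids present in both conditions
#' @return list with `per_replicate` (`replicate`, `ddct`, `fold`) and
#'   `fold` (geometric mean)
#' @export
ddct <- function(ct_table, target_gene, reference_gene) {
  get_ct <- function(gene, cond) {
    d <- ct_table[ct_table$gene_id == gene & ct_table$condition == cond, ]
    if (!nrow(d)) stop_genefam("no Ct for ", gene, " in condition ", cond)
    setNames(d$ct, d$replicate)
  }
  ts <- get_ct(target_gene, "stress"); tc <- get_ct(target_gene, "control")
  rs <- get_ct(reference_gene, "stress"); rc <- get_ct(reference_gene, "control")
  reps <- Reduce(intersect, list(names(ts), names(tc), names(rs), names(rc)))
  if (!length(reps)) stop_genefam("no complete replicate for ", target_gene)
  dd <- (ts[reps] - rs[reps]) - (tc[reps] - rc[reps])
  per <- data.frame(replicate = reps, ddct = unname(dd),
                    fold = unname(2^-dd), stringsAsFactors = FALSE)
  list(per_replicate = per, fold = 2^-mean(dd))
}

#' Classify a qPCR fold change
#'
#' @param fold positive fold change
#' @param up,down thresholds (default 2 and 0.5)
#' @return `"UP"`, `"DOWN"` or `"NS"`
#' @export
classify_induction <- function(fold, up = 2, down = 0.5) {
  if (any(fold <= 0)) stop_genefam("fold change must be positive")
  ifelse(fold > up, "UP", ifelse(fold < down, "DOWN", "NS"))
}
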