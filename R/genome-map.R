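#' Natural ordering of linkage-group / scaffold ids
#'
#' Orders `LG01..LG16` numerically before any non-LG seqid; non-LG seqids
#' (unanchored scaffolds) sort lexicographically after all linkage groups.
#'
#' @param seqid character vector
#' @return integer ranks usable as a sort key
#' @keywords internal
seqid_rank <- function(seqid) {
  anch <- is_anchored(seqid)
  num <- suppressWarnings(as.integer(sub("^LG", "", seqid)))
  key <- ifelse(anch, sprintf("0%06d", num), paste0("1", seqid))
  match(key, sort(unique(key)))
}

#' Order family genes along the genome and assign survey names
#'
#' Family members are sorted by linkage group in natural order (LG01..LG16),
#' then by start coordinate; unanchored genes come last, sorted by scaffold
#' id then start. Names are `prefix` followed by 1..N in that order. Ties on
#' (seqid, start) are broken by gene id, lexicographically.
#'
#' @param genes a [gene_models] data frame (may include non-family genes)
#' @param family_ids character vector of family-member gene ids
#' @param prefix name prefix (e.g. `"SIMYB"`)
#' @return data frame `gene_id`, `name`, `seqid`, `anchored`, `start`,
#'   `rank`, one row per family gene, in naming order
#' @export
assign_and_name <- function(genes, family_ids, prefix = "FAM") {
  missing <- setdiff(family_ids, genes$gene_id)
  if (length(missing))
    stop_genefam("family ids absent from gene models: ",
                 paste(missing, collapse = ", "))
  fam <- genes[genes$gene_id %in% family_ids, , drop = FALSE]
  ord <- order(seqid_rank(fam$seqid), fam$start, fam$gene_id)
  fam <- fam[ord, , drop = FALSE]
  data.frame(gene_id = fam$gene_id,
             name = paste0(prefix, seq_len(nrow(fam))),
             seqid = fam$seqid,
             anchored = is_anchored(fam$seqid),
             start = fam$start,
             rank = seq_len(nrow(fam)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect tandem-duplication arrays
#'
#' Two family genes on the same linkage group are chained when at most
#' `max_intervening` genes (of any family status) lie strictly between them
#' in the per-LG start ordering of the full gene complement. Arrays are the
#' connected components of this chaining relation over consecutive family
#' genes; components of size >= 2 are reported.
#'
#' @param genes the full [gene_models] complement (family plus background)
#' @param family_ids character vector of family gene ids
#' @param max_intervening maximum number of intervening genes (default 3)
#' @param anchored_only only consider genes on linkage groups (default TRUE)
#' @return data frame `array_id`, `seqid`, `size`, `members`
#'   (comma-separated gene ids ordered by start), sorted by LG then first
#'   start; zero rows when no arrays exist
#' @export
detect_tandem_arrays <- function(genes, family_ids, max_intervening = 3L,
                                 anchored_only = TRUE) {
  missing <- setdiff(family_ids, genes$gene_id)
  if (length(missing))
    stop_genefam("family ids absent from gene models: ",
                 paste(missing, collapse = ", "))
  g <- genes
  if (anchored_only) g <- g[is_anchored(g$seqid), , drop = FALSE]
  out <- list()
  for (lg in unique(g$seqid)[order(seqid_rank(unique(g$seqid)))]) {
    sub <- g[g$seqid == lg, , drop = FALSE]
    sub <- sub[order(sub$start, sub$gene_id), , drop = FALSE]
    fam_pos <- which(sub$gene_id %in% family_ids)
    if (length(fam_pos) < 2L) next
    gaps <- diff(fam_pos) - 1L            # genes strictly between
    linked <- gaps <= max_intervening
    comp <- cumsum(c(TRUE, !linked))
    for (cid in unique(comp)) {
      members <- fam_pos[comp == cid]
      if (length(members) >= 2L)
        out[[length(out) + 1L]] <- data.frame(
          seqid = lg, size = length(members),
          members = paste(sub$gene_id[members], collapse = ","),
          first_start = sub$start[members[1L]],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(array_id = integer(), seqid = character(),
                      size = integer(), members = character(),
                      stringsAsFactors = FALSE))
  arr <- do.call(rbind, out)
  arr <- arr[order(seqid_rank(arr$seqid), arr$first_start), , drop = FALSE]
  data.frame(array_id = seq_len(nrow(arr)), seqid = arr$seqid,
             size = arr$size, members = arr$members,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-linkage-group family summary
#'
#' Cross-tabulates family members by linkage group and subfamily (with a
#' single `Scaffold` row pooling unanchored genes) and computes the headline
#' percentages: anchored share of the family and tandem share of the
#' anchored genes. Headline figures are rounded half-up to integers; the
#' table carries 2 decimals.
#'
#' @param naming output of [assign_and_name()]
#' @param calls classification data frame (`gene_id`, `subfamily`)
#' @param arrays output of [detect_tandem_arrays()]
#' @return list with `table` (LG x subfamily counts with Total row/column),
#'   `anchored_total`, `unanchored_total`, `family_total`, `tandem_members`,
#'   `anchored_pct`, `tandem_pct` (headline integers), `anchored_pct_2dp`,
#'   `tandem_pct_2dp`
#' @export
per_lg_summary <- function(naming, calls, arrays) {
  fam_levels <- SUBFAMILY_LEVELS[-1L]
  sub <- calls$subfamily[match(naming$gene_id, calls$gene_id)]
  lg <- ifelse(naming$anchored, naming$seqid, "Scaffold")
  lg_levels <- c(sort(unique(naming$seqid[naming$anchored])),
                 if (any(!naming$anchored)) "Scaffold")
  tab <- table(factor(lg, levels = lg_levels),
               factor(sub, levels = fam_levels))
  tab <- cbind(as.matrix(unclass(tab)), Total = rowSums(tab))
  tab <- rbind(tab, Total = colSums(tab))
  family_total <- nrow(naming)
  anchored_total <- sum(naming$anchored)
  tandem_members <- if (nrow(arrays)) sum(arrays$size) else 0L
  a_pct <- 100 * anchored_total / max(family_total, 1L)
  t_pct <- 100 * tandem_members / max(anchored_total, 1L)
  list(table = tab,
       anchored_total = anchored_total,
       unanchored_total = family_total - anchored_total,
       family_total = family_total,
       tandem_members = tandem_members,
       anchored_pct = round_half_up(a_pct),
       tandem_pct = round_half_up(t_pct),
       anchored_pct_2dp = round_half_up(a_pct, 2L),
       tandem_pct_2dp = round_half_up(t_pct, 2L))
}

#' Exon/intron profile of the family
#'
#' @param genes a [gene_models] data frame
#' @param family_ids family gene ids
#' @return list with `per_gene` (data frame `gene_id`, `exon_count`,
#'   `intronless`) and `range` (c(min, max) exon count over the family)
#' @export
exon_intron_profile <- function(genes, family_ids) {
  fam <- genes[genes$gene_id %in% family_ids, , drop = FALSE]
  n_ex <- vapply(fam$exons, nrow, integer(1L))
  per_gene <- data.frame(gene_id = fam$gene_id, exon_count = n_ex,
                         intronless = n_ex == 1L,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       range = if (nrow(fam)) c(min = min(n_ex), max = max(n_ex))
               else c(min = NA_integer_, max = NA_integer_))
}
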