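#' Write the survey report tables
#'
#' Emits the standard TSV set: `family_summary.tsv`, `tandem_arrays.tsv`,
#' `ortholog_pairs.tsv`, `tissue_groups.tsv`, `deg_calls.tsv`,
#' `venn_counts.tsv`. Any element of `tables` may be omitted or `NULL`; a
#' header-only file is written in its place. Row order is deterministic
#' (sorted by gene id where applicable), so identical inputs give
#' byte-identical outputs.
#'
#' @param tables named list with any of: `family_summary` (from
#'   [summarize_family()]), `tandem_arrays` (from
#'   [detect_tandem_arrays()]), `ortholog_pairs` (from [find_orthologs()]),
#'   `tissue_groups` (the `per_gene` element of [tissue_groups()]),
#'   `deg_calls` (from [call_degs()]), `venn_counts` (a named numeric
#'   vector or the full [tissue_groups()] result's `venn`)
#' @param out_dir output directory (created if needed)
#' @return character vector of the files written, invisibly
#' @export
write_report <- function(tables, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_genefam("cannot create directory: ", out_dir)
  emit <- function(d, file, sort_col = NULL) {
    path <- file.path(out_dir, file)
    if (!is.null(sort_col) && nrow(d))
      d <- d[do.call(order, d[sort_col]), , drop = FALSE]
    num <- vapply(d, is.numeric, logical(1L)) &
      !vapply(d, is.integer, logical(1L))
    d[num] <- lapply(d[num], function(x) sprintf("%.2f", x))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    path
  }
  fs <- tables$family_summary %||%
    data.frame(subfamily = character(), count = integer(),
               percentage = numeric())
  ta <- tables$tandem_arrays %||%
    data.frame(array_id = integer(), seqid = character(), size = integer(),
               members = character())
  op <- tables$ortholog_pairs %||%
    data.frame(query_id = character(), reference_id = character(),
               sw_score = numeric(), evalue = numeric(),
               similarity = numeric(), best = logical(),
               transferred_label = character())
  tgp <- tables$tissue_groups %||%
    data.frame(gene_id = character(), pattern = character(),
               n_tissues = integer(), group = character())
  dc <- tables$deg_calls %||%
    data.frame(gene_id = character(), time_point = character(),
               fold_change = numeric(), verdict = character())
  vc <- tables$venn_counts %||% setNames(integer(), character())
  vcd <- data.frame(pattern = names(vc), count = as.integer(vc),
                    stringsAsFactors = FALSE)
  if (nrow(op)) {
    # E-values need scientific notation, not fixed 2-decimal formatting
    op$evalue <- formatC(op$evalue, format = "e", digits = 3)
    op$sw_score <- sprintf("%.1f", op$sw_score)
    op$similarity <- sprintf("%.4f", op$similarity)
  }
  files <- c(
    emit(fs, "family_summary.tsv"),
    emit(ta, "tandem_arrays.tsv"),
    emit(op, "ortholog_pairs.tsv", "query_id"),
    emit(tgp, "tissue_groups.tsv", "gene_id"),
    emit(dc, "deg_calls.tsv", c("gene_id", "time_point")),
    emit(vcd, "venn_counts.tsv"))
  invisible(files)
}
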