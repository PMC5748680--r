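#' Protein record container
#'
#' A `protein_records` object is a data frame with columns `gene_id` and
#' `sequence` (uppercase, 20-letter amino-acid alphabet; `X` permitted but
#' excluded from all numeric computations downstream).
#'
#' @param gene_id character vector of unique identifiers
#' @param sequence character vector of amino-acid sequences
#' @return a `protein_records` data frame
#' @export
protein_records <- function(gene_id, sequence) {
  gene_id <- as.character(gene_id)
  sequence <- toupper(as.character(sequence))
  if (length(gene_id) != length(sequence))
    stop_genefam("gene_id and sequence lengths differ")
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stop_genefam("duplicate protein ids: ", paste(dup, collapse = ", "))
  if (any(!nzchar(sequence)))
    stop_genefam("empty sequence for: ",
                 paste(gene_id[!nzchar(sequence)], collapse = ", "))
  out <- data.frame(gene_id = gene_id, sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Headers are split at the first whitespace to yield the gene id; sequence
#' bodies are uppercased. Record order is preserved.
#'
#' @param path path to a FASTA file
#' @return a [protein_records] data frame
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_genefam("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(protein_records(character(), character())[0L, , drop = FALSE])
  ids <- sub("\\s.*$", "", names(aa))
  log_records("read_fasta", path, length(aa))
  protein_records(ids, as.character(aa))
}

# record-count logging (never silently drop records); enable with
# options(genefam.verbose = TRUE)
log_records <- function(op, path, n) {
  if (isTRUE(getOption("genefam.verbose", FALSE)))
    message(op, ": ", n, " records from ", path)
  invisible(n)
}

#' Write protein records as FASTA
#'
#' @param records a [protein_records] data frame
#' @param path output path
#' @param width line width for the sequence body
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", records$gene_id[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Gene model container
#'
#' A `gene_models` object is a data frame with one row per gene: `gene_id`,
#' `seqid` (linkage group such as `LG01`, or a scaffold id for unanchored
#' genes), 1-based inclusive `start`/`end`, `strand`, and a list column
#' `exons` of two-column matrices (`start`, `end`), sorted, non-overlapping,
#' each within the gene span. Strand is recorded but does not affect any
#' downstream computation (ordering uses `start` only).
#'
#' @param gene_id,seqid,start,end,strand per-gene vectors
#' @param exons list of numeric matrices with columns start, end (one per
#'   gene); `NULL` entries become a single exon spanning the gene
#' @return a `gene_models` data frame
#' @export
gene_models <- function(gene_id, seqid, start, end, strand = "+", exons = NULL) {
  n <- length(gene_id)
  gene_id <- as.character(gene_id)
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stop_genefam("duplicate gene ids: ", paste(dup, collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  if (any(start > end))
    stop_genefam("start > end for: ",
                 paste(gene_id[start > end], collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop_genefam("strand must be '+' or '-'")
  if (is.null(exons)) exons <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(ex)) ex <- cbind(start = start[i], end = end[i])
    ex <- matrix(as.integer(ex), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] > ex[, 2L]) ||
        any(ex[, 1L] < start[i]) || any(ex[, 2L] > end[i]))
      stop_genefam("exon outside gene span for gene ", gene_id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      stop_genefam("overlapping exons for gene ", gene_id[i])
    exons[[i]] <- ex
  }
  out <- data.frame(gene_id = gene_id, seqid = as.character(seqid),
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Is a gene anchored to a linkage group?
#'
#' @param x a [gene_models] data frame (or a character vector of seqids)
#' @param lg_pattern regular expression identifying linkage-group seqids
#' @return logical vector
#' @export
is_anchored <- function(x, lg_pattern = "^LG\\d+$") {
  seqid <- if (is.data.frame(x)) x$seqid else as.character(x)
  grepl(lg_pattern, seqid)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features; exon `Parent` attributes must resolve
#' to a gene `ID`. Coordinates are kept 1-based inclusive (the GFF3
#' convention). Genes lacking exon features are treated as single-exon.
#'
#' @param path path to a GFF3 file
#' @return a [gene_models] data frame, in gene file order
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_genefam("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop_genefam("malformed GFF3 line ", keep[which(nf != 9L)[1L]],
                 ": expected 9 tab-separated columns, got ",
                 nf[which(nf != 9L)[1L]])
  tab <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  type <- tab[, 3L]
  g <- which(type == "gene")
  e <- which(type == "exon")
  gid <- attr_get(tab[g, 9L], "ID")
  if (anyNA(gid)) stop_genefam("gene feature without ID attribute (line ",
                               keep[g[which(is.na(gid))[1L]]], ")")
  parent <- attr_get(tab[e, 9L], "Parent")
  bad <- !(parent %in% gid)
  if (any(bad))
    stop_genefam("exon Parent does not resolve to a gene: ",
                 paste(unique(parent[bad]), collapse = ", "))
  ex_by_gene <- split(data.frame(start = as.integer(tab[e, 4L]),
                                 end = as.integer(tab[e, 5L])),
                      factor(parent, levels = gid))
  exons <- unname(lapply(ex_by_gene, function(d) {
    if (nrow(d) == 0L) NULL else cbind(start = d$start, end = d$end)
  }))
  log_records("read_gff3", path, length(g))
  gene_models(gene_id = gid, seqid = tab[g, 1L],
              start = as.integer(tab[g, 4L]), end = as.integer(tab[g, 5L]),
              strand = tab[g, 7L], exons = exons)
}

#' Write gene models as GFF3
#'
#' @param genes a [gene_models] data frame
#' @param path output path
#' @param source value for the GFF3 source column
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path, source = "genefam") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (i in seq_len(nrow(genes))) {
    writeLines(paste(genes$seqid[i], source, "gene", genes$start[i],
                     genes$end[i], ".", genes$strand[i], ".",
                     paste0("ID=", genes$gene_id[i]), sep = "\t"),
               con, sep = "\n")
    ex <- genes$exons[[i]]
    for (k in seq_len(nrow(ex)))
      writeLines(paste(genes$seqid[i], source, "exon", ex[k, 1L], ex[k, 2L],
                       ".", genes$strand[i], ".",
                       paste0("Parent=", genes$gene_id[i]), sep = "\t"),
                 con, sep = "\n")
  }
  invisible(path)
}

#' Read an expression table (TSV)
#'
#' First column holds gene ids, header row holds condition ids; cells are
#' non-negative RPKM values.
#'
#' @param path path to a tab-separated file
#' @return numeric matrix, genes in rows, conditions in columns
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_genefam("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop_genefam("ragged TSV: line ", which(nf != nf[1L])[1L],
                 " has ", nf[which(nf != nf[1L])[1L]], " fields, expected ",
                 nf[1L])
  d <- read.delim(path, check.names = FALSE, colClasses = "character",
                  quote = "")
  ids <- d[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_genefam("duplicated gene id: ", paste(dup, collapse = ", "))
  cond <- colnames(d)[-1L]
  if (anyDuplicated(cond)) stop_genefam("condition ids are not unique")
  vals <- suppressWarnings(
    vapply(d[-1L], as.numeric, numeric(nrow(d))))
  vals <- matrix(vals, nrow = nrow(d),
                 dimnames = list(ids, cond))
  if (anyNA(vals)) {
    ij <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_genefam("non-numeric cell at gene ", ids[ij[1L]],
                 ", condition ", cond[ij[2L]])
  }
  if (any(vals < 0)) {
    ij <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop_genefam("negative value at gene ", ids[ij[1L]],
                 ", condition ", cond[ij[2L]])
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and condition colnames
#' @param path output path
#' @param id_col header for the gene-id column
#' @return `path`, invisibly
#' @export
write_expression_tsv <- function(mat, path, id_col = "gene_id") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c(id_col, colnames(mat))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table (TSV)
#'
#' Long format with columns `gene_id`, `condition` (`stress`/`control`),
#' `replicate`, `ct` (cycles, > 0).
#'
#' @param path path to a tab-separated file
#' @return data frame with the four columns above
#' @export
read_ct_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, quote = "",
                  stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "replicate", "ct")
  if (!all(need %in% colnames(d)))
    stop_genefam("Ct table must have columns: ", paste(need, collapse = ", "))
  d$ct <- as.numeric(d$ct)
  if (anyNA(d$ct) || any(d$ct <= 0)) stop_genefam("Ct values must be > 0")
  d[need]
}
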