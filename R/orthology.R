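#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring >= S between a query of length m and a database of
#' length n. Defaults are the gapped BLOSUM62 (11/1) constants.
#'
#' @param score local alignment score S
#' @param query_len,db_len sequence lengths m and n (positive)
#' @param lambda_,K Karlin-Altschul parameters
#' @return the E-value (strictly decreasing in S, linear in m and n)
#' @export
evalue <- function(score, query_len, db_len, lambda_ = 0.267, K = 0.041) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop_genefam("sequence lengths must be positive")
  K * query_len * db_len * exp(-lambda_ * score)
}

#' Map queries onto a labeled reference proteome
#'
#' Smith-Waterman aligns every query against every reference; hits passing
#' both the E-value ceiling and the similarity floor are recorded. Each
#' query's best hit (highest score; ties broken by smaller E-value, then
#' lexicographic reference id) transfers the reference's functional label.
#'
#' @param queries,references [protein_records] data frames
#' @param reference_labels named character vector (reference id -> label) or
#'   data frame `gene_id`, `label`; unnamed references transfer `NA`
#' @param evalue_max E-value ceiling (default 1e-40)
#' @param min_similarity positives-fraction floor (default 0.70)
#' @param lambda_,K see [evalue()]
#' @inheritParams global_align
#' @return data frame of passing pairs: `query_id`, `reference_id`,
#'   `sw_score`, `evalue`, `similarity`, `best` (logical),
#'   `transferred_label` (non-NA only on best hits)
#' @export
find_orthologs <- function(queries, references, reference_labels = NULL,
                           evalue_max = 1e-40, min_similarity = 0.70,
                           matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.2, lambda_ = 0.267, K = 0.041) {
  if (is.data.frame(reference_labels))
    reference_labels <- setNames(reference_labels$label,
                                 reference_labels$gene_id)
  S <- substitution_matrix(matrix)
  rows <- vector("list", nrow(queries) * nrow(references))
  k <- 0L
  for (i in seq_len(nrow(queries))) for (j in seq_len(nrow(references))) {
    al <- smith_waterman(queries$sequence[i], references$sequence[j], S,
                         gap_open, gap_extend)
    ev <- evalue(al$score, nchar(queries$sequence[i]),
                 nchar(references$sequence[j]), lambda_, K)
    if (ev <= evalue_max && al$similarity >= min_similarity) {
      k <- k + 1L
      rows[[k]] <- data.frame(query_id = queries$gene_id[i],
                              reference_id = references$gene_id[j],
                              sw_score = al$score, evalue = ev,
                              similarity = al$similarity,
                              stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(query_id = character(), reference_id = character(),
                      sw_score = numeric(), evalue = numeric(),
                      similarity = numeric(), best = logical(),
                      transferred_label = character(),
                      stringsAsFactors = FALSE))
  pairs <- do.call(rbind, rows[seq_len(k)])
  pairs$best <- FALSE
  pairs$transferred_label <- NA_character_
  for (q in unique(pairs$query_id)) {
    idx <- which(pairs$query_id == q)
    b <- idx[order(-pairs$sw_score[idx], pairs$evalue[idx],
                   pairs$reference_id[idx])][1L]
    pairs$best[b] <- TRUE
    lab <- unname(reference_labels[pairs$reference_id[b]])
    pairs$transferred_label[b] <- if (is.null(lab)) NA_character_ else lab
  }
  pairs <- pairs[order(pairs$query_id, pairs$reference_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Copy-number summary of best-hit assignments
#'
#' @param pairs output of [find_orthologs()]
#' @return data frame `reference_id`, `n_queries`: how many queries chose
#'   each reference as best hit (references with zero are absent); the
#'   counts sum to the number of assigned queries
#' @export
copy_number_summary <- function(pairs) {
  best <- pairs[pairs$best, , drop = FALSE]
  if (!nrow(best))
    return(data.frame(reference_id = character(), n_queries = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(best$reference_id)
  data.frame(reference_id = names(tab), n_queries = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
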