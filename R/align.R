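# Pairwise alignment wrappers around the Gotoh C++ kernel.

#' Fetch a protein substitution matrix
#'
#' @param name matrix name (`"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`, ...) or a
#'   numeric matrix passed through unchanged
#' @return numeric substitution matrix with residue dimnames
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

# map residues to row indices of the substitution matrix; letters the matrix
# does not know fall back to its wildcard row ('X' for protein matrices)
encode_seq <- function(sequence, mat) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  idx <- match(chars, rownames(mat))
  wild <- match("X", rownames(mat))
  if (anyNA(idx)) {
    if (is.na(wild)) stop_genefam("unknown residue and no wildcard row")
    idx[is.na(idx)] <- wild
  }
  idx - 1L
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length L costs `gap_open + L * gap_extend`. Traceback ties are
#' broken deterministically preferring diagonal, then up (gap in `b`), then
#' left (gap in `a`).
#'
#' @param a,b sequence strings (non-empty)
#' @param matrix substitution matrix or its name (default BLOSUM62)
#' @param gap_open,gap_extend gap penalties (positive)
#' @return list with `score`, aligned strings `a` and `b`
#' @export
global_align <- function(a, b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.2) {
  if (!nzchar(a) || !nzchar(b)) stop_genefam("sequences must be non-empty")
  S <- substitution_matrix(matrix)
  r <- .align_pair_cpp(toupper(a), toupper(b),
                       encode_seq(a, S), encode_seq(b, S),
                       S, gap_open, gap_extend, FALSE)
  list(score = r$score, a = r$a, b = r$b)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' @inheritParams global_align
#' @return list with `score` (>= 0), aligned substrings `a` and `b`, their
#'   coordinates `start_a`/`end_a`/`start_b`/`end_b` (NA for the empty
#'   alignment), and `similarity`: (identities + positive-scoring
#'   substitutions) / alignment length, the fraction BLASTp reports as
#'   "positives"
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.2) {
  if (!nzchar(a) || !nzchar(b)) stop_genefam("sequences must be non-empty")
  S <- substitution_matrix(matrix)
  r <- .align_pair_cpp(toupper(a), toupper(b),
                       encode_seq(a, S), encode_seq(b, S),
                       S, gap_open, gap_extend, TRUE)
  r$similarity <- alignment_similarity(r$a, r$b, S)
  r
}

#' Positives fraction of an alignment
#'
#' @param aa,bb equal-length aligned strings (with `-` gaps)
#' @param matrix substitution matrix or name
#' @return (identities + positive-scoring substitutions) / alignment length;
#'   0 for an empty alignment
#' @export
alignment_similarity <- function(aa, bb, matrix = "BLOSUM62") {
  if (!nzchar(aa)) return(0)
  S <- substitution_matrix(matrix)
  ca <- strsplit(toupper(aa), "")[[1L]]
  cb <- strsplit(toupper(bb), "")[[1L]]
  if (length(ca) != length(cb)) stop_genefam("aligned strings differ in length")
  res <- ca != "-" & cb != "-"
  pos <- sum(S[cbind(encode_seq(paste(ca[res], collapse = ""), S) + 1L,
                     encode_seq(paste(cb[res], collapse = ""), S) + 1L)] > 0)
  pos / length(ca)
}
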