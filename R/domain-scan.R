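#' Scan a protein for repeat-domain occurrences
#'
#' Slides the profile over the sequence, scores every window as the sum of
#' per-position log-odds, keeps windows scoring at or above the profile
#' threshold, and resolves overlaps greedily: candidates are taken in order
#' of descending score (ties by smaller start) and a candidate is kept only
#' if it overlaps no previously kept hit.
#'
#' Residues outside the 20-letter alphabet score the worst value of their
#' column (with a warning); `X` scores 0 (unknown, uninformative).
#'
#' @param protein a single sequence string, or one row of [protein_records]
#' @param profile a [repeat_profile()]
#' @return data frame with columns `start`, `end` (1-based inclusive residue
#'   positions) and `score`, sorted by `start`; zero rows when nothing passes
#' @export
scan_repeats <- function(protein, profile) {
  seqstr <- if (is.data.frame(protein)) protein$sequence[[1L]] else protein
  seqstr <- toupper(seqstr)
  L <- profile$length
  n <- nchar(seqstr)
  empty <- data.frame(start = integer(), end = integer(), score = numeric())
  if (n < L) return(empty)
  chars <- strsplit(seqstr, "")[[1L]]
  idx <- match(chars, AA20)
  if (anyNA(idx)) {
    odd <- setdiff(unique(chars[is.na(idx)]), "X")
    if (length(odd))
      warning("non-standard residue(s) scored as worst column value: ",
              paste(odd, collapse = ", "), call. = FALSE)
  }
  # score lookup: 20 alphabet columns, col 21 = X (0), col 22 = other (row min)
  W <- cbind(profile$weights, X = 0, other = apply(profile$weights, 1L, min))
  col <- ifelse(is.na(idx), ifelse(chars == "X", 21L, 22L), idx)
  n_win <- n - L + 1L
  pos <- seq_len(L)
  scores <- vapply(seq_len(n_win), function(o)
    sum(W[cbind(pos, col[o + pos - 1L])]), numeric(1L))
  cand <- which(scores >= profile$threshold)
  if (!length(cand)) return(empty)
  ord <- cand[order(-scores[cand], cand)]
  kept <- integer()
  for (s in ord) {
    if (!any(abs(kept - s) < L)) kept <- c(kept, s)
  }
  kept <- sort(kept)
  data.frame(start = kept, end = kept + L - 1L, score = scores[kept])
}

#' Scan a whole protein set
#'
#' @param records a [protein_records] data frame
#' @param profile a [repeat_profile()]
#' @return named list of per-protein hit data frames (see [scan_repeats()])
#' @export
scan_proteome <- function(records, profile) {
  out <- lapply(records$sequence, scan_repeats, profile = profile)
  names(out) <- records$gene_id
  out
}

SUBFAMILY_LEVELS <- c("NOT_FAMILY", "1R", "R2R3", "R1R2R3", "ATYPICAL")

#' Classify a protein's subfamily from its repeat count
#'
#' The canonical repeat-count rule: 0 repeats is not a family member, 1 is
#' the 1R (related) subfamily, 2 is R2R3, 3 is R1R2R3, and 4 or more is
#' atypical.
#'
#' @param hits a hit data frame from [scan_repeats()], or an integer count
#' @return list with `n_repeats` and `subfamily` (one of `NOT_FAMILY`,
#'   `1R`, `R2R3`, `R1R2R3`, `ATYPICAL`)
#' @export
classify_subfamily <- function(hits) {
  n <- if (is.numeric(hits)) as.integer(hits) else nrow(hits)
  sub <- if (n == 0L) "NOT_FAMILY"
  else if (n == 1L) "1R"
  else if (n == 2L) "R2R3"
  else if (n == 3L) "R1R2R3"
  else "ATYPICAL"
  list(n_repeats = n, subfamily = sub)
}

#' Classify every protein in a scanned set
#'
#' @param scan named list from [scan_proteome()]
#' @return data frame `gene_id`, `n_repeats`, `subfamily`
#' @export
classify_proteome <- function(scan) {
  calls <- lapply(scan, classify_subfamily)
  data.frame(gene_id = names(scan),
             n_repeats = vapply(calls, `[[`, integer(1L), "n_repeats"),
             subfamily = vapply(calls, `[[`, character(1L), "subfamily"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Bjellqvist-style pKa values (ExPASy convention); pluggable.
PKA_DEFAULT <- c(Nterm = 7.5, Cterm = 3.55,
                 K = 10.0, R = 12.0, H = 5.98,       # basic side chains
                 D = 4.05, E = 4.45, C = 9.0, Y = 10.0)  # acidic side chains

#' Net protein charge at a given pH
#'
#' Positive groups (N-terminus, K, R, H) contribute `1/(1+10^(pH-pKa))`;
#' negative groups (C-terminus, D, E, C, Y) contribute `-1/(1+10^(pKa-pH))`.
#' `X` residues are ignored.
#'
#' @param sequence protein sequence string
#' @param pH numeric vector of pH values
#' @param pka named pKa vector (see `PKA_DEFAULT`)
#' @return numeric vector of net charges
#' @export
protein_charge <- function(sequence, pH, pka = PKA_DEFAULT) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  chars <- chars[chars != "X"]
  if (!length(chars)) stop_genefam("empty sequence")
  counts <- table(factor(chars, levels = AA20))
  pos_pka <- c(pka[["Nterm"]],
               rep(pka[["K"]], counts[["K"]]), rep(pka[["R"]], counts[["R"]]),
               rep(pka[["H"]], counts[["H"]]))
  neg_pka <- c(pka[["Cterm"]],
               rep(pka[["D"]], counts[["D"]]), rep(pka[["E"]], counts[["E"]]),
               rep(pka[["C"]], counts[["C"]]), rep(pka[["Y"]], counts[["Y"]]))
  vapply(pH, function(p)
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p))),
    numeric(1L))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in (0, 14) at which the net charge crosses zero, by
#' bisection to |charge| < `tol` (charge is strictly decreasing in pH).
#'
#' @param sequence protein sequence string (`X` ignored)
#' @param pka named pKa vector
#' @param tol convergence tolerance on |charge|
#' @return the isoelectric point (pH units)
#' @export
compute_pI <- function(sequence, pka = PKA_DEFAULT, tol = 1e-4) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- protein_charge(sequence, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) return(mid)
  }
}

# ExPASy-style average residue masses (Da)
AA_AVG_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water. `X` residues are excluded;
#' any other letter outside the 20-letter alphabet is an error.
#'
#' @param sequence protein sequence string
#' @return molecular weight in daltons
#' @export
compute_mw <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  chars <- chars[chars != "X"]
  if (!length(chars)) stop_genefam("empty sequence")
  bad <- setdiff(unique(chars), names(AA_AVG_MASS))
  if (length(bad))
    stop_genefam("unknown residue(s): ", paste(bad, collapse = ", "))
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

#' Summarize a family classification
#'
#' @param calls data frame from [classify_proteome()] (rows with subfamily
#'   `NOT_FAMILY` are dropped), or a named count vector over subfamilies
#' @return data frame with one row per subfamily (`1R`, `R2R3`, `R1R2R3`,
#'   `ATYPICAL`) plus a `Total` row; columns `subfamily`, `count`,
#'   `percentage` (100 * count / total, rounded half-up to 2 decimals)
#' @export
summarize_family <- function(calls) {
  fam_levels <- SUBFAMILY_LEVELS[-1L]
  if (is.data.frame(calls)) {
    sub <- calls$subfamily[calls$subfamily != "NOT_FAMILY"]
    counts <- table(factor(sub, levels = fam_levels))
  } else {
    counts <- setNames(integer(length(fam_levels)), fam_levels)
    counts[names(calls)] <- as.integer(calls)
  }
  counts <- as.integer(counts[fam_levels])
  total <- sum(counts)
  pct <- if (total == 0L) rep(0, length(counts))
  else round_half_up(100 * counts / total, 2L)
  data.frame(subfamily = c(fam_levels, "Total"),
             count = c(counts, total),
             percentage = c(pct, if (total == 0L) 0 else 100),
             stringsAsFactors = FALSE)
}
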