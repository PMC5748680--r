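#' Repeat-domain profile (position weight matrix)
#'
#' A `repeat_profile` holds an L x 20 matrix of per-position log-odds scores
#' (log2 of column probability over a uniform 1/20 background), a detection
#' threshold, and the consensus sequence (argmax residue per position).
#' It stands in for a profile HMM of the repeat domain: detection semantics
#' (find all above-threshold occurrences, count them) are preserved while
#' the scoring model stays desk-buildable.
#'
#' @param weights numeric matrix, one row per position, 20 columns named by
#'   the amino-acid alphabet
#' @param threshold detection threshold on the window score; if `NULL`,
#'   computed as `threshold_frac` of the consensus self-score
#' @param threshold_frac fraction of the consensus self-score used when
#'   `threshold` is not given (default 0.6)
#' @return a `repeat_profile` list with fields `length`, `weights`,
#'   `threshold`, `consensus`
#' @export
repeat_profile <- function(weights, threshold = NULL, threshold_frac = 0.6) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 20L)
    stop_genefam("profile must have 20 columns")
  if (is.null(colnames(weights))) colnames(weights) <- AA20
  if (!setequal(colnames(weights), AA20))
    stop_genefam("profile columns must be the 20 amino-acid letters")
  weights <- weights[, AA20, drop = FALSE]
  if (!all(is.finite(weights))) stop_genefam("profile weights must be finite")
  self_score <- sum(apply(weights, 1L, max))
  if (is.null(threshold)) threshold <- threshold_frac * self_score
  if (!is.finite(threshold)) stop_genefam("threshold must be finite")
  structure(list(length = nrow(weights), weights = weights,
                 threshold = threshold,
                 consensus = paste(AA20[apply(weights, 1L, which.max)],
                                   collapse = "")),
            class = "repeat_profile")
}

# Fixed 52-residue MYB-like repeat consensus used by the shipped profile.
# Arbitrary but versioned: the helix-turn-helix flavour (regular W anchors)
# mimics the real repeat's tryptophan periodicity.
REPEAT_CONSENSUS <- paste0(
  "KGPWTEEEDKLLVAYIQKHGEGNWRALPKKAGLKRCGKSCRLRWTNYLRPD")
# pad to 52 with a terminal anchor
REPEAT_CONSENSUS <- paste0(REPEAT_CONSENSUS, "I")

#' Build the default repeat profile
#'
#' Constructs the shipped 52-position profile deterministically: each column
#' gives probability `p_consensus` to the consensus residue and spreads the
#' remainder over the other 19 residues with Dirichlet-style perturbation
#' drawn from a fixed internal RNG stream (so the fixture is versioned, not
#' random). Weights are log2 odds against a uniform 1/20 background.
#'
#' @param consensus consensus sequence (default: the shipped 52-mer)
#' @param p_consensus probability mass on the consensus residue per column
#' @param threshold_frac passed to [repeat_profile()]
#' @return a `repeat_profile`
#' @export
default_repeat_profile <- function(consensus = REPEAT_CONSENSUS,
                                   p_consensus = 0.97,
                                   threshold_frac = 0.6) {
  res <- strsplit(consensus, "")[[1L]]
  if (!all(res %in% AA20)) stop_genefam("consensus must use the 20-letter alphabet")
  L <- length(res)
  probs <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  # deterministic perturbation stream, independent of the caller's RNG
  state <- 20260910
  nextu <- function(n) {
    # Lehmer MCG (Park-Miller); avoids touching .Random.seed
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
  for (i in seq_len(L)) {
    g <- -log(nextu(19L))            # Exp(1) draws -> Dirichlet(1) weights
    off <- (1 - p_consensus) * g / sum(g)
    probs[i, ] <- 0
    probs[i, setdiff(AA20, res[i])] <- off
    probs[i, res[i]] <- p_consensus
  }
  repeat_profile(log2(probs * 20), threshold_frac = threshold_frac)
}

#' Read a repeat profile from plain text
#'
#' Format: a header line of the 20 amino-acid letters, then one
#' whitespace-separated row of 20 scores per profile position.
#'
#' @param path input path
#' @param threshold,threshold_frac passed to [repeat_profile()]
#' @return a `repeat_profile`
#' @export
read_pwm <- function(path, threshold = NULL, threshold_frac = 0.6) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (!setequal(hdr, AA20))
    stop_genefam("PWM header must list the 20 amino-acid letters")
  rows <- lapply(lines[-1L], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  if (any(lengths(rows) != 20L)) stop_genefam("PWM rows must have 20 values")
  w <- do.call(rbind, rows)
  colnames(w) <- hdr
  repeat_profile(w, threshold = threshold, threshold_frac = threshold_frac)
}

#' Write a repeat profile as plain text
#'
#' @param profile a `repeat_profile`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pwm <- function(profile, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(profile$weights), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(profile$length))
    writeLines(paste(formatC(profile$weights[i, ], format = "g", digits = 10),
                     collapse = "\t"), con, sep = "\n")
  invisible(path)
}
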