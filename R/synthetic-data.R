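# Synthetic "sesame-like" dataset with planted ground truth.
#
# The generator states a world mirroring the published survey's scale: 287
# family genes over 16 linkage groups, subfamily mix 51.22/46.69/1.74/0.35,
# 55 genes in tandem arrays of size 2-4, 14 unanchored genes, five tissues
# with 173 ubiquitous / 19 silent genes, stress time courses with five
# waterlogging groups (39/12/12/22/29) and four drought groups (5/6/8/27)
# overlapping in 28 genes.

REPEATS_PER_SUBFAMILY <- c("1R" = 1L, "R2R3" = 2L, "R1R2R3" = 3L,
                           "ATYPICAL" = 4L)

DEFAULT_SUBFAMILY_MIX <- c("1R" = 0.5122, "R2R3" = 0.4669,
                           "R1R2R3" = 0.0174, "ATYPICAL" = 0.0035)

# 22 arrays totalling 55 genes (13x2 + 7x3 + 2x4), the published span
DEFAULT_TANDEM_SPEC <- data.frame(size = c(2L, 3L, 4L), count = c(13L, 7L, 2L))

# linkage groups the published arrays fall on
DEFAULT_ARRAY_LGS <- c("LG02", "LG03", "LG04", "LG05", "LG06", "LG07",
                       "LG08", "LG10", "LG11", "LG15", "LG16")

TISSUES <- c("root", "stem", "leaf", "capsule", "seed")

# verdict trajectories of the five waterlogging groups (3h, 9h, 15h) and
# the four drought groups (d1, d2, d3), as described for the published
# pattern groups
WATERLOGGING_GROUPS <- list(
  I   = c("NS", "UP", "NS"),    # strongly induced at 9 h
  II  = c("NS", "NS", "UP"),    # induced under intense stress (15 h)
  III = c("UP", "UP", "DOWN"),  # induced at 3 and 9 h, down at 15 h
  IV  = c("UP", "NS", "NS"),    # early induction only
  V   = c("UP", "DOWN", "UP"))  # down at 9 h, induced at 3 and 15 h
WATERLOGGING_SIZES <- c(I = 39L, II = 12L, III = 12L, IV = 22L, V = 29L)

DROUGHT_GROUPS <- list(
  I   = c("UP", "UP", "UP"),    # constitutive induction, striking at d3
  II  = c("NS", "UP", "UP"),    # induced under severe stress
  III = c("DOWN", "DOWN", "DOWN"),
  IV  = c("UP", "UP", "DOWN"))  # early induction, down at d3
DROUGHT_SIZES <- c(I = 5L, II = 6L, III = 8L, IV = 27L)

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# substitute each position with probability `rate` by a different residue
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- runif(length(chars)) < rate
  for (i in which(hit)) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

# one family protein: k noisy copies of the consensus motif embedded in
# random background; returns the sequence plus the motif-position mask so
# ortholog divergence can be confined to the background (the functional
# domain is conserved among orthologs)
plant_motifs <- function(k, profile, motif_noise) {
  motif <- function() mutate_protein(profile$consensus, motif_noise)
  parts <- character(2L * k + 1L)
  is_motif <- vector("list", 2L * k + 1L)
  parts[1L] <- random_protein(sample(30:80, 1L))
  for (i in seq_len(k)) {
    parts[2L * i] <- motif()
    parts[2L * i + 1L] <- random_protein(
      if (i < k) sample(5:40, 1L) else sample(30:120, 1L))
  }
  mask <- rep(rep(c(FALSE, TRUE), length.out = 2L * k + 1L),
              nchar(parts))
  list(seq = paste(parts, collapse = ""), mask = mask)
}

# mutate only positions where mask is FALSE (background, not motif)
mutate_background <- function(seq, mask, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- runif(length(chars)) < rate & !mask
  for (i in which(hit)) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

# draw exon structures: returns list of exon matrices plus gene length
make_exons <- function(exon_count) {
  ex_len <- sample(60:400, exon_count, replace = TRUE)
  in_len <- if (exon_count > 1L)
    sample(60:800, exon_count - 1L, replace = TRUE) else integer()
  starts <- cumsum(c(1L, head(ex_len, -1L) + in_len))
  cbind(start = starts, end = starts + ex_len - 1L)
}

#' Simulate a genome, proteome and reference proteome with planted truth
#'
#' Generates family proteins carrying 1-4 noisy copies of the repeat motif,
#' background proteins without motifs, gene models on `n_linkage_groups`
#' linkage groups (plus unanchored scaffolds), tandem arrays placed as
#' consecutive family genes with 0-3 intervening background genes (isolated
#' family genes are kept at least `max_intervening + 1` genes apart), and a
#' labeled synthetic reference proteome with planted ortholog groups.
#'
#' @param n_family_genes number of family genes (default 287)
#' @param n_background_genes number of non-family genes (default 1600)
#' @param n_linkage_groups number of linkage groups (default 16)
#' @param subfamily_mix named proportions over `1R`, `R2R3`, `R1R2R3`,
#'   `ATYPICAL` summing to 1
#' @param tandem_spec data frame `size` (2-4), `count` of planted arrays
#' @param seed RNG seed
#' @param n_unanchored family genes left on scaffolds (default 14)
#' @param motif_noise per-position substitution probability applied to each
#'   planted motif copy (default 0.05; 0 gives noiseless motifs)
#' @param profile a [repeat_profile()]; default the shipped one
#' @param ortholog_frac fraction of family genes given a planted reference
#'   ortholog (default 133/287)
#' @param n_decoy_refs unrelated reference proteins (default 30)
#' @param max_intervening tandem chaining rule used to space isolated genes
#' @return list with `genes` ([gene_models]), `proteins`
#'   ([protein_records], family + background), `references`
#'   ([protein_records]), `reference_labels` (data frame `gene_id`,
#'   `label`), and `truth` (list: `genes` per-gene data frame with
#'   `subfamily`, `n_repeats`, `ortholog_ref`; `arrays`; `subfamily_counts`)
#' @export
simulate_genome <- function(n_family_genes = 287L,
                            n_background_genes = 1600L,
                            n_linkage_groups = 16L,
                            subfamily_mix = DEFAULT_SUBFAMILY_MIX,
                            tandem_spec = DEFAULT_TANDEM_SPEC,
                            seed = 1L,
                            n_unanchored = 14L,
                            motif_noise = 0.05,
                            profile = default_repeat_profile(),
                            ortholog_frac = 133 / 287,
                            n_decoy_refs = 30L,
                            max_intervening = 3L) {
  if (abs(sum(subfamily_mix) - 1) > 1e-6)
    stop_genefam("subfamily_mix proportions must sum to 1")
  if (any(!tandem_spec$size %in% 2:4))
    stop_genefam("tandem array sizes must be in 2..4")
  n_tandem_genes <- sum(tandem_spec$size * tandem_spec$count)
  n_anchored <- n_family_genes - n_unanchored
  if (n_tandem_genes > n_anchored)
    stop_genefam("requested arrays exceed the anchored family gene budget")
  set.seed(seed)

  # ---- subfamily labels (multinomial draw, recorded in truth) ----
  subfam <- sample(names(subfamily_mix), n_family_genes, replace = TRUE,
                   prob = subfamily_mix)
  fam_ids <- sprintf("FAMG%04d", seq_len(n_family_genes))

  # ---- ortholog groups (within-subfamily) and protein sequences ----
  n_orth <- round(ortholog_frac * n_family_genes)
  orth_ref <- rep(NA_character_, n_family_genes)
  proteins <- character(n_family_genes)
  ref_seqs <- character(); ref_ids <- character(); ref_labs <- character()
  group_no <- 0L
  for (sf in names(REPEATS_PER_SUBFAMILY)) {
    members <- which(subfam == sf)
    # proportional share of the ortholog budget
    take <- round(n_orth * length(members) / n_family_genes)
    take <- min(take, length(members))
    chosen <- if (take) sample(members, take) else integer()
    rest <- setdiff(members, chosen)
    k <- REPEATS_PER_SUBFAMILY[[sf]]
    while (length(chosen)) {
      size <- sample(1:6, 1L, prob = c(0.60, 0.20, 0.09, 0.06, 0.03, 0.02))
      size <- min(size, length(chosen))
      grp <- chosen[seq_len(size)]
      chosen <- chosen[-seq_len(size)]
      group_no <- group_no + 1L
      proto <- plant_motifs(k, profile, motif_noise)
      rid <- sprintf("REF%03d", group_no)
      ref_ids <- c(ref_ids, rid)
      ref_seqs <- c(ref_seqs, mutate_protein(proto$seq, 0.08))
      ref_labs <- c(ref_labs, sprintf("C%d", group_no))
      for (g in grp) {
        # co-ortholog divergence lives in the background; the planted
        # domain copies stay as drawn (domain conservation)
        proteins[g] <- if (g == grp[1L]) proto$seq
        else mutate_background(proto$seq, proto$mask, 0.04)
        orth_ref[g] <- rid
      }
    }
    for (g in rest) proteins[g] <- plant_motifs(k, profile, motif_noise)$seq
  }
  # decoy references: no family counterpart
  for (d in seq_len(n_decoy_refs)) {
    ref_ids <- c(ref_ids, sprintf("DECOY%03d", d))
    ref_seqs <- c(ref_seqs, random_protein(sample(150:400, 1L)))
    ref_labs <- c(ref_labs, sprintf("D%d", d))
  }

  # ---- background proteins ----
  bg_ids <- sprintf("BKGG%04d", seq_len(n_background_genes))
  bg_seqs <- vapply(sample(120:450, n_background_genes, replace = TRUE),
                    random_protein, character(1L))

  # ---- genome layout ----
  lgs <- sprintf("LG%02d", seq_len(n_linkage_groups))
  # anchored family genes: arrays first, then isolated singles
  arr_sizes <- rep(tandem_spec$size, tandem_spec$count)
  fam_pool <- sample(seq_len(n_family_genes))   # placement order
  unanch <- fam_pool[seq_len(n_unanchored)]
  fam_pool <- fam_pool[-seq_len(n_unanchored)]
  arrays <- list()
  blocks <- list()   # per block: list(lg, items = c(ids), fam = logical)
  bg_pool <- sample(seq_len(n_background_genes))
  take_bg <- function(n) {
    if (n > length(bg_pool))
      stop_genefam("background gene budget exhausted; raise n_background_genes")
    out <- bg_pool[seq_len(n)]; bg_pool <<- bg_pool[-seq_len(n)]
    out
  }
  arr_lgs <- intersect(DEFAULT_ARRAY_LGS, lgs)
  if (!length(arr_lgs)) arr_lgs <- lgs
  for (a in seq_along(arr_sizes)) {
    sz <- arr_sizes[a]
    members <- fam_pool[seq_len(sz)]; fam_pool <- fam_pool[-seq_len(sz)]
    lg <- arr_lgs[(a - 1L) %% length(arr_lgs) + 1L]
    items <- integer(); famflag <- logical()
    for (m in seq_len(sz)) {
      items <- c(items, members[m]); famflag <- c(famflag, TRUE)
      if (m < sz) {
        nb <- sample(0:max_intervening, 1L)
        if (nb) { items <- c(items, -take_bg(nb)); famflag <- c(famflag, rep(FALSE, nb)) }
      }
    }
    blocks[[length(blocks) + 1L]] <- list(lg = lg, items = items)
    arrays[[length(arrays) + 1L]] <-
      data.frame(seqid = lg, size = sz,
                 members = paste(fam_ids[members], collapse = ","),
                 stringsAsFactors = FALSE)
  }
  # isolated singles: uneven spread over all LGs
  lg_w <- as.numeric(stats::rgamma(n_linkage_groups, shape = 2))
  for (g in fam_pool) {
    lg <- sample(lgs, 1L, prob = lg_w)
    blocks[[length(blocks) + 1L]] <- list(lg = lg, items = g)
  }
  # assemble per-LG orderings: blocks separated by >= max_intervening + 1
  # background genes so isolated genes never chain into arrays
  per_lg_items <- setNames(vector("list", n_linkage_groups), lgs)
  by_lg <- split(blocks, vapply(blocks, `[[`, character(1L), "lg"))
  for (lg in names(by_lg)) {
    bl <- by_lg[[lg]]
    bl <- bl[sample(length(bl))]
    items <- -take_bg(sample(1:3, 1L))
    for (b in bl) {
      items <- c(items, b$items,
                 -take_bg(max_intervening + 1L + sample(0:2, 1L)))
    }
    per_lg_items[[lg]] <- items
  }
  # leftover background genes: spread across LGs at the tails
  while (length(bg_pool)) {
    lg <- sample(lgs, 1L)
    n <- min(length(bg_pool), sample(1:10, 1L))
    per_lg_items[[lg]] <- c(per_lg_items[[lg]], -take_bg(n))
  }

  # ---- coordinates and exon structures ----
  # planted exon-count distribution for family genes: 16 intronless, 5
  # high-exon (16-31), the rest 2-12 (the published range is 1-31)
  n_intronless <- min(16L, n_family_genes)
  n_high <- min(5L, max(0L, n_family_genes - n_intronless))
  fam_exn <- integer(n_family_genes)
  pick <- sample(seq_len(n_family_genes))
  fam_exn[pick[seq_len(n_intronless)]] <- 1L
  if (n_high)
    fam_exn[pick[n_intronless + seq_len(n_high)]] <- sample(16:31, n_high,
                                                            replace = TRUE)
  left <- which(fam_exn == 0L)
  fam_exn[left] <- sample(2:12, length(left), replace = TRUE)
  bg_exn <- sample(1:10, n_background_genes, replace = TRUE)

  rows <- list()
  emit <- function(item, seqid, at) {
    fam <- item > 0L
    idx <- abs(item)
    exn <- if (fam) fam_exn[idx] else bg_exn[idx]
    ex <- make_exons(exn)
    span <- max(ex[, 2L])
    start <- at
    ex[, 1L] <- ex[, 1L] + start - 1L
    ex[, 2L] <- ex[, 2L] + start - 1L
    rows[[length(rows) + 1L]] <<- list(
      gene_id = if (fam) fam_ids[idx] else bg_ids[idx],
      seqid = seqid, start = start, end = start + span - 1L,
      strand = sample(c("+", "-"), 1L), exons = ex)
    start + span - 1L + sample(200:2000, 1L)
  }
  for (lg in lgs) {
    at <- sample(1000:5000, 1L)
    for (item in per_lg_items[[lg]]) at <- emit(item, lg, at)
  }
  for (i in seq_along(unanch)) {
    emit(unanch[i], sprintf("Scaffold%03d", i), sample(1000:5000, 1L))
  }
  genes <- gene_models(
    gene_id = vapply(rows, `[[`, character(1L), "gene_id"),
    seqid = vapply(rows, `[[`, character(1L), "seqid"),
    start = vapply(rows, `[[`, numeric(1L), "start"),
    end = vapply(rows, `[[`, numeric(1L), "end"),
    strand = vapply(rows, `[[`, character(1L), "strand"),
    exons = lapply(rows, `[[`, "exons"))

  truth_genes <- data.frame(gene_id = fam_ids, subfamily = subfam,
                            n_repeats = REPEATS_PER_SUBFAMILY[subfam],
                            ortholog_ref = orth_ref,
                            exon_count = fam_exn,
                            anchored = !(seq_len(n_family_genes) %in% unanch),
                            row.names = NULL, stringsAsFactors = FALSE)
  arrays <- if (length(arrays)) do.call(rbind, arrays) else
    data.frame(seqid = character(), size = integer(), members = character(),
               stringsAsFactors = FALSE)
  list(genes = genes,
       proteins = protein_records(c(fam_ids, bg_ids), c(proteins, bg_seqs)),
       references = protein_records(ref_ids, ref_seqs),
       reference_labels = data.frame(gene_id = ref_ids, label = ref_labs,
                                     stringsAsFactors = FALSE),
       truth = list(genes = truth_genes, arrays = arrays,
                    subfamily_counts = table(factor(subfam,
                        levels = names(REPEATS_PER_SUBFAMILY)))))
}

#' Default planted tissue-pattern allocation
#'
#' 173 genes expressed in all five tissues, 19 silent, eight
#' tissue-specific (2 root, 1 stem, 1 leaf, 1 capsule, 3 seed), the
#' remainder given random 2-4 tissue patterns.
#'
#' @return a list understood by [simulate_expression()]
#' @export
default_tissue_spec <- function() {
  list(tissues = TISSUES, n_common = 173L, n_silent = 19L,
       specific = c(root = 2L, stem = 1L, leaf = 1L, capsule = 1L,
                    seed = 3L))
}

#' Default planted stress-response plan
#'
#' Five waterlogging trajectory groups of sizes 39/12/12/22/29 and four
#' drought groups of sizes 5/6/8/27, with 28 genes differentially expressed
#' under both stresses; planted fold changes 6 (up) and 1/6 (down).
#'
#' @return a list understood by [simulate_expression()]
#' @export
default_stress_spec <- function() {
  list(waterlogging = list(time_points = c("wl_3h", "wl_9h", "wl_15h"),
                           groups = WATERLOGGING_GROUPS,
                           sizes = WATERLOGGING_SIZES),
       drought = list(time_points = c("dr_d1", "dr_d2", "dr_d3"),
                      groups = DROUGHT_GROUPS,
                      sizes = DROUGHT_SIZES),
       n_shared = 28L,      # DEGs planted in both stresses
       fc_up = 6, fc_down = 1 / 6)
}

#' Simulate tissue and stress expression with planted patterns
#'
#' Tissue RPKM: expressed tissues get a log-normal base well above the
#' RPKM > 1 threshold, silent tissues sit near 0.05, and multiplicative
#' log-normal noise (`noise_sd` on the log scale) is applied on top. Stress
#' tables plant fold changes of 6 (up) and 1/6 (down) against the control
#' column — a 2x margin beyond the 2 / 0.5 calling thresholds, so calls
#' survive noise at `noise_sd <= 0.25`.
#'
#' @param truth the `truth` element from [simulate_genome()]
#' @param tissue_spec see `default_tissue_spec()`
#' @param stress_spec see `default_stress_spec()`
#' @param noise_sd log-scale noise standard deviation (default 0.2)
#' @param seed RNG seed
#' @return list with matrices `tissues`, `waterlogging` (control + 3 time
#'   points), `drought` (control + 3 periods) over the family genes, and
#'   `truth` augmented with `tissue_pattern`, `waterlogging_group`,
#'   `drought_group` columns
#' @export
simulate_expression <- function(truth, tissue_spec = default_tissue_spec(),
                                stress_spec = default_stress_spec(),
                                noise_sd = 0.2, seed = 1L) {
  if (noise_sd < 0) stop_genefam("noise_sd must be >= 0")
  set.seed(seed + 101L)
  tg <- truth$genes
  n <- nrow(tg)
  tissues <- tissue_spec$tissues
  nt <- length(tissues)
  need <- tissue_spec$n_common + tissue_spec$n_silent +
    sum(tissue_spec$specific)
  if (need > n)
    stop_genefam("tissue_spec allocates more genes than the family holds")
  if (!all(names(tissue_spec$specific) %in% tissues))
    stop_genefam("unknown tissue in tissue_spec$specific")

  # ---- assign tissue patterns ----
  pool <- sample(n)
  pat <- matrix(FALSE, n, nt, dimnames = list(tg$gene_id, tissues))
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  pat[take(tissue_spec$n_common), ] <- TRUE
  take(tissue_spec$n_silent)                       # stay all-FALSE
  for (ts in names(tissue_spec$specific))
    pat[take(tissue_spec$specific[[ts]]), ts] <- TRUE
  for (g in pool) pat[g, sample(nt, sample(2:(nt - 1L), 1L))] <- TRUE

  base <- matrix(0.05, n, nt, dimnames = dimnames(pat))
  base[pat] <- rlnorm(sum(pat), meanlog = log(20), sdlog = 0.5)
  noise <- matrix(rlnorm(n * nt, 0, noise_sd), n, nt)
  tissue_mat <- base * noise

  # ---- stress group assignment ----
  wl <- stress_spec$waterlogging; dr <- stress_spec$drought
  n_wl <- sum(wl$sizes); n_dr <- sum(dr$sizes)
  n_sh <- stress_spec$n_shared
  if (n_wl + n_dr - n_sh > n)
    stop_genefam("stress DEG plan exceeds family size")
  ord <- sample(n)
  wl_genes <- ord[seq_len(n_wl)]
  dr_genes <- ord[(n_wl - n_sh + 1L):(n_wl - n_sh + n_dr)]
  wl_group <- rep(NA_character_, n)
  wl_group[wl_genes] <- rep(names(wl$sizes), wl$sizes)
  dr_group <- rep(NA_character_, n)
  dr_group[dr_genes] <- rep(names(dr$sizes), dr$sizes)

  plant_stress <- function(groups, group_of, time_points) {
    ctrl <- rlnorm(n, meanlog = log(10), sdlog = 0.4)
    m <- matrix(0, n, 1L + length(time_points),
                dimnames = list(tg$gene_id, c("control", time_points)))
    m[, "control"] <- ctrl * rlnorm(n, 0, noise_sd)
    for (j in seq_along(time_points)) {
      fc <- rep(1, n)
      for (gname in names(groups)) {
        verdict <- groups[[gname]][j]
        sel <- which(group_of == gname)
        if (verdict == "UP") fc[sel] <- stress_spec$fc_up
        if (verdict == "DOWN") fc[sel] <- stress_spec$fc_down
      }
      m[, 1L + j] <- ctrl * fc * rlnorm(n, 0, noise_sd)
    }
    m
  }
  wl_mat <- plant_stress(wl$groups, wl_group, wl$time_points)
  dr_mat <- plant_stress(dr$groups, dr_group, dr$time_points)

  tg$tissue_pattern <- apply(pat, 1L, function(x)
    if (!any(x)) "NOT_EXPRESSED" else paste(tissues[x], collapse = ","))
  tg$waterlogging_group <- wl_group
  tg$drought_group <- dr_group
  truth$genes <- tg
  list(tissues = tissue_mat, waterlogging = wl_mat, drought = dr_mat,
       truth = truth)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Ct values follow `Ct = base_ct - log2(expression) + Normal(0, ct_sd)`
#' with control expression 1 and stress expression equal to the planted
#' fold change; the reference gene has fold change 1 by construction.
#'
#' @param genes character vector of target gene ids
#' @param fold_changes positive planted fold changes, one per gene
#' @param reference_gene reference gene id (default `"ACTIN"`)
#' @param seed RNG seed
#' @param n_replicates biological replicates (default 3)
#' @param base_ct baseline cycle number (default 25)
#' @param ct_sd Ct noise standard deviation (default 0.15)
#' @return long data frame `gene_id`, `condition`, `replicate`, `ct`
#' @export
simulate_qpcr <- function(genes, fold_changes, reference_gene = "ACTIN",
                          seed = 1L, n_replicates = 3L, base_ct = 25,
                          ct_sd = 0.15) {
  if (length(genes) != length(fold_changes))
    stop_genefam("genes and fold_changes lengths differ")
  if (any(fold_changes <= 0)) stop_genefam("fold changes must be positive")
  set.seed(seed + 202L)
  rows <- list()
  add <- function(gene, cond, expr) {
    for (r in seq_len(n_replicates))
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene, condition = cond, replicate = r,
        ct = base_ct - log2(expr) + rnorm(1L, 0, ct_sd),
        stringsAsFactors = FALSE)
  }
  for (i in seq_along(genes)) {
    add(genes[i], "control", 1)
    add(genes[i], "stress", fold_changes[i])
  }
  add(reference_gene, "control", 1)
  add(reference_gene, "stress", 1)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and write the full synthetic dataset
#'
#' Orchestrates [simulate_genome()], [simulate_expression()] and
#' [simulate_qpcr()] and writes `proteins.fasta`, `genes.gff3`,
#' `references.fasta`, `ref_labels.tsv`, `tissues.tsv`, `waterlogging.tsv`,
#' `drought.tsv`, `qpcr.tsv` and `truth.json` to `out_dir`.
#'
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed governing every draw
#' @param noise_sd,tissue_spec,stress_spec passed to
#'   [simulate_expression()]
#' @param ... passed to [simulate_genome()]
#' @return the in-memory dataset (list), invisibly
#' @export
simulate_dataset <- function(out_dir, seed = 1L, noise_sd = 0.2,
                             tissue_spec = default_tissue_spec(),
                             stress_spec = default_stress_spec(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(seed = seed, ...)
  expr <- simulate_expression(gen$truth, tissue_spec = tissue_spec,
                              stress_spec = stress_spec,
                              noise_sd = noise_sd, seed = seed)
  gen$truth <- expr$truth
  # qPCR panel: ten genes spanning the planted verdict range
  set.seed(seed + 303L)
  panel <- sample(gen$truth$genes$gene_id, 10L)
  folds <- c(22, 8, 4, 1, 1, 1, 0.4, 0.2, 0.1, 3)
  qpcr <- simulate_qpcr(panel, folds, seed = seed)
  write_fasta(gen$proteins, file.path(out_dir, "proteins.fasta"))
  write_fasta(gen$references, file.path(out_dir, "references.fasta"))
  write.table(gen$reference_labels, file.path(out_dir, "ref_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gff3(gen$genes, file.path(out_dir, "genes.gff3"))
  write_expression_tsv(expr$tissues, file.path(out_dir, "tissues.tsv"))
  write_expression_tsv(expr$waterlogging, file.path(out_dir, "waterlogging.tsv"))
  write_expression_tsv(expr$drought, file.path(out_dir, "drought.tsv"))
  write.table(qpcr, file.path(out_dir, "qpcr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- gen$truth
  truth_json$subfamily_counts <- as.list(truth_json$subfamily_counts)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(genes = gen$genes, proteins = gen$proteins,
                 references = gen$references,
                 reference_labels = gen$reference_labels,
                 truth = gen$truth, tissues = expr$tissues,
                 waterlogging = expr$waterlogging, drought = expr$drought,
                 qpcr = qpcr))
}
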