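---
title: "genefam: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genefam: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefam)
```

`genefam` implements the standard published workflow for a genome-wide
transcription-factor family survey. This vignette documents the models and
their assumptions, every tunable threshold with its default and rationale,
the numerical choices, what the synthetic world does and does not emulate,
and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Domain detection and subfamily classification

**Model.** The family-defining DNA-binding module is an imperfect tandem
repeat of about 52 amino acids, carried in one to four copies. Published
surveys detect it with a profile HMM (HMMER against the Pfam domain model)
plus a confirmatory scan in a second tool. `genefam` replaces both with a
single position-weight-matrix (PWM) scanner: a window of length $L$
starting at offset $o$ scores

$$S(o) = \sum_{p=1}^{L} w_{p,\,x_{o+p-1}}, \qquad
  w_{p,a} = \log_2 \frac{\pi_{p,a}}{1/20},$$

and every window with $S \ge \theta$ is a candidate repeat. Overlaps are
resolved greedily by descending score (ties: smaller start), giving a
maximal non-overlapping hit set. The subfamily is a pure function of the
hit count: 0 → not family, 1 → `1R`, 2 → `R2R3`, 3 → `R1R2R3`, ≥ 4 →
`ATYPICAL`. This preserves the pipeline semantics (find above-threshold
repeat occurrences; count them) while remaining fully testable against an
exhaustive window-enumeration oracle; it does not model insert/delete
states, so a repeat interrupted by an insertion scores as background — a
deliberate scope cut relative to a profile HMM.

**Thresholds.** $\theta$ defaults to 60% of the consensus self-score
(`profile_threshold_frac = 0.6`). For the shipped profile
(`default_repeat_profile()`, self-score ≈ 222 bits) this is ≈ 133 bits. A
uniform-background window has expected score ≈ −4.5 bits/position, about
24 standard deviations below $\theta$, so false positives are effectively
impossible; a sampled motif copy sits 5σ above it, and even at 10%
per-position substitution noise the margin is ≈ 2.6σ per copy — the basis
of the ≥ 95% closure criterion. Residues outside the 20-letter alphabet
score the worst value of their column (with a warning); `X` scores 0 and
is excluded from every numeric computation.

**The profile fixture is arbitrary but versioned.** No PWM is published
for the domain; the shipped 52-column profile is built deterministically
from a fixed consensus (with the tryptophan periodicity characteristic of
the real repeat) by giving the consensus residue probability 0.97 per
column and spreading the rest with Dirichlet-style perturbation from a
fixed internal generator — regenerating it always yields the same bytes
(`inst/extdata/repeat_pwm.txt`).

**pI and Mw.** The isoelectric point solves $Q(\mathrm{pH}) = 0$ by
bisection to $|Q| < 10^{-4}$, where positive groups (N-terminus, K, R, H)
contribute $1/(1+10^{\mathrm{pH}-pK_a})$ and negative groups (C-terminus,
D, E, C, Y) contribute $-1/(1+10^{pK_a-\mathrm{pH}})$; $Q$ is strictly
decreasing in pH, so the root is unique and the termini guarantee it
exists. The pKa table is the Bjellqvist-style set used by the common web
tool (N-term 7.5, C-term 3.55, K 10.0, R 12.0, H 5.98, D 4.05, E 4.45,
C 9.0, Y 10.0) and is pluggable. Molecular weight sums *average* residue
masses plus one water (18.01524 Da) and is reported in daltons — the
original survey prints dalton-magnitude values labeled "kDa", an
inconsistency we do not reproduce.

## 2. Chromosomal mapping and tandem arrays

Family genes are ordered by linkage group (natural order `LG01..LG16`),
then start coordinate, unanchored scaffold genes last (scaffold id, then
start), and named `prefix`+1..N; ties on (seqid, start) break by gene id
and naming is deterministic. Strand is recorded but never used.

Two family genes are *chained* when at most `max_intervening = 3` genes of
any family status lie strictly between them on the same linkage group —
distance counted in genes, not kilobases, per the convention the surveys
cite. Arrays are the transitive closure of chaining (A–B and B–C linked
puts A, B, C in one array), so reported sizes can exceed pairs. Headline
percentages (anchored share, tandem share of anchored) round half-up to
integers, matching how such surveys print "95%" and "20%"; the TSVs carry
two decimals. Base R `round()` rounds half to even and is not used for
these figures.

## 3. Phylogeny

**Distances.** The published workflow aligns with ClustalW and builds a
neighbor-joining tree in MEGA. Full progressive multiple alignment is
deliberately replaced by all-pairs global alignment (Needleman–Wunsch,
affine gaps: a gap of length $k$ costs `gap_open` $+ k\,\cdot$
`gap_extend`, defaults 10 and 0.2 — the penalties the surveys state)
under BLOSUM62 (configurable; no matrix is published). The p-distance is
mismatches over counted columns, counting residue-vs-gap as mismatch and
excluding gap–gap columns; entries therefore lie in $[0,1]$. This keeps
the data-flow shape (distance matrix → NJ) while being property-testable;
it is a method stand-in, not a ClustalW reproduction.

**Neighbor joining.** Classical Saitou–Nei: join the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - r_i - r_j$; ties break by the lexicographically
smallest pair of representative taxon labels so the tree is
input-order-independent. Negative branch estimates are clamped to zero
with the deficit moved to the sibling branch, preserving path lengths
(standard practice). For additive input the recovered path metric equals
the input to numerical precision — the suite checks $10^{-9}$ on random
trees up to 12 taxa. Two taxa are represented as two half-length edges
through a degree-2 node so the path length equals $d$.

**Bootstrap.** Column resampling needs a single fixed column space, which
all-pairs alignments do not provide; the one place an MSA is unavoidable.
`genefam` builds a *star alignment* — every sequence aligned to the
longest one, whose positions define the columns; insertions relative to
the center are dropped. Each replicate resamples columns with replacement,
recomputes p-distances and NJ, and an internal edge's support is the
percentage of replicates containing its bipartition. Rows are
canonicalized by taxon id before resampling, so supports are invariant to
input order at a fixed seed. The published setting is 1000 replicates;
tests and the CLI default to `bootstrap_reps = 100` purely for runtime —
a knob, not a semantic change.

**Subgroups.** Queries join the references in one NJ tree and take the
label of the nearest reference by path length; beyond
`subgroup_ceiling = 0.75` they stay `UNASSIGNED`, emulating
lineage-specific subgroups. The ceiling sits between typical
within-subgroup path distances (≈ 0.2–0.5 at the divergence the generator
plants) and the ≈ 0.95 expected for unrelated proteins (random 20-letter
agreement 1/20); it is configuration, and the subgroup count is emergent —
the package never forces a particular number of subgroups.

## 4. Orthology

BLASTp heuristics are replaced by exact Smith–Waterman (strictly more
sensitive; the synthetic proteomes are small enough that exactness is
affordable). Hits must pass both $E = K m n e^{-\lambda S} \le$
`evalue_max` $= 10^{-40}$ and positives fraction ≥ `min_similarity`
$= 0.70$ — the thresholds the surveys state. "Similarity" is read as
BLAST's *positives*: identities plus positive-scoring substitutions, over
alignment length including gaps. $\lambda = 0.267$, $K = 0.041$ are the
gapped BLOSUM62 (11/1) constants; the surveys never state them, so both
are arguments. The best hit per query (score, then E-value, then
lexicographic reference id) transfers the reference's label;
reciprocal-best filtering is not applied because the published criterion
is one-directional. Because family members share the planted domain,
near-threshold cross-hits between different ortholog groups can pass the
filters — only *best-hit* assignments feed the copy-number summary, which
therefore stays a function of query.

## 5. Expression

"Expressed" means RPKM > `rpkm_expressed` = 1, evaluated per tissue
independently; a gene's presence pattern is the tissue subset where it
passes, and patterns are grouped with canonical numbering (descending
size, ties by pattern bit-string, Roman labels). The original I–XXV labels
depend on unpublished ordering and are not claimed. DEG calling is pure
fold change — `(stress + ε)/(control + ε)` with ε = 0.01 RPKM guarding
zeros (`fold_epsilon`, configurable; the surveys are silent on zeros) —
`UP` above `fc_up = 2`, `DOWN` below `fc_down = 0.5`, strict inequalities.
No dispersion model and no p-values, faithfully to the method being
reproduced; the cost is an irreducible false-positive rate under noise
(see §6). Trajectory clusters are exact verdict signatures. The
`2^{-\Delta\Delta C_t}` computation pairs replicates by id and summarizes
with the geometric mean (arithmetic mean on the $\Delta\Delta C_t$ scale),
the scale on which Ct noise is additive; the reference gene against itself
is identically 1.

## 6. The synthetic world

The generator *states* a world at the published scale: 287 family genes,
subfamily mix 51.22/46.69/1.74/0.35 (a recorded multinomial draw), 16
linkage groups, 14 unanchored genes, 22 planted arrays (13×2 + 7×3 + 2×4 =
55 genes) on the eleven linkage groups the survey names, 16 intronless
genes and exon counts spanning 1–31, five tissues with 173
all-tissue/19 silent/8 tissue-specific genes, waterlogging groups
39/12/12/22/29 and drought groups 5/6/8/27 with 28 genes shared, planted
stress fold changes 6 and 1/6 (a 2× margin beyond the 2/0.5 thresholds, so
calls survive log-normal noise at sd ≤ 0.25), qPCR Ct =
base − log₂(expression) + N(0, 0.15), and an ortholog fraction of 133/287
with reference copy numbers drawn from 1..6. Values the survey does not
state — background gene count (1600), protein lengths, expression noise
sd 0.2, co-ortholog divergence 4% / reference divergence 8%, motif noise
5% — were chosen once as field-realistic and are documented arguments, not
tuning dials.

Design points worth naming:

* **Isolated family genes are placed ≥ 4 background genes from any other
  family gene**, so the planted arrays are exactly the detectable ones —
  the tandem detector must recover them with no splits or merges, and the
  suite checks set equality, not overlap.
* **Co-ortholog divergence is confined to non-motif positions.** Mutating
  whole sequences stacked ortholog divergence on motif noise and broke the
  detection-margin arithmetic at the stated 10% noise bound; restricting
  divergence to the background models domain conservation, which is also
  the biologically standard expectation.
* **Group V of the waterlogging plan is (UP, DOWN, UP)** — the literal
  reading of "down-regulated at 9 h but induced at 3 h and 15 h".
* Expression matrices cover family genes only (the surveys profile the
  family, not the genome); RPKM is generated directly — no read
  simulation, no count sampling, no nucleotide sequences.

**What a green test establishes — and what it does not.** Recovery
criteria (≥ 95% subfamily labels under ≤ 10% motif noise, 100% noiseless;
exact tandem arrays; ≥ 95% DEG recall; ≥ 95% ortholog recovery) certify
the *detectors* against a world whose signal margins are stated above.
They do not certify performance on real proteomes, where repeats diverge
far beyond i.i.d. substitution noise, arrays are disrupted by assembly
artifacts, and expression noise is not log-normal. Note also that DEG
*recall* is the planted criterion; pure fold-change calling has no error
control, so at noise sd 0.2 some of the 173 planted non-DEGs are called —
which is why the stress Venn bookkeeping targets are computed from the
printed group sizes, not from simulation.

## 7. Numerical and formatting conventions

Coordinates are 1-based inclusive everywhere (the GFF3 dialect); genes
without exon features are single-exon (every gene needs an exon count for
the profile). Reports are TSV, UTF-8, `.` decimal, percentages printed
with two decimals ("51.22" style); report row order is sorted so identical
inputs give byte-identical files. pI bisection terminates at charge
$|Q| < 10^{-4}$ (≈ 10⁻⁴ pH accuracy against a dense-grid oracle).
Alignment traceback ties prefer diagonal, then up (gap in the second
sequence), then left. All randomness flows through explicit seeds; the
generator's fixture PWM uses its own fixed Lehmer stream so it never
perturbs the caller's RNG state.

## 8. Known limitations

No profile-HMM states (insertions inside a repeat defeat the scanner); no
true multiple alignment (star alignment drops insertions relative to the
center, slightly flattening bootstrap variance); E-values lack
finite-length edge corrections; no synteny, Ka/Ks, or GO inference beyond
label transfer; no figures — matrix/table outputs replace heatmaps and
chromosome plots. The acceptance targets cover the survey's internally
reproducible arithmetic; headline counts that depend on the real proteome
(287 detected in the real genome, 133 real orthologs, real pI range) are
out of reach without the original databases and are deliberately not
claimed.
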