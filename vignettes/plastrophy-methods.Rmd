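---
title: "Methods: inferring structural degradation of heterotroph plastomes"
author: "plastrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring structural degradation of heterotroph plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`plastrophy` analyzes structurally degraded plastid genomes — the kind
produced when a parasitic or mycoheterotrophic plant relaxes selection on
photosynthesis. This vignette explains the models and procedures behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the problem left them open.

## The genome model

A `plastome` is a circular DNA sequence with a flat feature table.
Internal coordinates are 0-based half-open; a feature whose `end` exceeds
the genome length wraps the origin, and all interval logic is
rotation-invariant (`rotate_plastome()` shifts every coordinate by the
same offset mod length). On disk, sequences travel as FASTA and features
as a GFF3 subset (1-based inclusive `gene` lines carrying `Name=` and
`status=` attributes); the round trip is byte-exact, including wrapped
features. Gene symbols map to functional classes by prefix
(psa/psb/pet/atp/ndh/rbc/chl/rpo/rpl/rps/trn/rrn, bundled in
`inst/extdata/gene_classes.tsv` and overridable).

## Synthetic degraded plastomes

The generator is a first-class module: it gives every downstream stage a
planted ground truth.

`make_reference_plastome()` builds an IR-less photosynthetic reference
with the canonical 82 protein / 32 tRNA / 4 rRNA complement (real plastid
gene symbols). Protein genes are unambiguous ORFs by construction — ATG,
interior drawn from the 61 sense codons, TAA — because the classifier's
reading-frame rules need a reference in which any internal stop is a
lesion, never background. Default sizes (protein genes 300–1800 bp,
spacers ~200–450 bp) give a ~130 kb genome, the scale of an IR-less
conifer plastome.

`degrade_plastome()` applies a scenario: pseudogenizing lesions
(premature stop = an in-frame TAA at a random codon within 10–80% of the
CDS, so the truncation is unambiguous under the classifier's 90% rule;
frameshift = 1 bp inserted or deleted in the 10–50% window; truncation =
loss of the terminal 30%), deletions (gene plus half of each flanking
spacer), segmental inversions (between spacer midpoints), and an IR gain:
a run of genes whose span approximates the target IR length is copied in
inverted orientation into a spacer on the opposite side of the circle,
with duplicated features suffixed `_ir`. After insertion the four
IR/single-copy junction bases are adjusted so the planted repeat is
*exactly maximal*: without this, one-base chance extensions (probability
1/4 per side) would make "exact boundary recovery" ill-defined.

`simulate_reads()` draws `round(coverage * L / (2 * read_len))` fragments
uniformly on the circle from both strands, Gaussian fragment lengths
(default 650 +/- 65 bp, truncated at the read length), 150-bp mates read
inward, and uniform substitution errors only — indel errors would add
nothing to planted-truth tests. FASTQ qualities are constant because no
stage uses them. `simulate_insert_fragments()` emulates
nuclear/mitochondrial copies of a deleted gene: reads confined to a
contiguous window covering a fraction of the gene, at a chosen fraction
of the main coverage.

What the generator does **not** emulate: GC-related coverage biases and
rRNA coverage spikes (real data show them; no parameters are published to
calibrate them), real Illumina error profiles, and assembly artifacts —
the "assembly" handed to detection is the true degraded sequence. Passing
tests therefore demonstrate correctness of the inference rules under the
stated read model, not robustness to every artifact of real sequencing.

## IR detection

`find_inverted_candidates()` reports maximal inverted self-matches (>= 1
kb by default, separating large-IR calls from census-scale inverted
repeats; `min_len` under 50 bp is refused). The default `max_mismatch =
0` reflects the near-identity of real IR copies. Candidates are validated
by reads placed with the built-in mapper: exact 31-mer seeds at three
offsets per read, both strands, leftmost placement wins. Two signals
feed `call_ir()`:

- **split pairs** — pairs with one mate inside an IR copy and the other
  anchored in single-copy sequence with discordant geometry (same-strand
  mates, or an implied span beyond twice the insert size). These arise
  because a read from one copy is placed at the other; they cannot occur
  for an interval of a single-copy genome. Per-junction support counts
  pairs whose single-copy mate lies within one insert length of each of
  the four IR/single-copy junctions.
- **coverage ratio** — mean depth inside the interval over mean flank
  depth; a collapsed assembly (one copy removed) shows ~2x.

A candidate is accepted iff it reaches `min_ir_len` (1000 bp) and either
all four junctions have >= `min_pairs` (5) supporting pairs or the
coverage ratio falls in [1.7, 2.3]. These numbers are package choices
(the underlying field practice is visual read-stack inspection); they are
exposed in the configuration and were chosen for 50–200x simulated data.
Boundaries are the outermost bases of the maximal sequence match — read
evidence validates but never moves them.

## Gene-status classification

For each reference gene the target is searched with exact 21-mers every
10 bp (both strands, densest position-cluster wins), the candidate
window is aligned locally (match +2, mismatch -3, gap open -5, extend -2)
and the rules applied:

| call | rule |
|---|---|
| absent | no homolog at >= 60% identity covering >= 30% of the CDS |
| intact | covered fraction >= 0.9, no internal stop before 90% of the protein, net indel = 0 mod 3 |
| pseudogene | homolog found and any lesion fires (premature_stop, frameshift, truncated) |

tRNA/rRNA genes have no reading frame: intact requires covered >= 0.9 and
identity >= 80%. A frame-restoring indel pair (net 0 mod 3) does not by
itself demote a gene, but any stop it introduces does. All thresholds
are package operationalizations of qualitative practice ("truncated or
frameshifted reading frame") and sit in
`classification_thresholds()`. "Truncated" means a predicted protein
under 90% of reference length — tolerant of terminal sloppiness, strict
on real truncations. Intron structure is not modeled: the synthetic
genes are single-exon, and on real annotations classification should be
run on spliced CDS.

`verify_absence()` maps the full read pool onto the reference CDS
(21-mer seeds): any covered span reveals a retained fragment, and its
depth relative to the main plastome coverage is reported — relative
depth below 1 is the read-level analogue of the low k-mer coverage that
betrays extra-plastomic (nuclear or mitochondrial) inserts.

## Repeat censuses

A repeat pair is a *maximal window along a diagonal* of the comparison
between the sequence and a transformed copy (identity, reversed,
complemented, reverse-complemented): at most `k` mismatches, not
extendable on either side without exceeding `k`. The engine seeds with
exact matches of length `floor(min_len / (k + 1))` (pigeonhole-complete,
capped at 31) and extends along circular diagonals; a brute-force
diagonal-scan oracle pins the definition in the tests. Defaults follow
the classical plastome screen: min length 20 bp, Hamming distance 3,
e-value <= 1e-3. The e-value is package-defined — candidate pair count
(4 n^2) times the binomial tail P(>= l - k matches at p = 1/4) — since
the classical tool's exact formula is not published; correctness rests on
the oracle, not on e-values. Each unordered pair is reported once;
self-identical pairs and pairs overlapping by more than half the shorter
interval are suppressed (tandem arrays belong to the tandem scanner).
Perfect tandem arrays require total length >= 10 bp, at least two full
copies, and a primitive unit of 2–50 bp, reported at the smallest unit.

## Rearrangements over a fixed phylogeny

Genomes are reduced to shared single-copy anchors (genes, or unique
31-mers), each genome is linearized at a canonical shared anchor
(rotation/reflection-invariant, the convention of whole-genome aligners
operating on linearized plastome FASTA), and maximal runs of anchors
adjacent and equioriented in every genome become locally collinear
blocks. One IR copy must be collapsed first (`collapse_ir()`), since a
large duplication breaks single-copy anchoring.

Block orders become signed permutations (first genome = identity).
`breakpoint_distance()` counts signed adjacencies (an adjacency and its
reverse complement identified; linear framing adds end caps).
`reversal_distance()` is exact up to 10 blocks via iterative-deepening
search under the breakpoint-graph cycle bound `n + 1 - c`, which changes
by at most one per reversal and is therefore an admissible, consistent
heuristic; hurdle corrections are unnecessary because the search is
exact. Larger instances return the cycle lower bound, flagged.

`count_tree_rearrangements()` labels internal nodes of a fixed rooted
tree and sums branch distances. Exact minimization is a reversal-median
(Steiner) problem; the package uses Sankoff dynamic programming over a
label pool containing the leaf permutations plus intermediate states on
optimal reversal paths between them, refined by single-reversal hill
climbing, restarts from uniform leaf labelings, and a few seeded
perturbation kicks. The output is an upper bound on the true minimum
(flagged `heuristic = TRUE`) and never less than the largest pairwise
leaf distance; on planted simulations (Poisson(1.2) reversals per branch
of 6-leaf trees, 8 blocks) it stays within the planted event count in
all acceptance scenarios, with rare hard instances (about 1–2% under
other random regimes) exceeding it by one.

## Correlated trait evolution

Two traits evolving by Brownian motion on a tree with branch lengths in
expected-variance units have tip covariance `R (x) C`: `R` is the 2x2
rate matrix (variances sigma_x^2, sigma_y^2 per unit branch length,
covariance sigma_xy) and `C[i, j]` the depth of the MRCA of tips i and j.
The log-likelihood is evaluated through per-trait whitening by the
Cholesky factor of `C` (never the dense 2n x 2n matrix, which serves as
the test oracle). The ML fit is closed-form — GLS root means, then the
whitened cross-product estimate of `R`; the independent model zeroes
sigma_xy — so no iterative optimizer is involved and the free model's
likelihood dominates the null's exactly. Zero-length terminal branches
are floored at 1e-8 of tree height to keep `C` nonsingular; perfectly
collinear traits are handled by flooring 1 - r^2 at 1e-12, which drives
the LRT p-value below 1e-6 rather than overflowing.

The raw likelihood ratio for sigma_xy = 0 equals `-n log(1 - r^2)` with
`r` the whitened-residual correlation. Against chi-square(1) this is
anticonservative in small samples (type-I error near 0.08 at n = 16),
so the reported p-value uses a Bartlett-type correction: under the null
`r^2 ~ Beta(1/2, (nu - 1)/2)` with `nu = n - 1` residual dimensions,
giving `E[LR] = n (psi(nu/2) - psi((nu-1)/2))`; the statistic is rescaled
to unit null mean before the chi-square tail. Measured type-I error is
0.052 over 10,000 null simulations on a 16-taxon tree, with near-uniform
p-values. Binary traits (IR presence, heterotrophy) are coded 0/1 and
analyzed under the same continuous random-walk model — a deliberate
simplification, flagged by a caveat in the output, appropriate for
correlation screening but not for estimating transition rates.

## Problem sizes and determinism

Every stochastic component takes an explicit seed and restores the
caller's RNG state; pipelines derive per-stage substreams from one
top-level seed, so identical configurations give byte-identical outputs.
The test and acceptance simulations use scaled references (15–25 protein
genes, ~25–35 kb, 40–100x reads) with the same lesion spectrum as the
full-size scenario; the full 82/32/4 complement is exercised by the
default pipeline and the coding-capacity worked examples. Exhaustive
oracle checks run at the scales where exhaustion is feasible: sequences
up to ~1 kb for repeat oracles, all signed permutations to n = 6 (plus
BFS tables to n = 8) for reversal distances, trees to 8 tips for dense
likelihood comparison.

## Known limitations

- The mapper is exact-seed and ungapped; it is sufficient for simulated
  reads (and replaceable by a SAM subset via `read_sam_subset()`), not a
  general aligner.
- IR isomers (flip-flop orientation) and assembly-graph evidence are out
  of scope; the IR call is sequence + read-pair based.
- The tree rearrangement total is a heuristic upper bound, not a median
  solver; translocations are out of model (single circular chromosome,
  reversals only).
- Selection analyses (omega regimes, episodic selection) are outside the
  package's scope.
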