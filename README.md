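# plastrophy

Structural and comparative analysis of reduced plastid genomes in
heterotrophic plants.

When a plant abandons photosynthesis — as parasites and mycoheterotrophs
do — selection on its plastid genome (plastome) relaxes and the genome
degrades: photosynthesis genes are deleted or pseudogenized, the
quadripartite architecture (large and small single-copy regions flanked by
a pair of large inverted repeats, LSC/SSC/IR) may be lost or, remarkably,
regained, and structural rearrangements accumulate. `plastrophy`
implements the inference chain used to characterize such genomes:

- **IR detection** — maximal inverted self-matches of the assembly,
  validated by read coverage and by *split read pairs*: pairs with one
  mate inside the repeat whose partner anchors in single-copy sequence
  with discordant geometry, the signature of a true duplication. A
  candidate is accepted when all four IR/single-copy junctions carry at
  least `min_pairs` straddling pairs, or when the interval shows the ~2x
  coverage of a collapsed assembly.
- **Quadripartite partitioning** — `partition_quadripartite()` labels the
  longer single-copy gap LSC and the shorter SSC, with the invariant
  `len(LSC) + len(SSC) + 2 len(IR) = genome length`.
- **Gene-status classification** — each reference gene is located in the
  target by exact 21-mer anchoring and local affine alignment, then
  called *intact* (homolog covering >= 90% of the CDS, no internal stop
  before 90% of the protein, net indel = 0 mod 3), *pseudogene*
  (premature stop, frameshift, or truncation), or *absent* (no homolog at
  >= 60% identity over >= 30% of the CDS). Absences are verified against
  the raw reads; covered fragments at relative depth < 1 flag copies
  residing in other genomic compartments.
- **Repeat censuses** — maximal dispersed repeats in four orientation
  classes (forward, reverse, complement, inverted; default min length
  20 bp, Hamming distance <= 3, e-value <= 1e-3) and perfect tandem
  arrays (total >= 10 bp, primitive units of 2–50 bp).
- **Rearrangement analysis** — locally collinear blocks from shared
  single-copy gene (or unique 31-mer) anchors, signed-permutation
  encodings, signed breakpoint distances, exact signed reversal distances
  (iterative-deepening search under the breakpoint-graph cycle bound
  `n + 1 - c`), and a tree-wide rearrangement total by Sankoff labeling
  with local-search refinement over a fixed phylogeny.
- **Correlated trait evolution** — two traits evolving by Brownian motion
  on a tree have tip covariance `R (x) C`, with `R` the 2x2 rate matrix
  and `C` the shared-path-length matrix. `fit_bm()` gives the closed-form
  ML fit; `lrt_correlation()` tests `sigma_xy = 0` with a small-sample
  (Bartlett-type) corrected likelihood ratio against chi-square(1).

A synthetic-data layer (`make_reference_plastome()`,
`degrade_plastome()`, `simulate_reads()`, `simulate_traits()`, ...)
generates reference/degraded plastome pairs with planted deletions,
pseudogenizations, inversions, a planted IR, low-depth insert fragments
and 150-bp paired-end reads — so every stage can be tested against known
ground truth without downloading anything.

## Worked example

```r
library(plastrophy)

ref  <- make_reference_plastome(seed = 42)            # 82 + 32 + 4 genes
scen <- heterotroph_scenario(ref, seed = 42)          # parasite-like lesions
deg  <- degrade_plastome(ref, scen, seed = 42, id = "parasite")
deg$genome
#> plastome 'parasite': 101,893 bp (circular), 100 features

reads <- simulate_reads(deg$genome, coverage = 60, error_rate = 0.005,
                        seed = 42)
det <- detect_ir(deg$genome, reads)
det$call
#> ir_call: 9,804 bp IR, copies at [16652,26456) / [65518,75322), accepted by split_pairs

partition_quadripartite(deg$genome, det$call)
#> quadripartite map: LSC 43,223 / SSC 39,062 / IR 9,804 bp each (total 101,893)
```

The call recovers the planted IR boundaries exactly (`deg$planted$ira`,
`deg$planted$irb`). Annotating the degraded genome with the generator's
truth statuses and summarizing coding capacity:

```r
ann <- deg$genome
st  <- setNames(deg$truth$status, deg$truth$gene)
ann$features$status <- unname(st[sub("_(ir|copy[0-9]+)$", "", ann$features$name)])
summarize_coding_capacity(ann)$by_type
#>           intact pseudogene absent
#>   protein     33         21      0
#>   trna        31          0      0
#>   rrna         4          0      0
```

68 unique intact genes remain (33 proteins, 31 tRNAs, 4 rRNAs); the 28
deleted proteins and one deleted tRNA have no features left to count, and
`classify_gene()` / `build_status_matrix()` recover the full
intact/pseudogene/absent truth table from sequence alone. The whole chain
— simulate, detect-ir, partition, gene-status, repeats, synteny, traits —
runs as one command with `run_pipeline(pipeline_config(seed = 1))`, or
from the shell via `inst/cli/plastrophy`.

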