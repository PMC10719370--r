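# polyrearrange

Characterizing the subgenome structure of an allotetraploid genome: where
its two subgenomes rearranged after polyploidization, which accessions
carry a large pericentromeric inversion, and how transposable-element (TE)
families drifted apart between subgenomes and their diploid progenitors.
The package is aimed at plant-genome analysts working with an
allopolyploid assembly (e.g. quinoa, *Chenopodium quinoa*, with A and B
subgenomes and diploid relatives for each) plus the usual satellite data:
gene and repeat annotations, homolog tables, resequencing alignments, and
a genetic map.

## What it computes

* **Collinear blocks** — homologous gene pairs (anchors, from BLAST
  tabular) are chained over gene-rank space by dynamic programming into
  orientation-signed blocks. A block needs at least `MATCH_SIZE = 8`
  anchors; chains break when more than `max_gap_genes = 25` ranks are
  skipped on either axis. `collinearity_summary()` reports the percentage
  of genes in collinear blocks per genome pair:
  `pct = 100 · |genes in blocks| / |genes considered|`.
* **Rearrangements** — breaks in homoeologous collinearity classified by
  rule: runs of inverted blocks → inversions; regions collinear with a
  non-homoeologous chromosome *and* lacking diploid-relative synteny →
  (reciprocal) translocations; regions whose anchors map to two disjoint
  partner regions → segmental duplications. Accounting merges overlapping
  intervals before summing bp per subgenome, and flags events `major` when
  > 1 Mb and > 100 genes.
* **Inversion genotyping** — for a reference that carries an inversion
  In(chrom)(left::right), an accession is called `absent` when ≥ 1
  discordant read pair joins ±500 bp windows at the two breakpoints with a
  recomputed insert inside a gate around the inversion span, `present`
  when no such pair exists and reads span both breakpoints, `inconclusive`
  otherwise; accessions under 5× coverage are excluded.
  `genotype_summary()` produces the ecotype × genotype distribution table.
* **Repeat dynamics** — per-family copy numbers and merged bp by
  subgenome; LTR family enrichment by log2(B/A copies) at the two-fold
  boundary, with subgenome-specific classes for zero counts and a
  highly-repeated flag above the mean per-family LTR copy number;
  attribution of the subgenome size difference to TE space; 1-Mb density
  tracks; expansion/contraction deltas against each diploid.
* **Map concordance** — markers placed by unique exact flank match
  (250 bp each side), then breaks reported where the sliding 5-marker rank
  correlation of cM vs bp changes sign (after normalizing whole-chromosome
  orientation).
* **Synthetic truth** — a seeded generator builds the whole data bundle
  (two diploids, tetraploid with planted reciprocal translocation,
  inversion and tandem duplication, biased TE families, per-accession SAM
  alignments around the inversion, marker maps) with machine-readable
  truth, so every rule is validated end to end.

## Worked example

Simulate the demo allotetraploid, chain blocks, and call rearrangements:

```r
library(polyrearrange)

sim  <- simulate_genomes(sim_config(seed = 1), sequences = FALSE)
tet  <- sim$genes$tetraploid
tetA <- tet[tet$subgenome == "A", ]; tetB <- tet[tet$subgenome == "B", ]
chain <- function(a, gq, gs) chain_collinear_blocks(dedupe_anchors(a, gq, gs), gq, gs)

blocks <- chain(sim$anchors$self, tetA, tetB)
dip    <- list(A = chain(sim$anchors$A, tetA, sim$genes$diploidA),
               B = chain(sim$anchors$B, tetB, sim$genes$diploidB))
events <- call_rearrangements(blocks, dip, tet)
events[, c("event_id", "kind", "chrom1", "start1", "end1", "chrom2", "n_genes", "span_bp")]
#>  event_id                     kind chrom1 start1   end1 chrom2 n_genes span_bp
#>     ev001                inversion   Cq3A 140187 259805   Cq3B     104  238461
#>     ev002 reciprocal_translocation   Cq2B 336822 399183   Cq1B      80  128870
#>     ev003    segmental_duplication   Cq2B  80892 102944   Cq2B      24   45559
```

All three planted events are recovered (compare `sim$truth$events`): the
inversion spanning genes 75–126 of Cq3B (reported with its interval on both
homoeologs), the 40-gene terminal swap between Cq1B and Cq2B merged into
one reciprocal translocation, and the two tandem copies of the 12-gene
duplication on Cq2B. `span_bp` is the summed interval length and `n_genes`
the distinct genes involved, the quantities that feed
`rearrangement_totals()`.

The published breakpoints of a real pericentromeric inversion illustrate
the genotyping containers:

```r
breakpoint_pair("Cq3B", 11136405, 63361214,
                insert_min = 52223700, insert_max = 52225600)
#> breakpoint pair Cq3B:11136405 / 63361214 (span 52224809 bp, insert gate [52223700, 52225600])
```

The span, 52.2 Mb, is the inversion size implied by the breakpoints, and
the insert gate brackets it: a read pair whose mates sit in the two windows
with an insert inside the gate is evidence the accession lacks the
inversion relative to this reference.

The one-shot demo (`run_all(list(out_dir = "demo", seed = 1))`, or
`inst/scripts/polyrearrange run-all`) wires every stage over the files the
generator writes and emits block, event, genotype, repeat and marker tables
plus a markdown report.

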