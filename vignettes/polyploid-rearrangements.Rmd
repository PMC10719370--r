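---
title: "Detecting chromosomal rearrangements and subgenome dynamics in an allotetraploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal rearrangements and subgenome dynamics in an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrearrange)
```

## The problem

An allotetraploid genome carries two subgenomes (A and B) descended from two
diploid progenitors. After polyploidization the two subgenomes diverge:
chromosome arms exchange (reciprocal translocations), large pericentromeric
segments invert, blocks of genes duplicate, transposable-element (TE)
families expand asymmetrically, and one subgenome fractionates faster than
the other. None of these events are visible in a single alignment; they
emerge from the joint analysis of gene order (synteny), read-mapping
signatures, repeat annotations, and genetic maps. `polyrearrange` implements
that joint analysis as a set of composable operations over standard formats
(GFF3, BLAST tabular, SAM, FASTA, TSV), plus a seeded synthetic
allotetraploid with planted events so every rule can be validated against
known truth.

## Collinear blocks

The unit of synteny is the *anchor*: a pair of homologous genes, one on each
chromosome being compared, read from 12-column BLAST tabular output and
filtered at an e-value threshold (default `1e-10`). Genes are reduced to
their *rank* — the 0-based ordinal position along their chromosome — and
anchors are chained in rank space by dynamic programming. A chain may extend
from one anchor to the next only if both rank gaps are at most
`max_gap_genes` (default 25, the common default of collinearity chaining
tools); forward and inverted orientations are chained separately; and a
chain only becomes a block if it contains at least `match_size` anchors
(default 8, the usual minimum number of gene pairs required to define a
collinearity block). Chain score is the sum of anchor bit scores minus one
per skipped gene rank; no scoring scheme is standardized for this step, so
we chose the simplest monotone one. Blocks are extracted greedily —
best-scoring chain first, ties broken by leftmost query coordinate — so each
anchor belongs to at most one block.

Before chaining, `dedupe_anchors()` keeps at most `top_n = 5` subject
partners per query (mirroring the usual alignment-report limits) and
collapses tandem arrays (consecutive ranks hitting one partner gene) to
their best-scoring representative, which otherwise inflate block counts.

The chaining implementation is verified against an independent brute-force
oracle that exhaustively enumerates maximal monotone chains under the same
gap rule and replays the same greedy extraction; on 200 random instances of
up to 20 anchors the two agree exactly. The oracle's test instances draw
anchor scores in [50, 100] so that every chain extension has positive net
score (the largest possible gap penalty is `2 * max_gap_genes = 48`), which
guarantees the optimum chain is maximal and the enumeration exhaustive;
continuous scores make ties a measure-zero event.

## Rearrangement calls

Three rules operate on the block table for the within-tetraploid
(subgenome A vs subgenome B) comparison, with homoeologs paired by naming
convention (`Cq3A`/`Cq3B`), not inferred:

* **Inversions** (`detect_inversions`): maximal runs of inverted-orientation
  blocks between homoeologs. The event stores the run's span on *both*
  homoeologs, because self-synteny alone cannot tell which chromosome
  physically inverted; read evidence (below) resolves that.
* **Translocations** (`detect_translocations`): a region collinear with a
  *non*-homoeologous chromosome of the other subgenome whose own
  diploid-relative synteny is absent in that region (coverage of the region
  by blocks against the same-index diploid chromosome at most
  `max_diploid_cover = 0.2`). The donor is the homoeolog of the matched
  chromosome; when both exchanged regions of one chromosome pair are found,
  the calls merge into one reciprocal translocation. A missing diploid
  comparison yields a call flagged `diploid-unconfirmed` rather than
  silence.
* **Segmental duplications** (`detect_segmental_duplications`): a region
  whose anchors participate in two blocks is mapped through each block's
  anchors to the partner side; if the two partner images are disjoint, they
  are the duplicate copies (intra- or inter-chromosomal by their
  chromosomes). Each block must contribute at least `min_dup_genes = 8`
  anchors inside the shared region.

Event endpoints are the outer gene boundaries of the flanking anchors, so
planted events are recovered to within one gene interval. Accounting
(`rearrangement_totals`) merges overlapping event intervals per subgenome
before summing base pairs — overlapping calls are never double-counted — and
an event is flagged `major` when longer than 1 Mb *and* containing more than
100 genes. A fourth, independent signal (`detect_mapping_swaps`) scans
windowed diploid read-mapping rate tracks for the signature of a
homoeologous exchange: windows where the expected diploid relative maps at
no more than half its chromosome-wide mean while the alternative relative
reaches at least half of its own.

## Inversion genotyping from read pairs

For a large inversion whose breakpoints are known, and a reference that
*carries* the inversion, a resequenced accession that lacks it produces
discordant read pairs with one mate near each breakpoint and an implied
insert (recomputed from mate coordinates as the outer span, never trusted
from TLEN) close to the inversion span. `breakpoint_pair()` bundles the two
positions, counting windows of ±500 bp, and an insert gate that defaults to
span ± 1,500 bp so it scales with the event. The genotype rule
(`genotype_inversion`) is:

* **absent** — at least one insert-gated discordant pair joins the windows;
* **present** — no discordant pairs and at least one read spanning each
  breakpoint (strict containment, at least one aligned base on each side);
* **inconclusive** — no discordant pairs but a breakpoint without spanning
  reads;
* accessions under `min_genome_coverage = 5` fold-coverage are excluded.

The mapping-quality filter is pairwise: both mates must reach `min_mapq`
(default 20). We interpret per-read `-q`-style filtering this way because a
single low-quality mate invalidates the pair as inversion evidence; whether
pairs with one low-quality mate should survive is genuinely ambiguous, and
the threshold is a parameter.

`locate_breakpoints()` refines breakpoint positions inside candidate
regions (from synteny or map breaks) by maximizing the product of the
coverage-interruption depth (the region's maximum coverage minus the
coverage at the position) and the local cluster size of discordant mates
(within 1 kb). With end-to-end alignment the true breakpoint is the
coverage *minimum*, flanked by ramps about one read length wide; scoring
the interruption depth rather than a single-base coverage step localizes
the breakpoint to a few bases on the synthetic panels instead of drifting
across the ramp.

## Repeat dynamics

`summarize_repeats()` aggregates repeat copies per family and partition
(subgenome A, subgenome B, whole genome). Copy number counts annotated
elements; base pairs are summed after merging overlapping same-family
copies (union), a policy chosen to prevent double-counting nested or
fragmented annotations — the raw-sum policy is available as an option.
Because the merge is applied per chromosome, the subgenome partitions sum
exactly to the whole-genome totals, which the tests assert.

`ltr_family_enrichment()` classifies each LTR family (Gypsy, Copia,
TRIM/LARD superfamilies) by the log2 ratio of B to A copy numbers: at least
two-fold difference (|log2fc| ≥ 1, boundary inclusive) is enriched; a zero
count on one side is subgenome-specific; a family is *highly repeated* when
its whole-genome copy number exceeds the mean per-family LTR copy number of
the input (the published mean of 698 copies is data-specific, so the
threshold is recomputed unless overridden). The classification is exactly
antisymmetric under relabeling the subgenomes, a property the tests check.
`te_space_attribution()` expresses the absolute TE base-pair difference
between subgenomes as a percentage of their assembly size difference, with
per-superfamily contributions; `dynamics_vs_diploid()` reports
per-superfamily copy and bp deltas against the progenitor, labeling
expansions and contractions and the fraction of total absolute change due
to reduction. `window_density()` produces 1-Mb-window feature-count tracks
(a feature belongs to the window containing its start; the last partial
window is kept).

## Genetic-vs-physical map concordance

`place_markers()` locates linkage-map markers on an assembly by exact
search of their flank sequences (by convention 250 bp on each side of the
marker) on both strands, keeping only a unique best hit; ties leave the
marker unplaced as ambiguous. For assemblies too large for in-memory exact
search, `place_markers_blast()` applies the same single-top-hit rule to a
precomputed tabular search. `detect_map_breaks()` then sorts each
chromosome's markers by physical position, flips the genetic axis if the
global Spearman correlation is negative (a whole-chromosome orientation
flip is not a rearrangement), slides a window of 5 markers computing the
rank correlation of cM versus bp, and reports a break wherever the windowed
correlation changes sign, the break interval being the physical span of the
markers driving the transition. Consecutive flips within two windows are
collapsed to one break: a single transition zone can flip the windowed sign
more than once, while the two genuine boundaries of an inverted run of at
least `match_size` markers always sit further apart. No formal break
criterion is standard for this comparison (such breaks are usually read off
dot plots); the windowed sign-change rule is this package's
operationalization, and both the window and the minimum marker count are
parameters.

## The synthetic allotetraploid

`simulate_genomes()` builds two diploid gene orders (3 chromosomes × 200
genes each by default), copies them into the tetraploid subgenomes, and
applies the planted events: a 40-gene reciprocal terminal translocation
between Cq1B and Cq2B, a 52-gene pericentromeric inversion on Cq3B, and a
12-gene tandem segmental duplication on Cq2B. Gene positions follow a
softened arcsine layout giving ~1.7× higher gene density at chromosome ends
than the middle (gene density rising toward the telomeres), with 2 kb of
sequence per gene (1 kb gene + spacing); TE copies are placed with a
Beta(2, 2) centromere-proximal bias. Homology is emitted directly as
BLAST-tabular anchor tables joining genes of shared ancestral identity —
the pipeline consumes alignments, so sequence-level homology search is out
of scope. Six TE families (two Gypsy, two Copia, one TRIM/LARD, one SINE)
carry planted copy-number biases spanning every enrichment class.

`simulate_panel_alignments()` models a resequencing panel around the
inversion: the reference carries it, carrier accessions emit concordant
pairs, and non-carriers are modeled by re-inverting the segment and
re-projecting mate coordinates, so fragments straddling a breakpoint become
discordant pairs joining the two breakpoint regions while reads crossing a
breakpoint itself are dropped (end-to-end alignment would not place them).
Insert sizes are Normal(400, 40) at 100 bp read length — free parameters,
since no library geometry is prescribed for this analysis — and depth per
accession is configurable (10× for the validation panel; 0.1× accessions
fall below the coverage filter and are excluded, as intended).

`simulate_diploid_readmap()` emits the windowed mapping-rate tracks for the
translocation scan: baseline 0.9 for the expected diploid and 0.1 for the
alternative, with the planted exchange dropping the expected rate to 0.4×
baseline and raising the alternative to 0.8. The 0.4 factor is chosen so
that the planted drop sits below the half-of-chromosome-mean detection
threshold even though the depressed region itself lowers that mean; with
per-window Gaussian noise of sd 0.05 the planted region is recovered in
well over 95% of replicates.

All outputs derive from one global seed through per-component substreams,
so each file is reproducible independently of generation order, and two
runs under one seed are byte-identical (asserted in the tests, including
the end-to-end pipeline report).

What the generator does *not* emulate: sequencing errors and base
qualities, split-read alignment (soft clips), paralogy noise in the anchor
tables, assembly gaps, segregating minor rearrangements within the panel,
and TE nesting. Passing the planted-truth suites therefore demonstrates the
correctness of the decision rules and their coordinate arithmetic, not
robustness to alignment noise in real resequencing data — on real inputs
the thresholds (`match_size`, gap sizes, the insert gate, coverage filters)
do that work and are all exposed as parameters.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at file boundaries (GFF3 and SAM are 1-based on disk). Round-trips
  are asserted byte-exact.
* Insert size is always recomputed from mate coordinates (outer span);
  TLEN conventions vary by aligner and are never trusted.
* Ties in chaining are broken by leftmost query start, then subject start;
  block and event tables are sorted deterministically before IDs are
  assigned.
* The two published coordinates for the right inversion breakpoint differ
  between sections of the source study (63,361,214 in the results and the
  inversion's name, 63,361,684 in the methods); the package defaults to
  63,361,214 and treats the discrepancy as an input choice, not something
  to resolve.
* Degenerate inputs: empty annotation tables, empty block sets, zero
  totals, and chromosomes with too few markers all return typed empty
  results or `NA` percentages (never `NaN`), with warnings where the spec
  of the operation calls for them.
* Problem sizes in the test-suite were chosen to keep the full suite under
  a minute on one CPU: 3 × 200-gene chromosomes, a 20-accession panel at
  10× over a 200 kb chromosome, 100-instance/100-seed property loops.
  These sizes are stated here as the package's validation conditions; all
  detectors run unchanged on genome-scale inputs, where chaining (the
  heaviest step) is quadratic per chromosome pair in anchor count.

## Known limitations

* Translocation scope attribution relies on the chromosome naming
  convention; genomes without `<index><A|B>`-style names need an explicit
  map.
* `detect_inversions` reports the homoeologous pair of intervals; assigning
  the event to one chromosome requires the read-evidence module or an
  outgroup.
* The segmental-duplication rule sees only duplications large enough to
  chain (`min_dup_genes` anchors) and with both copies anchored to the same
  partner region; dispersed single-gene duplications are invisible by
  design.
* `place_markers()` is exact-match only; real flanks with variants should
  go through the BLAST-import path.
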