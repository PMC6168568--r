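---
title: "Methods: synteny, scaffolding and rearrangement analysis in syntenica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny, scaffolding and rearrangement analysis in syntenica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenica)
```

`syntenica` turns a draft assembly and precomputed protein similarity hit
tables into assembled chromosomes and quantitative rearrangement
statistics. This vignette explains the models behind each stage, the
parameters that matter, what the built-in simulator does and does not
emulate, and the numerical choices that keep everything deterministic.

## Coordinates and containers

All internal coordinates are 0-based half-open `[start, end)`; GFF3's
1-based closed intervals are converted at the I/O boundary and nowhere
else. A `genome` is a pair of tibbles (contigs, genes) with an optional
sequence set; marker classes (`subtelomeric`, `pericentromeric`,
`rdna5S`, `rdna_large`, `trna`) come from a curated sidecar table rather
than free-text GFF attributes, because such classes are curated lists in
practice. A gene's strand on a flipped contig is recomputed on the fly,
never stored twice. Analysis ids are opaque strings; the package never
interprets annotation-database naming schemes.

## Orthology

A pair (a, b) is an orthologue candidate when b is a's unique best hit
and a is b's unique best hit, both under `evalue_max` (default `1e-3`,
the conventional protein-search ceiling). Best hits rank by bitscore
(descending), then E-value (ascending), then subject id; a gene whose top
two hits tie on all three is ambiguous and forms no pair — determinism
here mirrors the field's practice of excluding ambiguous repeats.
`drop_multicopy()` removes genes participating in more than one candidate
pair and every pair touching a dispersed-repeat class (5S rDNA, tRNA).
`filter_by_synteny()` then keeps a pair only if at least `min_neighbors`
(default 1) other pairs lie within `window_genes` (default 5) gene
positions on *both* genomes with consistent relative order. The window
defaults are deliberately permissive: they are validated by
planted-truth recovery (precision 1.0, recall ≥ 0.95 on simulated noisy
tables) and exposed in `analysis_config()`.

## Synteny blocks

Anchors chain into signed locally collinear blocks per contig pair and
orientation by sparse dynamic programming maximising anchor count.
Consecutive anchors must be ≤ `max_anchor_gap_bp` apart (default
30,000 bp — large enough to bridge intergenic gaps and occasional missed
anchors, small enough not to step over whole conserved blocks) and
strictly collinear; chains below `min_block_anchors` (default 3) are
noise and discarded. `min_block_anchors` is this package's counterpart of
an alignment-weight threshold: alignment-tool weight units do not port
across implementations, so the anchor count is the unit here. Greedy
extraction from heaviest chain down, with residual span overlaps resolved
by keeping the heavier block and trimming the lighter at the overlap
midpoint, makes blocks tile without overlap; any consistent maximal-chain
rule would do, and the choice is recorded here.

`classify_blocks()` marks *gross* blocks: strictly longer than
`gross_min_block_bp` (20,000 bp) and not within `subtelomere_margin_bp`
(default 50,000 bp — the scale of subtelomeric gene clusters in small
fungal genomes; the literature does not quantify "subtelomeric region")
of a subtelomeric contig end. Gross blocks drive the large-rearrangement
counts because chromosome ends churn structurally and small blocks are
enriched for alignment artefacts.

## Scaffolding

Contig ends are labelled by the marker genes within `margin_bp` (50,000
bp) of them; pericentromeric markers anywhere on a contig set a
contig-level centromere flag. On each reference chromosome, two blocks
within `max_reference_gap_bp` (30,000 bp) of each other whose contig-side
spans reach the respective contig ends propose an adjacency between those
ends, with orientation deciding which ends pair; all pairs within the gap
window are scanned, not only consecutive blocks, because blocks from
rearranged segments interleave on the reference axis. Support is the
bridging anchor count summed per reference.

`order_contigs()` searches for a maximum-support path cover with exactly
`n_chromosomes` paths in which every path terminates at subtelomeric
ends, contains a centromeric contig, and uses each contig once. The
search is greedy in descending support with constraint backtracking —
problem sizes are at most dozens of contigs, and this mirrors
evidence-ranked manual reasoning while staying deterministic. When two
references propose different partners for one end, the earlier reference
in `reference_priority` wins (callers should order references by
ascending whole-genome rearrangement distance) and the conflict is
reported. If a second cover of equal support exists the result is
flagged non-unique instead of being silently chosen. Assemblies are
canonical (lexicographically smaller terminal end first), named by
descending assembled length, and exported with 100-N spacers; overlapping
contig end sequences are not merged. `lift_blocks_to_assembly()` rewrites
block coordinates from contig space to assembled-chromosome space so that
fragmentation does not masquerade as rearrangement downstream.

## Rearrangement distance and scenarios

Shared blocks become signed permutations (markers numbered along genome
A; genome B receives the induced signed order). The distance is the exact
double-cut-and-join (DCJ) closed form *d = N − C − I/2* over the
adjacency graph (N markers, C cycles, I odd paths). DCJ was chosen over
the inversion+translocation (HP) model because it has a clean exact
closed form, agrees with HP on the vast majority of instances, and the
analyses here use distances comparatively; the brute-force BFS oracle in
the test suite validates DCJ semantics specifically. Circular
chromosomes are unsupported as inputs (the genomes of interest are
linear).

`sort_scenario()` builds one optimal scenario deterministically: target
adjacencies are fixed in ascending marker order, always by a
distance-reducing operation, preferring operations that keep all
chromosomes linear. Operations are typed inversion / translocation /
fusion / fission. One subtlety is unavoidable: some optimal sortings of
linear genomes (block interchanges, e.g. `(1 3 2) → (1 2 3)`, distance
2) have **no** linear-only scenario at optimal length; the sorter then
emits an `excision` creating a transient circular intermediate and
reabsorbs it with the very next operation (`reintegration`). Histories
made of inversions and translocations with unreused breakpoints sort
without this pair, so planted-history scenarios are typed with the four
standard kinds. Scenario rows carry the created adjacency, so
`replay_scenario()` reproduces the target exactly.

`mcd_summary()` normalises counts per chromosome and per Mb and reports
the gross/all percentage. Ratios round half away from zero to two
decimals and percentages to the nearest integer, matching how such
tables are conventionally printed (base R's `round()` rounds half to
even, so the package implements the rounding explicitly). Per-Mb values
require a genome size the caller must supply; when unknown they stay
`NA`.

## Breakpoints and the random breakage model

Between two genome-adjacent gross blocks whose counterparts are not
adjacent and equally oriented on the other genome lies a breakpoint
region; chromosome ends are excluded, and running both directions gives
the reciprocal consistency check (counts agree when breakpoints are not
reused). Features associate with a region when their span intersects it
extended by `breakpoint_margin_bp` (default 5,000 bp, exposed in config
and reported alongside counts, since "at the block edge" is not a sharp
notion); regions longer than 1,000 bp containing no gene are flagged as
large intergenic.

Under uniform (random) breakage, segment lengths between breakpoints are
exponential, f(x) = 1/L·e^(−x/L) with L the mean segment length.
`random_breakage_test()` turns the classical visual histogram comparison
into a calibrated test: a Kolmogorov–Smirnov statistic against
Exponential(mean L), with the p-value from a parametric bootstrap that
re-estimates L in every replicate (Lilliefors-style), because L is
estimated from the data being tested — the plain KS null would be
anticonservative. Segment lengths fed to the test are the gross-block
lengths per genome. Fewer than five segments is refused as meaningless.
The test's null rejection rate is verified at 0.05 ± 0.02 over 500
simulated seeds (n = 200 segments, 199 bootstrap replicates), its null
p-values are checked for uniformity, and its power against a two-point
mixture (repeat-clustered short segments) exceeds 0.8 at the same n.

## Statistics layer

`pearson_with_p()` reports the product-moment r with the exact two-sided
p from t = r·sqrt(n−2)/sqrt(1−r²) on n−2 df (delegated to `cor.test`;
the t transform is asserted against its closed form in tests).
`compare_length_distributions()` runs Kruskal–Wallis with tie correction
plus pairwise Mann–Whitney U — exact when both groups have ≤ 20
observations and no ties, normal approximation otherwise — reporting
pairwise p-values both raw and Bonferroni-adjusted (both are emitted and
labelled; post-hoc conventions differ between fields). Quartiles use
linear interpolation (type 7), the default of most desktop statistics
software. Normality pre-tests are deliberately out of scope: rank tests
are always reported.

## The simulator

`sim_spec()` defaults define the study conditions everything is tested
under: 3 chromosomes, 500 log-normal blocks (mean 25 kb, sd 20 kb —
about a 12.5 Mb genome), 4 genes per block, a history of 4 inversions
plus 7 translocations (translocations outnumbering inversions, as
between closely related fission yeasts), a draft of 9 contigs, 2
subtelomeric terminal blocks per chromosome end, 1 pericentromeric
central block, 20 dispersed 5S rDNA and 10 tRNA loci, a 10% decoy hit
rate. Cut sites are drawn uniformly over inter-block adjacencies — never
at telomeres, which keeps subtelomeric blocks terminal — or with
`bias_weight`-fold mass on repeat-flanking adjacencies under the
repeat-biased model. Translocation products that would carry zero or two
centromeres are rejected and redrawn: such karyotypes are inviable, and
modelling only viable reciprocal translocations is what makes the
centromere-per-chromosome scaffolding constraint meaningful.

Fragmentation cuts between blocks, shuffles and flips the pieces, and
records the truth. `fragment_genome()` can be told to avoid a set of
adjacencies; the recovery harness passes the adjacencies altered by the
history, because a contig boundary placed exactly at a rearrangement
breakpoint is unbridgeable on the reference *by construction* — no
assembler could recover it from synteny evidence, so including such cuts
would test the evidence, not the algorithm. With that proviso the
full-pipeline recovery property holds exactly: 50/50 seeded simulations
recover the planted order and orientation up to whole-chromosome
reflection.

What the simulator does **not** emulate: nucleotide evolution (hits are
drawn from stylised score distributions, not alignments), gene
duplication and loss beyond the repeat classes, missing or chimeric
annotations, assembly gaps inside blocks, and segmental duplications.
Passing tests therefore demonstrate correctness of the combinatorics and
robustness to score noise and repeat confusion — not robustness to every
artefact of real draft assemblies.

## Problem sizes and runtime

The shipped test and acceptance workloads use: 200 random ≤ 6-marker
instances for the BFS-vs-closed-form check, 40 random ≤ 12-marker
scenarios for replay, 60 seeds at 500 blocks / 20 operations for
planted-distance recovery, 50 seeds of the full scaffold pipeline, and
500 + 100 seeds at 199 bootstrap replicates for breakage-test
calibration and power. These sizes were chosen so the whole suite runs
in minutes on a single core while keeping every rate estimate's
sampling error well inside its acceptance band.

## Known limitations

* DCJ can undercount relative to an inversion+translocation-only model
  on the rare instances where they differ; distances are meant for
  comparative use.
* The scaffolder requires subtelomeric evidence at every chromosome end
  (2·K labelled ends); genomes with eroded subtelomeres need markers
  supplied, or fail with an explicit evidence report.
* Orthologue counts and block counts from real published comparisons
  depend on the original tools' internals and manual curation; this
  package reproduces the printed table arithmetic and the method's
  behaviour on planted truth, not tool-internal numbers.
* Headline counts from the motivating study (e.g. specific breakpoint
  tallies) require the real genomes and their manual curation; they are
  external validations, not test targets.
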