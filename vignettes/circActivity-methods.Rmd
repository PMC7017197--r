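---
title: "Methods and modelling choices in circActivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in circActivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`circActivity` implements a complete desk-scale pipeline for circular RNA
analysis in two-condition experiments: back-splice junction detection and
RPM quantification, differential expression, seed-based miRNA target
prediction, direction-constrained ceRNA network inference with consensus
hub ranking, and ribosome-footprint-based translation screening. This
vignette explains each model, its assumptions and tunable parameters, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Coordinate conventions

Genomic intervals live in 1-based inclusive `GRanges` internally, the
Bioconductor convention that lets interval algebra go through
`GenomicRanges`/`IRanges`. External formats keep their native conventions
and are converted at the boundary: GTF is 1-based inclusive, while the
split-segment alignment table and BED output are 0-based half-open.
Within-sequence positions (seed-site positions, ORF starts, footprint
offsets) are 0-based, as is usual for string indices in sequence analysis.

## Back-splice detection

A read supports a back-splice junction when its two aligned segments share
chromosome and strand and occur in *reversed* genomic order: the segment
that comes first in the read maps at or beyond the end of the second. The
junction spans from the upstream segment's leftmost to the downstream
segment's rightmost coordinate. Candidates sharing coordinates merge, and
only junctions with **`minSupport = 2`** or more reads survive — the
"more than one read" confidence rule. Reads with more than two segments
are skipped with a warning rather than guessed at; antisense calls
(segments on opposite strands) are out of scope.

Detected junctions are snapped to annotated exon boundaries within
**`tolerance = 2`** nt (absorbing aligner soft-clip jitter without
merging distinct junctions); when several transcripts match, the one
covering the junction with the most exons wins, then the lexicographically
smallest id, so output is deterministic. Junctions that fail snapping are
retained and classified (intronic if inside one intron, intergenic
otherwise) so that origin tallies cover everything. Exonic junctions are
refined to coding-exon / 5'UTR / 3'UTR by which regions the included exons
overlap, priority coding-exon > 5'UTR > 3'UTR; exon ordinals count from
the transcript 5' end, so minus-strand genes count from the right.

Abundance is RPM: `1e6 * support / totalMapped` per sample. RPM is
invariant under duplicating every read and doubling totals, which the
tests assert on random matrices.

## Differential expression

Counts are pooled within groups and tested with the exact conditional
binomial test: conditional on a feature's total `a + b`, `a` is
`Binomial(a + b, N_A / (N_A + N_B))` under the null, with `N_A`, `N_B`
the summed library sizes. Two-sided p-values use the minimum-likelihood
rule (as `binom.test` does). Fold changes carry a 0.5 pseudocount so
zero counts stay finite. BH controls the FDR across features.

**Assumption and stated limitation.** Conditioning on totals is exact
under Poisson sampling (technical replication) but deliberately ignores
biological overdispersion. On simulated negative-binomial nulls with
dispersion 0.1 (variance `m + 0.1 m²`) at mean 100 and 3 vs 3 samples,
the test rejects ~56% of features at p < 0.05 — it is *not* calibrated
for biologically replicated counts, and the test suite records that
measurement honestly. Under Poisson nulls the realized rejection rate is
~4–5%, which the suite also asserts. Users with strong biological
variability should treat the p-values as enrichment scores, or supply a
dispersion-aware test; the surrounding machinery (thresholds, FDR,
direction labels) is agnostic to the test used. Power is nonetheless
high where it matters for the bundled fixtures: planted 4-fold changes
at mean 100 are recovered at >95% under the circRNA profile.

Class-specific thresholds mirror the study design: circRNA calls use raw
p < 0.05 with fold change ≥ 2 (few replicates, low counts — FDR on
thousands of circRNAs would be hopeless at this depth); miRNA and mRNA
use FDR < 0.05 with fold changes 1.5 and 2. `deProfile()` returns these
profiles; everything is overridable.

For circRNA DE the library sizes are the *total mapped reads* per sample
(the RPM denominator), not junction-count column sums: junction counts
are a tiny, effect-driven fraction of a library, and normalizing by their
column sums would absorb genuine global shifts into the denominator.

Spearman association (`spearmanAssoc`) uses midranks, an exact
permutation null for n ≤ 8 (complete enumeration) and the t
approximation above that; constant vectors are flagged rather than
silently returning a correlation.

## miRNA target prediction

Canonical site types are defined against the miRNA seed (positions 2–8):
a target match to the reverse complement of positions 2–7 is the core;
position-8 complementarity and/or an A opposite position 1 upgrade it to
7mer-m8, 7mer-A1 or 8mer. Only the strongest type is reported per locus.
Reported positions are the 0-based start of the core match.

The efficacy score is a deliberate simplification of context-style
scoring: `score = base(type) + auWeight * (1 − AU)` with defaults
`base = {8mer −0.31, 7mer-m8 −0.16, 7mer-A1 −0.10, 6mer −0.03}` and
`auWeight = 0.10`. The AU fraction is measured over up to 15 nt flanking
each side of the site span, excluding the site itself (the site core has
fixed composition, so including it would compress the score range; local
AU content outside the site is the classical accessibility proxy). Sites
are retained when `score < −0.2`. Under the defaults an 8mer always
passes unless its context is strongly GC-rich, and a 6mer never does —
the score is used only as a binary cutoff, so the weights matter less
than their ordering; all are configurable for recalibration.

circRNA target sequences are the concatenated exonic sequence scanned
*circularly* (extended by the first 7 nt), so junction-spanning sites are
found once and flagged. mRNA targets are full transcript sequences by
default; restricting to 3'UTRs is a matter of passing those sequences.

## ceRNA network and hub ranking

Edges require both endpoints differentially expressed and a predicted
interaction. The direction rules are asymmetric on purpose: miR–mRNA
edges must join opposite directions (repression leaves an inverse
footprint), while circ–miR edges ignore direction (sponging need not
change miRNA steady-state levels). The merged graph keeps miRNAs with
edges on one side only (`linkersOnly = TRUE` drops them); the class
validity machinery re-asserts the structural rules on every object.

Eleven centralities are computed on the full unweighted, undirected
tripartite graph; ranking is restricted to circRNA nodes afterwards.
Distance-based scores are computed within components, and Closeness is
harmonic (`sum of 1/d`) so disconnected pairs contribute zero —
tripartite unions are rarely connected. Parameter choices where the
methods have free knobs: DMNC exponent 1.7; BottleNeck counts, for each
source's deterministic BFS shortest-path tree (parent = smallest-index
neighbor), the trees in which a node's subtree exceeds a quarter of the
tree; EPC averages, over `R = 1000` seeded edge-percolation replicates at
retention 0.5, the size of the component containing each node (the
end-to-end pipeline uses `R = 200` to keep the bundled run fast — EPC
converges well before that for graphs of this size, and the convergence
test asserts <2% drift between independent replicate sets). Ranks break
ties lexicographically by node id, so every ranking is a deterministic
permutation.

Consensus hubs are the `nHubs = 15` restricted-kind nodes appearing most
often in the per-method top-`kTop = 20`, ties broken by mean rank, then
id. The hub subnetwork is the two-hop induced construction: hubs, their
miRNAs, and those miRNAs' mRNAs.

## Translation screening

The junction index stores, per circle, the 36-nt window of the doubled
sequence centered on the wrap point (18 nt per side); shorter circles
wrap cyclically and are flagged, and identical 36-mers deduplicate with a
cross-reference. Footprints are length-filtered to 25–40 nt, then matched
by exhaustive anchored Hamming comparison against the entry extended with
circle sequence (reads longer than 36 nt overhang into the body): a hit
needs ≥ `minAnchor = 6` nt on each side of the wrap and ≤
`maxMismatch = 2` mismatches, keeping the best placement (fewest
mismatches, then largest left anchor). An explicit matcher was chosen
over an external aligner so the mapping contract is exactly testable
against a brute-force oracle; pre-filtering reads that align to the
linear genome is the caller's concern, modelled as an exclusion list.

Rolling-circle ORFs scan the three forward frames of the 4×-concatenated
sequence (circles are single-stranded; the antisense frames are not
biological here) for ATG-initiated ORFs starting in the first copy. An
ORF crossing a multiple of the circle length is junction-crossing. When
the circle length is divisible by 3, a frame can return to its own phase
without meeting a stop: such ORFs are flagged *stopless* and truncated at
one full turn (L/3 codons) — the translation would be processive. With L
not divisible by 3 each wrap shifts frame, all three frames are visited,
and stoplessness is impossible; an ORF that still runs off the fourth
copy is reported truncated with a warning. Start codons are ATG only —
a conservative default; near-cognate starts are not scanned. The coding call is a heuristic — ≥ 20 aa and
junction-crossing — not a trained coding-potential model; calls are
useful comparatively (which circles could code) and are not absolute.

Region annotation intersects each junction's genomic span with 5'UTR,
CDS and 3'UTR intervals, labelling by maximal overlap with ties broken
5'UTR > CDS > 3'UTR (the 5'UTR enrichment signal is the biologically
interesting one, so ties should not silently default to CDS).
Compositions are compared by Pearson chi-square without continuity
correction; group abundance by exact Mann–Whitney on per-sample
junction-reads-per-million.

## The synthetic-data generator

`simulateStudy()` emulates the *structure* of a depolarization
experiment: a toy genome (default 40 genes, 3–6 exons of 120–300 nt,
random strands) with CDS and UTRs; planted whole-exon circRNAs over
3 + 3 replicates whose junction-read support is negative binomial
(variance `m + d·m²`, mean 20, dispersion 0.05) with 4-fold planted
effects on half the circles; miRNA and mRNA count matrices over 4 + 4
replicates with planted ±4-fold (miRNA) and ±4-fold (mRNA) effects;
22-nt miRNAs whose 8mer sites are planted into circle and mRNA sequences
so that three designated circles are wired as high-connectivity sponges;
and ribosome footprints with a controlled junction-crossing fraction.
Linear read depth (1000/sample) dwarfs junction reads, as in real
libraries, so library sizes are dominated by the linear background. All
randomness derives from one master seed; identical seeds give
byte-identical outputs, which the manifest test asserts.

What it does **not** emulate: sequencing error profiles and quality
scores, paired ends, realistic depth (real libraries run tens of millions
of reads; these run thousands — problem sizes were chosen so the whole
suite and the end-to-end run complete in minutes on one CPU), isoform
complexity (one transcript per gene), RNase R enrichment, and
conservation signal in target sites. Passing tests therefore demonstrate
algorithmic correctness on data whose generative process is known — they
do not certify performance on real libraries, where alignment artifacts
and overdispersion dominate.

## Degenerate inputs and tie-breaking, collected

* All-zero features test as (log2fc 0, p 1); zero totals are refused by
  sample name.
* Empty junction tables, empty networks, empty hub sets and empty ORF
  tables all propagate as empty objects, not errors.
* Fully tied abundance vectors report p = 1; one-sample groups warn.
* Junction snapping, hub selection, footprint placement and centrality
  ranks all break ties deterministically (documented per function), so
  identical inputs always give identical outputs.

## Known limitations

The DE test's overdispersion blindness (above) is the main one. Target
prediction ignores thermodynamics, conservation and non-canonical sites.
Centrality definitions follow the common plugin formulations; where those
leave parameters open the defaults above were fixed once and exposed.
Coding calls are length heuristics. The segment-table ingestion assumes
an upstream chimeric aligner has already resolved split alignments.
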