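---
title: "Degradome-guided miRNA-target analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradome-guided miRNA-target analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretarget)
```

## The analysis in one paragraph

Plant miRNAs regulate their targets mainly by guide-directed endonucleolytic
cleavage: the RISC complex slices the mRNA between the nucleotides paired
with miRNA positions 10 and 11, leaving an uncapped 5'-monophosphate
fragment. Degradome (PARE) sequencing captures the 5' ends of exactly such
fragments, so a pile of degradome tags whose 5' ends sit opposite miRNA
nucleotide 10 of a predicted complementary site is direct physical evidence
that the site is sliced in vivo. `paretarget` implements the full chain of
that argument: complementarity-based candidate sites, degradome evidence at
the expected slice position, per-condition differential expression of both
the miRNA and the mRNA layer, and the final join that keeps only
degradome-validated pairs in which both members are differentially
expressed — flagging the *reversed* pairs (miRNA up, target down or vice
versa) that behave as repression predicts. The package is aimed at
non-model plant studies built on a de novo transcriptome (unigenes as gene
proxies), a mature miRNA catalog, one pooled degradome library, and small
replicated count matrices — a 4-condition x 2-replicate drought design
(control and stressed leaf and root: `CK_L`, `D18d_L`, `CK_R`, `D18d_R`)
is the built-in template.

## Duplex scoring

Candidate sites are scored with the plant-specific position-weighted
penalty scheme used by the classic plant target predictors: each duplex
column contributes

* 0 for a Watson-Crick pair,
* 0.5 for a G:U wobble,
* 1 for a mismatch,
* 1 per bulged (unpaired) nucleotide,

and every contribution is doubled when it falls inside miRNA positions
2-13 (counted from the miRNA 5' end), the region where pairing is
functionally critical for slicing. A perfect complement scores 0; the
default reporting cutoff is 4, and all penalties are configurable through
`duplex_weights()`. At most one single-nucleotide bulge per duplex is
considered (either side); this keeps the register space exhaustively
enumerable and matches common plant-miRNA practice, where multi-bulge
sites are rarely functional. Two conventions had to be fixed where the
scheme itself is silent:

* a bulged *target* nucleotide sits between miRNA positions *g* and
  *g + 1* and is charged at position *g + 1*; a bulged *miRNA* nucleotide
  is charged at its own position;
* overlapping hits of one miRNA on one transcript are collapsed keeping
  the lowest score, ties broken by the smaller start coordinate and then
  by the register closest to ungapped, so output is deterministic.

`scan_transcript()` evaluates every window of width L-1, L and L+1 via a
vectorized penalty-matrix formulation (cumulative sums over alignment
registers), which makes the all-vs-all `predict_targets()` feasible in
plain R; the test suite checks it against a brute-force window-by-window
enumeration oracle.

The expected cleavage position of each hit (`cleavage_expect`) is the
transcript coordinate paired with miRNA nucleotide 10. For a 21-nt miRNA
whose site occupies transcript positions 101-121 that is position 112.

## Degradome mapping and the five-category key

Tags are matched to transcripts by exact, full-length, sense-strand string
matching only — one mismatch disqualifies an alignment. A multi-mapping
tag contributes its full read count at every matching locus; no fractional
allocation is attempted, because the category logic below is defined on
raw read counts at a position, not on allocated fractions. Mapping
statistics keep the two views apart: `mapped_reads` counts each read once
(this is the number behind a library-level "mapping ratio"), while
`assigned_reads` sums all per-locus contributions.

Each occupied position is classified by the standard t-plot abundance
key, applied in this order:

| category | rule at the position |
|---|---|
| 4 | exactly one raw read |
| 0 | >1 read, equal to a transcript maximum attained at exactly one position |
| 1 | >1 read, equal to a maximum attained at two or more positions |
| 2 | >1 read, above the transcript median but below the maximum |
| 3 | >1 read, no more than the median |

Two points deserve comment. First, the singleton rule is checked first, so
a transcript whose only signal is a single read is category 4 even though
that read is also the transcript maximum. Second, the key does not say
whether the "median for the transcript" includes unoccupied (zero-depth)
positions. `paretarget` defaults to the median over occupied positions
only: with the all-position convention the median is almost surely zero on
any long transcript, which makes every sub-maximal occupied position
"above the median" and empties category 3 of meaning. The all-position
convention remains available (`median_include_zeros = TRUE`) for
sensitivity analyses.

Validation (`validate_cleavage()`) inspects `cleavage_expect` plus/minus a
window (default 1 nt, settable to 0 for the strictest reading) and returns
the in-window position with the highest abundance, ties resolved by
smaller offset magnitude and then smaller coordinate.

## Expression layer

Transcript counts are normalized to RPKM; miRNA counts use common-set
scaling, where each library is rescaled by the summed counts of the
miRNAs detected in *every* sample — a scheme robust to condition-specific
high-abundance miRNAs, with total-count scaling available as a fallback
when the common set is empty.

With two replicates per condition there is no usable within-group
variance, so replicate counts are pooled and each feature is tested with
the two-sided exact test on the 2x2 table of (feature reads, remaining
library reads) in the two conditions; Pearson chi-squared (no continuity
correction) is available as the large-count alternative. Fold changes are
computed from mean normalized expression with a pseudocount of 1 on the
normalized scale. Default calls follow the field's conventions: genes at
p < 0.05 **and** |log2FC| >= 1; miRNAs at p < 0.05 with no fold-change
gate. Raw p-values are the default (as is conventional for these designs);
a Benjamini-Hochberg option exists but is off by default.

A known, deliberate limitation: pooled exact tests ignore biological
replicate variability, so under strong overdispersion their p-values are
anticonservative. The gene-layer fold-change gate absorbs most of this in
practice, and the miRNA layer inherits the convention of the designs this
package emulates; users wanting dispersion-modelled inference should treat
the DE layer as exchangeable and feed ranked candidates to a
negative-binomial engine. The package's own calibration check therefore
uses an equal-proportion multinomial null, where the exact test is
conditionally valid, and verifies <= 6% of null features at p < 0.05.

## Integration

`join_pairs()` keeps a (miRNA, gene) pair for a comparison iff the miRNA
is significant, the gene is significant, and the pair carries a
degradome-validated site. A pair validated at several sites collapses to
one record with the best (lowest) category, ties resolved by highest
abundance — the output table is one row per pair, mirroring the shape of
published correlation tables (comparison, miRNA, its regulation, target,
annotation, its regulation). "Up" always means the first-named condition
relative to the second. `flag_reversed()` partitions pairs by direction
agreement; no correlation coefficient is computed — with two replicates
per condition, direction concordance is the only robust statement, and
the package deliberately stops there. GO/KEGG annotations are joined from
a user-supplied table (`attach_annotations()`), never computed:
enrichment testing is out of scope.

## The synthetic experiment generator

Because real libraries of this kind are tens of millions of reads, the
package ships a generator that reproduces the *structure* of such a study
at desk scale with full ground truth:

* `simulate_transcriptome()` / `simulate_mirnas()` — i.i.d. sequences at
  fixed GC, transcript lengths 400-900 nt, miRNAs 20-24 nt;
* `plant_sites()` — inserts exact reverse-complement sites (by
  substitution, lengths unchanged), optional point mutations placed
  outside miRNA positions 9-11 so the slicing register survives;
* `simulate_degradome()` — signal tags whose 5' ends sit exactly at each
  planted cleavage position, plus uniform background tags (each one
  read). No decay-gradient background is modelled: uniform noise is
  sufficient to exercise the category logic, and the studies emulated
  publish no background model to copy;
* `simulate_counts()` — log-normal baseline abundances, negative-binomial
  counts (variance mu + dispersion x mu^2) with planted per-condition
  multipliers; a multinomial mode draws fixed-depth libraries at exactly
  equal proportions for calibration nulls.

Ground truth is *derived, not assumed*: expression is measured on the
relative scale (RPKM, common-set scaling, exact tests on proportions), so
an effect planted on one feature's absolute mean also shifts every other
feature's proportion. The generator therefore (a) keeps planted features
at a modest pinned baseline weight so that compositional drift in null
features stays far below the significance gates, and (b) derives the
planted DE table and planted pair set from the true per-condition
*proportion* matrices, including effect "leakage" into every comparison
that shares the perturbed condition (a gene 8-fold up in drought-treated
root versus control root is necessarily also ~8-fold up against
drought-treated leaf). A planted pair is expected in each comparison where
the miRNA's true proportions differ and the gene's true |log2 ratio|
clears the gene gate.

Three presets fix the study conditions:

| preset | effects | depth/sample | dispersion | degradome | site mutations |
|---|---|---|---|---|---|
| `baseline` | 8-fold | 1e5 | 0.01 | 50 reads/site, no noise | 0 |
| `noisy` | 4-fold | 1e4 | 0.1 | 20 reads/site, 10:1 signal:noise | 1 |
| `null` | none | 1e5 | 0.1 | background only | — |

All presets use 80 transcripts, 16 planted miRNA-target pairs (four per
condition contrast, three of each four reversed) and 24 unplanted miRNAs.
These sizes keep a full closed-loop run around ten seconds while leaving
enough null features for composition and false-positive behaviour to be
observable. Every generator is a pure function of its arguments and seed
(the RNG state is saved and restored around each call), which is what
makes byte-identical re-runs of whole pipeline stages testable.

Under `baseline` the pipeline is expected to recover the planted pair set
*exactly*; under `noisy` the binding constraint is the gene-layer
fold-change gate — a 4-fold effect on a feature with roughly 45
reads/sample at dispersion 0.1 has about 90% probability of showing
|log2FC| >= 1 in a 2-replicate pooled comparison — so pooled precision
and recall over replicate simulations sit a little above 0.9 rather than
near 1. That is a property of the study conditions (depth, replication,
thresholds), not of the implementation, and the acceptance suite asserts
it at exactly those conditions.

## What the synthetic data does and does not establish

Passing the closed loop shows that the implementation's stages compose
correctly and invert the generator's known ground truth under realistic
noise. It does not certify performance on real libraries, where the
generator's idealizations fail in known ways: real degradome backgrounds
follow decay gradients rather than uniform noise; real transcriptomes
contain repeated and paralogous sequence, so multi-mapping is common
rather than rare; real miRNA families share near-identical members;
adapter and quality artifacts are absent here by construction; and real
biological replicates are more overdispersed than any single
negative-binomial dispersion constant.

## Numerical and degenerate-input conventions

* All transcript coordinates are 1-based and inclusive on the sense
  strand; tags and sites are reported by their 5'-most coordinate.
* RNA input (U) is normalized to DNA (T) on read; `N` is tolerated in
  transcripts (it never matches anything) and rejected in miRNAs and
  tags, where perfect-match semantics must be unambiguous.
* Reported percentages are rounded half-up to two decimals; full
  precision is kept internally.
* A transcript shorter than the miRNA scans to an empty result, not an
  error; an empty pair list writes a header-only table.
* The exact test uses the conventional relative tolerance (1 + 1e-7) when
  summing tables "no more probable" than the observed one, so
  floating-point ties behave as in the reference implementations.
* Tie-breaks are everywhere deterministic and documented (lowest score,
  then smallest coordinate; highest abundance, then smallest offset, then
  smallest position), so identical inputs yield identical files.
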