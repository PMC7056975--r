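---
title: "Reverse engineering postponed senescence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering postponed senescence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The analysis chain

`pleioscan` implements the computational chain of an evolve-and-resequence
study of postponed reproductive senescence in *Drosophila melanogaster*:
five replicate populations selected for late-age reproduction (O lines,
long-lived) are contrasted with five unselected controls (B lines), and the
genomic footprint of selection is followed down to single-gene functional
tests.

1. **Divergence scan** — find genomic intervals where the allele-frequency
   difference between the selected and control line means, Δp, is at or
   near fixation.
2. **Candidate filter** — keep genes in those intervals (or nominally
   divergent outside them) that are expressed in the reproductive tissues
   under selection and have usable RNAi stocks.
3. **Effect calling** — ANOVA models for the RNAi screen readouts:
   lifespan by sex, lifetime and weekly productivity, and qPCR knockdown
   validation.
4. **Pleiotropy classification** — map each gene's calls onto the
   antagonistic-pleiotropy taxonomy that evolutionary theories of
   senescence predict.

A seeded synthetic-data generator emulates the study design so that every
stage is testable, end to end, without any external download.

## The interval scan

A variant qualifies when `Δp > 0.8` (strictly greater), where
`Δp = |mean(freq_O) − mean(freq_B)|` over replicate lines. Maximal runs of
consecutively indexed qualifying variants form seed intervals; two
neighbouring intervals are merged — together with the interruption between
them — when the interruption contains fewer than three variants, each with
`Δp > 0.5`. Merging is iterated to a fixpoint.

Three choices deserve comment:

* **Adjacency is counted in variants, not base pairs.** The
  fewer-than-three-variants rule is only meaningful on the index scale; a
  bp-based reading would make the interruption rule depend on local variant
  density.
* **Merge order cannot matter.** Whether an interruption qualifies depends
  only on the interruption itself, never on how large its flanking
  intervals have grown, so the merge relation is a fixed graph on seed
  intervals and the fixpoint is its connected components. The test suite
  nevertheless asserts equivalence against a brute-force oracle that merges
  in random order (1000 random tables).
* **Interval span is the distance between the first and last member
  variant.** Single qualifying variants are reported as one-variant,
  zero-span intervals; they underestimate the true swept region when
  variant density is low.
* **Δp is `|mean − mean|`**, not the mean of pairwise line differences;
  with 5-vs-5 replicate lines the two differ, and the mean-of-means form is
  implemented. Allele polarity is irrelevant to `|Δp|`, so the reader
  accepts whichever allele the input reports.

Interruption runs at the ends of an arm are never absorbed: only
interruptions *between* two seed intervals are merged.

The gene–interval assignment rule is closed-interval overlap of at least
1 bp, with an explicit `flank_bp` parameter (default 0) because published
gene-in-interval counts rarely state their flank convention.

## The candidate filter

Selection requires (1) divergence evidence — either interval membership
with a per-variant divergence P-value below `1e-5`, or, for genes outside
any interval, nominal significance below `1e-3`; (2) expression in both
ovary and accessory gland (the tissues the productivity analysis
implicates); (3) an available RNAi stock without off-target effects. The
per-variant P-values are consumed as an input column (they come from a
prior divergence analysis); the package never recomputes them. Expression
and stock availability are input flags rather than live database lookups,
keeping the pipeline download-free; rejections carry audit flags naming
every failed criterion so alternative reconstructions are possible.

## The ANOVA engine

The screen's designs are (near-)balanced factorials with a random
replicate-vial effect nested in genotype. The engine fits them by classical
expected-mean-squares ANOVA rather than REML:

* Sums of squares are partial (Type III-style): each term's SS is the
  residual-SS increase from deleting its sum-to-zero contrast block from
  the full model. On balanced data this reduces to the orthogonal
  sequential decomposition (asserted to 1e-8 relative in the tests).
* The F denominator for each term is the lowest random term whose factor
  set contains the tested term's factors — e.g. genotype is tested against
  vial-within-genotype, and sex and sex×genotype against
  sex×vial-within-genotype — falling back to the residual for purely fixed
  models.
* Nested random blocks are built as within-cell sum-to-zero contrasts, so
  a cell with a single replicate simply contributes no columns.

REML would differ slightly on unbalanced data (e.g. attrition), and
commercial implementations may use different conventions; on the balanced
synthetic designs the two coincide, and the tests pin the engine to the
base-R `aov` error-strata decomposition as an independent oracle.
Tukey–Kramer comparisons use the studentized-range distribution against the
same EMS error stratum; the compact letter display is computed from the
maximal cliques of the non-significance graph, so groups share a letter
exactly when they are not significantly different.

Significance is `P < 0.05` per test with **no multiple-testing
correction** — this mirrors how such screens are read out, and it means
that with six weekly tests per gene roughly one gene in four will pick up a
spurious weekly call under the null. The classifier therefore inherits that
per-test error rate; the tallies the pipeline reports are estimates of the
screen's own behaviour, not corrected discovery counts.

## Effect calls and classification

Per gene, the callers emit one row per trait: `lifespan_F`, `lifespan_M`
(per-sex reduced models `Y = µ + G + Rep(G) + ε`), `lifetime_productivity`
(per-vial sums, one-way model), `weekly_productivity` per week (one-way per
week), and `expression_*` from qPCR (log2 normalized expression,
`2^−(Ct_target − Ct_ref)`, with biological replicate as the random
stratum). "Affected lifespan" means a significant genotype effect in at
least one per-sex reduced model; the full-model sex×genotype P-value is
carried alongside for sensitivity analyses.

Lifetime productivity sums a vial's observed weeks: after all of a vial's
females have died, reproduction has genuinely ended, so missing late weeks
contribute zero to the lifetime sum. The weekly models, in contrast, treat
those cells as missing data and drop weeks where a genotype has no
surviving vials.

Classification defines three antagonism axes: **sex** (significant
lifespan calls of opposite direction in the two sexes),
**early-vs-late reproduction** (significant weekly calls of opposite
direction between the early and late week sets), and
**lifespan-vs-reproduction** (a significant lifespan call opposing a
significant productivity call in fitness sign, where a decrease in either
trait is a cost). Any non-empty axis set makes the gene
`antagonistic_pleiotropy`; no significant call at all is `no_effect`; the
remaining genes are lifespan-only, productivity-only or concordant. The
early/late boundary is a parameter (early = weeks 1–2, late = weeks ≥ 4 by
default) because the underlying vocabulary has no canonical cutoff; weeks
in neither set still feed the lifespan-vs-reproduction axis but never the
early/late axis. When a gene's weekly calls mix directions without
spanning the early/late boundary, the week-level pattern reports the cost
(`some_week_down`) in preference to the benefit.

## What the generator emulates — and what it does not

The generator reproduces the study's *structure* and uses its stated design
constants throughout: 5-vs-5 replicate lines; 48 lifespan vials per
genotype with 3 flies of each sex sharing a vial effect; weekly
productivity for 13 of those vials, ending when a vial's females have died;
15 vials per cross and four weekly lays in the reciprocal O/B assay; qPCR
with 2 biological × 3 technical replicates against a constant housekeeping
gene; the screen split into 6 blocks with construct-matched controls per
block.

Genome side: each variant's ancestral frequency is uniform on
(0.05, 0.95); line-to-line drift is Beta with concentration `c = 50`
(roughly the spread expected after tens of generations at moderate
effective size); sequencing noise is binomial at 50× coverage. Inside a
planted sweep the selected lines are displaced toward the boundary opposite
the control mean by the target divergence, drawn where that displacement is
feasible, so the expected in-sweep |Δp| equals the target. At these
defaults the no-sweep tail beyond Δp = 0.8 is far below 0.1%, so false
intervals of three or more variants are not expected in a 10,000-variant
genome.

Phenotype side, deliberate simplifications:

* **Lifespan noise is Gaussian** (mean 55 d females / 50 d males, vial SD
  3 d, residual SD 12 d), not Gompertz: the downstream models are ANOVAs on
  means, so only the variance components matter for their calibration. The
  type-I error of the per-sex call is verified to sit in [0.03, 0.07] over
  1000 null simulations.
* **Productivity is simulated on the analysed scale** (offspring per
  female per vial), declining from 45/week to 7/week over six weeks with
  SD 8, truncated at zero — not as egg counts with viability.
* **No linkage structure within sweeps** and no Wright–Fisher forward
  simulation of the selection regime itself: planted sweeps are frequency
  displacements, which suffices to exercise the scan but says nothing about
  haplotype-level signatures.
* Default planted effects (lifespan shifts of 8–10 days, weekly
  productivity shifts of 10 offspring/female, knockdown to 25% expression)
  are free parameters chosen to be comfortably detectable at the design's
  replication — the source material reports no effect-size distribution for
  causal loci, so these are working magnitudes, not estimates. Pre-build
  power calculations at the design sizes give ≈ 1.3 d standard error for a
  per-sex lifespan contrast (so a 10 d shift is ≈ 7.5 SE) and ≈ 3.1
  offspring/female for a weekly contrast (a 10-unit shift is ≈ 3.2 SE,
  per-week power ≈ 0.88); the acceptance script re-estimates both by
  simulation.

Passing tests on these data therefore demonstrate the *procedures* —
thresholding, merging, EMS testing, classification — under the study's
replication structure and realistic noise magnitudes. They do not
demonstrate robustness to non-Gaussian mortality, linked selection, or
batch structure beyond the block design.

## Numerical choices and degenerate inputs

* Thresholds are strict inequalities; a variant at exactly Δp = 0.8 does
  not qualify and an interruption variant at exactly 0.5 blocks a merge.
* A term whose SS is exactly zero reports F = 0, P = 1 even when its EMS
  denominator is also zero (perfectly symmetric inputs).
* Aliased model terms, empty fixed-effect cells, single-level factors and
  zero residual df are errors, named after the offending term.
* Variants with missing line frequencies are dropped with a warning by
  default; a `min_lines` threshold re-admits variants with enough
  non-missing lines per group, recomputing Δp from the available lines.
* All coordinates are 1-based inclusive internally; only the BED export
  converts to 0-based half-open.
* Every stochastic stage draws from a substream seeded by a hash of the
  master seed and a stage tag, so the same configuration is byte-identical
  on re-run and extending the screen panel never perturbs the genome
  simulation.

## Problem sizes used in the tests

The shipped test and acceptance workloads use a 10,000-variant genome with
fifteen planted sweeps for parameter recovery, 1000 random small tables for
the scan oracle, 1000 null screens for ANOVA calibration, and 50 replicate
screens for power estimation — sizes chosen so the full suite documents the
method's operating characteristics while remaining quick to run on a
laptop.

## Known limitations

* The EMS engine targets the small factorial designs of this study; it is
  not a general mixed-model package (no REML, no crossed random effects
  beyond the nesting grammar, no variance-component confidence intervals).
* Classification granularity is that of the call table: a gene whose true
  effects cancel within a week set, or whose effects fall between the
  early and late sets, can be classified conservatively.
* The per-variant divergence P-values are inputs; nothing here models the
  pooled-sequencing error process that produced them.
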