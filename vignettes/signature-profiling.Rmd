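---
title: "Small RNA size-profile signatures: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA size-profile signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virosift)
```

## The model

Insect antiviral RNAi chops double-stranded viral replication
intermediates into 21-nt siRNAs that map to both strands of the viral
genome; the PIWI pathway generates 23–29-nt piRNAs, peaking at 27–28 nt,
usually from predominantly one strand; degradation of abundant single
transcripts produces a broad 15–35-nt smear, also strand-biased. A
contig's *size–strand profile* — read counts over 42 cells (lengths 15–35
nt × strand) — therefore carries a signature of how the host processed it,
independent of sequence similarity to any known virus.

`virosift` operationalizes this in five steps:

1. **Profile.** Each alignment with read length in 15–35 nt increments one
   cell; out-of-range reads are excluded from both cells and total. Only
   contigs with ≥ 100 in-range reads are profiled further (below that, the
   42-cell frequency estimate is too noisy to correlate reliably).
2. **Normalize.** Frequencies are standardized to a z-profile: mean 0,
   sd 1 over the 42 cells.
3. **Cluster.** Pairwise Pearson correlation of z-profiles; UPGMA on
   `d = 1 − r`; cut to `k` clusters.
4. **Label.** Rules on the cluster's mean z-profile and mean
   positive-strand fraction assign `sirna`, `sirna_pirna_mixed`,
   `pirna_positive_biased`, `pirna_negative_biased` or `unassigned`.
5. **Recruit.** An unclassified contig joins the cluster of its
   best-correlated classified virus contig if `r >= 0.9` (and, by
   default, both come from the same sample pool). Rerunning recruitment
   on known-host contigs (the reconstruction control) measures the
   specificity of each signature class: strand-biased profiles are also
   produced by host transcripts, so recruitment into those clusters is
   supporting — not conclusive — evidence of viral origin, while the
   two-strand siRNA signature is highly specific.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| size range | 15–35 | nt | spans siRNA and piRNA products plus flanking degradation sizes |
| `min_len` | 500 (exclusive) | nt | assembly-quality gate; "longer than 500" is strict, so 501 passes |
| `min_reads` | 100 (inclusive) | reads | minimum evidence for a stable 42-cell frequency estimate |
| `corr_threshold` | 0.9 (inclusive) | r | recruitment stringency; inclusive per the method's "at least" wording |
| `identity` / `coverage` | 0.95 / 0.90 | fraction | redundancy collapse, coverage measured on the shorter sequence |
| `k` | 4 | clusters | the number of major signature groups expected in a mixed virome; use 3 for the bundled three-class benchmark |
| `z_enrich` | 1.0 | z units | a cell (or band mean) one population-sd above the profile mean counts as enriched |
| `bias_threshold` | 0.75 | fraction | "predominant" strand: at least 3 of 4 reads on one strand |
| species filters | 100 reads and 1 % | reads, fraction | both inclusive; failing species pool into an "other" wedge |

All are arguments with these defaults; the pipeline config
(`virosift_config()`) round-trips them through JSON.

## What the simulator emulates — and what it does not

`simulate_contigs()` + `simulate_reads()` generate random uniform-GC
contigs and read populations from per-class signature models:

* `sirna`: sizes {20: 0.10, 21: 0.80, 22: 0.10}, strand fraction 0.5;
* `pirna`: {23: 0.05, 24: 0.07, 25: 0.10, 26: 0.15, 27: 0.25, 28: 0.25,
  29: 0.13}, strand fraction 0.10 (negative-biased), with a mirrored
  positive-biased variant;
* `degradation`: uniform over 15–35 nt, strand fraction 0.20.

These pmfs are calibration choices grounded in the qualitative cluster
descriptions of the field (no study prints a quantitative pmf); they were
fixed before any acceptance measurement and are not tuned. Read starts
are uniform (no coverage hotspots), there are no sequencing errors by
default (an optional per-base substitution rate exercises the ≤ 1-mismatch
mapping contract), and contigs are i.i.d. random sequences — so a green
recovery test establishes that the statistical machinery separates the
stated populations, **not** that real viromes separate this cleanly. Real
data add multi-mapping between related viruses, positional coverage
structure, chimeras and pool-to-pool depth variation that the generator
deliberately does not model.

Defaults for the stated benchmark world: 20 contigs per class, lengths
uniform in 1000–3000 nt (typical virus-derived contig lengths after the
500 nt gate), GC 0.5, 4 sample pools assigned round-robin, 1000 reads per
contig. Degradation-class contigs carry origin label `host`, standing in
for the host-derived contigs used in the reconstruction control.

## Numerical choices

* **Joint-strand z-scoring.** The 42-cell vector is standardized across
  both strands jointly, not per strand: the signature heatmaps of this
  method display both strand panels on one normalized scale, and the
  strand asymmetry itself is informative. A per-strand alternative would
  erase strand bias from the profile. (The underlying method description
  is ambiguous; joint is this package's choice.)
* **Population sd (divisor 42).** The 42 cells are the complete
  distribution, not a sample. Correlations are affine-invariant, so the
  choice cannot change any clustering or recruitment result — a property
  the tests verify directly.
* **Degenerate profiles.** A perfectly flat profile has sd 0; it is
  flagged, given all-zero z-values, and excluded from correlation with a
  message rather than producing NaNs.
* **UPGMA tie-breaking.** At equal minimum distance the pair whose sorted
  (smallest-member) labels are lexicographically smallest merges first,
  making the dendrogram deterministic under input permutation. Merge
  heights are the unweighted mean of all original between-group
  distances; average linkage is monotone, so heights never decrease.
* **Correlation method.** Pearson by default; Spearman is available
  (`corr_method`) because parts of the originating literature quote
  Spearman thresholds — the discrepancy is inherited, both are supported.
* **Recruitment rule.** Assignment follows the single best-correlated
  virus contig (the source method names no aggregation rule); the mean
  correlation to the assigned cluster's members is reported alongside for
  transparency. The 0.9 threshold is inclusive.
* **Redundancy collapse.** Greedy longest-first (ties by id), each contig
  joining the first representative reached at ≥ 0.95 identity over
  ≥ 0.90 of the shorter sequence, both orientations tried. The alignment
  is a fitting alignment (shorter global vs best window of the longer;
  match +1, mismatch −1, gap −2). Whether the original tooling measured
  coverage on the shorter or longer sequence is unstated; shorter is
  assumed, which is the more permissive merge.
* **Chi-squared continuity correction** defaults on: with the Yates
  correction the published worked example (36/19,193,551 vs
  160/19,167,336) reproduces its printed statistic 77.36 to two decimals,
  which the tests confirm against an independent four-cell-formula
  oracle.
* **Chimera removal** from the upstream assembly procedure is *not*
  implemented: the original rule is unspecified, and guessing one would
  silently change the contig universe.

## Worked run

```{r example}
sim <- simulate_dataset(n_per_class = 5, reads_per_contig = 500, seed = 101)
pr <- filter_profiles(compute_profiles(sim$alignments, sim$contigs))
zp <- zscore_profiles(pr)
model <- cluster_profiles(zp, pr, k = 3)
model$signatures
```

```{r chisq}
proportion_chisq(36, 19193551, 160, 19167336, locus_id = "XLOC_012931")
```

## Known limitations

* The exhaustive mapper is O(reads × contig length); it exists so tests
  need no external aligner, not for production-scale libraries.
* Recruitment evidence is a correlation, not a homology statement; the
  reconstruction control quantifies, per cluster, how often host contigs
  would be recruited under the same rule, and strand-biased clusters
  should be interpreted with that base rate in mind.
* `k` must be chosen; no height-based or gap-statistic cut is provided
  because the signature classes of interest are few and known.
* The RPKM library-size denominator is the total mapped reads per pool by
  default; if host-filtered totals are available they can be passed
  explicitly, and the choice shifts all values in a pool by a constant
  log-offset.
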