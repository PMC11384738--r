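---
title: "Condition-specific TF target groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific TF target groups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrewire)
```

## The analysis in one paragraph

A transcription factor is profiled (ChIP-seq or CUT&RUN) in two cellular
conditions — think of a naïve pluripotent state and an early
differentiation timepoint. `tfrewire` takes the two called peak sets and
asks three questions. *Where does the factor move?* Peaks are categorised
into condition-1-only, condition-2-only and shared groups, and each
category's overlap with annotated enhancer classes (or with another
factor's peaks) is scored with a hypergeometric test against an explicit
background universe of accessible regions. *Which genes does it target?*
Each peak is assigned to its nearest-TSS gene, giving three disjoint
gene-level target groups. *Does the binding matter transcriptionally?* Each
target group's mean log2 fold change between the conditions is compared
against a null distribution of equally sized random gene groups resampled
from all detected genes — a size-matched bootstrap. A synthetic-data module
generates toy genomes with planted peak composition and planted expression
effects, so every one of these stages can be verified end to end against
known truth.

## Interval conventions

All user-facing coordinates are 0-based half-open (the BED dialect):
`[0, 100)` covers the first 100 bases. Internally intervals live in
`GRanges` (1-based closed); conversion happens only at the BED boundary.
Consequences worth knowing:

* `[0, 100)` and `[100, 200)` do **not** overlap (zero shared bases), so
  they are never joined into one "shared" region and never counted as an
  overlap pair.
* `merge_regions()` at its default `max_gap = 0` **does** join book-ended
  intervals, matching the common merge dialect of interval toolkits. Use
  `normalise_regions()` to collapse only strictly overlapping intervals.
* Peaks on unplaced contigs (name prefix `chrUn` by default) are removed by
  `drop_unplaced()`, and `filter_blacklist()` drops any peak touching an
  artefact-catalogue region by one base or more.

Categorisation (`categorize_by_condition()`) calls a condition-1 peak
*shared* when it overlaps any condition-2 peak by at least one base;
reported shared regions are merged unions of mutually overlapping peaks
from both sides. Because published peak accounting is usually per input
peak, the result exposes both the merged-region count and the per-side
counts, and the per-side counts obey exact conservation:
`n(cond1-only) + n(shared, cond1 side) = n(cond1 peaks)`.

Replicate consensus (`consensus_peaks()`) retains a reference-replicate
peak when some peak of the other replicate covers at least half of it (the
threshold is inclusive and configurable). The fraction is measured on the
reference side because the usual phrasing of the rule ("at least a 50%
overlap between replicates") does not name a denominator; a reciprocal
mode is available when both sides should pass.

## Peak-to-gene assignment

`assign_peaks_to_genes()` implements nearest-TSS assignment: every peak is
given the gene whose TSS is closest on the same chromosome, with distance 0
if the peak spans the TSS and otherwise the gap to the nearest peak edge.
The sign follows the gene's strand (negative = upstream). Exact ties go to
the lexicographically smallest gene id — an arbitrary but deterministic
rule. The promoter flag uses a signed window of (−3000, +3000) bp by
default, the conventional promoter definition of peak-annotation tools.
There is deliberately no default distance cap (every peak gets a gene,
mirroring how distal enhancer peaks are credited to genes in this kind of
analysis); `max_distance` restores a cap when a conservative assignment is
wanted.

Gene-level groups (`derive_target_groups()`) resolve multi-peak genes as
follows: a gene reached via a shared peak, or via separate peaks in both
conditions, is a *shared* target; otherwise it is specific to the one
condition that reaches it. The second clause is a genuine design choice —
peak-level accounting cannot distinguish it — so it is controlled by
`separate_as_shared`; switching it off sets such genes aside as
`ambiguous` rather than silently assigning them, preserving the invariant
that the three groups are disjoint and cover exactly the bound genes.

## The hypergeometric overlap test

The urn must be well defined: a raw peak can straddle two universe
regions, so all counts are taken in **universe-region space**. With a
universe of `N` merged regions, `K` of them overlapped by set A, `n` by
set B and `k` by both, the reported p-value is the upper tail
`P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (depletion is available
behind a flag). The descriptive percentages shown next to the test
(fraction of A peaks overlapping B) are computed on raw peak counts and do
not depend on the universe — the p-value does, which is why
`build_background()` records provenance.

The choice of universe is scientific, not technical. Using only the TF
peaks plus the enhancer catalogue makes the urn nearly degenerate (almost
every region is peak-overlapped and enrichment is invisible). The
appropriate universe is *everywhere the factor could have bound*: all
detected accessible regions merged with the enhancer catalogues. In
synthetic mode the pipeline therefore generates an accessible-chromatin
set (`generate_accessible_regions()`, 3000 regions by default) and merges
it with the enhancer classes and peak sets; in file mode an
`accessible` BED can be supplied. `hypergeom_upper_tail()` itself defers
to the numerically stable distribution function and is checked against
exact combinatorial enumeration for every configuration with `N <= 30`
(for those sizes all binomial coefficients are exactly representable in
double precision, so the enumeration is an exact rational oracle).

No multiple-testing correction is applied inside the enrichment module —
results are reported per test, with `bh_adjust()` available at the
pipeline layer.

## The size-matched bootstrap

For a target group of size `k`, `bootstrap_effect_size()` draws `B`
(default 30,000) random groups of `k` genes *without replacement within a
draw, independently across draws* from the pool of all detected genes —
targets included, since a target list is itself part of the detected
transcriptome; `exclude_targets` changes that. The draw statistic is the
unweighted mean log2FC; genes lacking a log2FC are dropped from pool and
targets with a warning. The empirical p uses the add-one permutation
convention, `(1 + #extreme) / (B + 1)`, so the smallest reportable value
is `1/(B+1)` and 0 is never emitted.

By default the tail is taken in the direction of the observed mean — the
natural question for a group that visibly moved ("how often would a random
group move at least this far in the direction it moved?"). This adaptive
direction has a calibration cost that users should understand: under a
true null the adaptive p is uniform on `(0, 1/2]`, so thresholding it at
`alpha` rejects at about `2*alpha`. All calibration claims in the test
suite are therefore made with a prespecified direction
(`alternative = "greater"`), which is exactly nominal; the adaptive
default is kept for discovery because observed directions of real target
groups are not chosen post hoc from noise. A two-sided option on `|mean|`
is also provided.

`bootstrap_exact()` enumerates every possible draw (bounded at 10^6
combinations) and is the oracle the sampler is tested against; on the pool
`{1,2,3,4,5}` with the two top genes as the target, exactly one of the
`C(5,2) = 10` draws reaches the observed mean, so the exact tail is 1/10.
One further caveat is inherited from sampling the pool as-is: when the
pool itself contains large planted (or real) effect groups, the null
distribution shifts with the pool mean, so an unperturbed control group
can sit slightly off-centre. That is a property of the method, not a bug,
and is visible in the pipeline's null-control results.

## Expression statistics

* `filter_degs()` applies inclusive thresholds: `padj <= alpha` (default
  0.05) **and** `|log2FC| >= 0.5`. Both are deliberately `>=`/`<=`, so a
  gene at exactly log2FC 0.5 or padj 0.05 passes.
* `rank_sum_test()` / `signed_rank_test()` wrap the Wilcoxon tests with a
  documented switch point: exact enumeration for tie-free samples with
  `min(n, m) <= 8` (rank-sum) or `n <= 15` (signed-rank), the normal
  approximation with tie and continuity corrections otherwise. Zero paired
  differences are dropped before the signed-rank test, the standard
  convention.
* `trajectory_summary()` z-normalises each gene across timepoints before
  group-averaging; a constant gene maps to an all-zero trajectory rather
  than NaN.
* `cutrun_relative_signal()` implements the spike-in qPCR scheme: target
  signal over a genomic background region, then over the exogenous
  spike-in, then relative to the control sample, whose own fold change is
  exactly 1. Signals are accepted on a linear scale, or as Ct values
  (`input = "ct"`, converted via `2^(-Ct)`). When a sample carries several
  background or spike-in amplicons their geometric mean is used, since
  these are ratio-scale quantities.

## What the synthetic data emulate — and what they do not

The generator is a study-conditions stand-in, not a sequencing simulator.
Its defaults encode the situation the statistics are designed for:

| parameter | default | why |
|---|---|---|
| genome | one 10 Mb chromosome | exercises interval logic without multi-chromosome bookkeeping (multi-chromosome is supported via config) |
| genes | 300, TSS >= 20 kb apart | keeps peak-to-gene assignment unambiguous enough to validate |
| enhancers | 80 / 100 / 60 per class, 500 bp, >= 3 kb from any TSS | distal regulatory regions; the TSS exclusion mirrors how enhancer catalogues are filtered |
| condition-2 peak composition | 0.04 / 0.50 / 0.24 / 0.22 over (stateA, stateB, shared, background) | ~74% of condition-2 peaks on formative-state enhancers, the headline overlap magnitude the enrichment stage should recover |
| planted effects delta | −0.5 / +0.5 / 0 for (cond1-specific, cond2-specific, shared) targets | condition-1-specific targets down, condition-2-specific up, shared flat — the qualitative pattern the bootstrap must detect, at the same scale as the DEG threshold |
| log2FC noise sd | 0.5 | per-gene scatter comparable to the effect size, so detection is non-trivial |
| replicate jitter | Gaussian, sd 20 bp, 50 bp minimum width | replicates as perturbed copies; no peak-calling noise model is claimed |

Composition labels are exact by construction: enhancer-born peaks are
centred inside a uniformly chosen enhancer of the sampled class, and
background peaks are rejection-resampled until they touch no enhancer.
Synthetic adjusted p-values come from a one-sample z-score of the log2FC
against the noise sd with Benjamini–Hochberg adjustment — this emulates
the *threshold semantics* of a DE table, not the power of a replicated
negative-binomial analysis, and with effect sizes equal to the noise sd it
yields few DEGs; DEG-dependent outputs in synthetic mode should be read
accordingly. (With `noise_sd = 0` the z-score is degenerate; padj is set
to 0 for any nonzero log2FC and 1 otherwise.) Not modelled at all:
nucleotide sequence, read-level noise, signal tracks, peak-width
distributions, inter-gene correlation, library-size effects. Passing
tests on these data demonstrate that the *statistical machinery* is
correct and calibrated — not that any particular biological dataset will
behave this way.

## Determinism and problem sizes

Every generator is a pure function of its config and seed (seeds are
applied through `withr::with_seed`, leaving the caller's RNG untouched);
the pipeline splits one global seed into fixed per-stage offsets, and two
runs with the same config are byte-identical, which the suite checks by
hashing every output file. The test suite exercises: all hypergeometric
configurations with `N <= 30` against exact enumeration; all rank-sum
configurations with `n <= m <= 8` and all signed-rank sign patterns with
`n <= 12`; 100 random toy-genome instances against per-base and all-pairs
oracles; bootstrap calibration over 500 simulated null target sets
(group 100, pool 5000, `B = 499`) and a study-scale run with group sizes
249 / 889 / 486 and `B = 30,000` from a pool of 8000 detected genes —
sizes chosen to match the scale of a typical two-condition TF study while
remaining desk-sized.

## Known limitations

* Nearest-TSS assignment ignores gene bodies, isoforms and annotation
  hierarchies; it is the reproducible core of peak-to-gene association,
  not a replacement for curated annotation.
* The bootstrap pool is not stratified by expression level or gene length;
  matched-covariate resampling is out of scope.
* Enrichment counts ignore how *many* peaks hit a universe region
  (region-space counting keeps the urn valid but discards multiplicity).
* The qPCR normalisation assumes amplification efficiency 2 in Ct mode.

## A compact end-to-end run

```{r run, eval = FALSE}
cfg <- pipeline_config(mode = "synthetic",
                       sim = sim_config(seed = 42),
                       seed = 42, bootstrap_B = 10000,
                       outdir = tempfile("demo_"))
report <- run_pipeline(cfg)
report
report$stages$bootstrap
```

The report's every number is re-derivable from the BED/TSV files written
to `outdir` — the suite re-runs the bootstrap from the written expression
table and compares.
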