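# tfrewire

Integrative analysis of transcription-factor (TF) binding across two
cellular conditions — for example a naïve pluripotent state versus an
early differentiation timepoint. Given per-condition peak sets (BED),
enhancer-class catalogues, gene models and a differential-expression
table, `tfrewire`:

1. **categorises peaks** into condition-1-only, condition-2-only and
   shared groups (1-bp overlap rule, merged shared regions, per-side count
   conservation);
2. **annotates peaks to genes** by nearest TSS (signed distance, promoter
   window, deterministic tie-breaks) and derives three disjoint gene-level
   **target groups**;
3. **scores overlaps** of peak sets with enhancer classes or co-factor
   peaks by a **hypergeometric test** on an explicit background universe
   of accessible regions — with `N` universe regions, `K` overlapped by
   set A, `n` by set B and `k` by both, it reports
   `P(X ≥ k), X ~ Hypergeom(N, K, n)`;
4. **scores transcriptional impact** of each target group with a
   **size-matched bootstrap**: the group's mean log2 fold change is
   compared with `B = 30,000` random same-size gene groups drawn without
   replacement from all detected genes, giving an empirical
   `p = (1 + #extreme) / (B + 1)`;
5. provides DEG filtering (`padj ≤ 0.05`, `|log2FC| ≥ 0.5`, inclusive),
   Wilcoxon rank-sum / signed-rank tests with exact small-sample modes,
   time-course trajectory summaries, and spike-in-normalised CUT&RUN qPCR
   quantification (`fold = ((target/background)/spike) / control`).

A first-class **synthetic-data module** plants known peak composition and
known expression effects on a toy genome, so every stage can be validated
against ground truth without any external download.

## Worked example

```r
library(tfrewire)

cfg <- pipeline_config(mode = "synthetic",
                       sim = sim_config(seed = 42),
                       seed = 42, bootstrap_B = 10000,
                       outdir = "/tmp/readme_run")
report <- run_pipeline(cfg)
print(report)
#> tfrewire run (synthetic mode, seed 42)
#>   peaks: 322 cond1-only, 779 cond2-only, 122 shared
#>   target groups: 30 / 68 / 151 genes
#>   DEGs: 0 of 300
#>   enrichment rows: 6; bootstrap rows: 3
#>   outputs: /tmp/readme_run

report$stages$bootstrap[, c("label","size","observed_mean","p_empirical")]
#>            label size observed_mean p_empirical
#> 1 cond1_specific   30   -0.51511965  0.00009999
#> 2 cond2_specific   68    0.43281330  0.00009999
#> 3         shared  151    0.08055561  0.59524048
```

Reading the output: the simulator planted a mean log2FC shift of −0.5 on
condition-1-specific targets, +0.5 on condition-2-specific targets and 0
on shared targets. The bootstrap recovers exactly that pattern — the two
planted groups are more extreme than any of the 10,000 random size-matched
gene groups (`p = 1/(B+1) ≈ 1e-4`), while the unperturbed shared group is
indistinguishable from random (`p ≈ 0.6`). The enrichment stage likewise
recovers the planted ~74% overlap of condition-2 peaks with the
formative-state enhancer classes:

```r
e <- report$stages$enrich
e[e$set_a == "cond2" & e$set_b == "stateB_specific", ]
#>   set_a           set_b    N   K   n   k     p_value frac_a_in_b frac_b_in_a
#> 4 cond2 stateB_specific 3151 436 100 100 2.74104e-91   0.5358333           1
```

(0 DEGs is expected here: synthetic adjusted p-values emulate threshold
semantics from a single z-score per gene, not the power of a replicated
DE analysis — see the vignette.) All intermediate BED/TSV files are
written under `outdir`, and a rerun with the same config and seed is
byte-identical.

The methods vignette (`vignettes/target-group-analysis.Rmd`) documents the
statistical model, the interval conventions, every tunable threshold, and
what the synthetic data do and do not emulate.

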