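# epistim

Differential methylation and expression analysis for short in vitro
stimulation time courses in primary immune cells.

## The problem this package addresses

Experiments that expose isolated human monocytes to a hormone (e.g.
triiodothyronine, T3), an innate-immune agonist (e.g. LPS), or both, with
a handful of donors contributing paired samples to every arm, produce two
feature-by-sample matrices: EPIC-style methylation beta values
(β ∈ [0, 1], profiled at attachment and 24 h) and RNA-seq counts
(profiled at 0, 4 and 24 h). The scientific questions are set-algebraic:

* which CpGs/genes change during spontaneous in-culture
  monocyte-to-macrophage differentiation (medium vs 0 h);
* which of those changes the hormone *attenuates* (a significant,
  opposite-sign shift of at least 5% methylation);
* which features are *treatment-specific* (changed vs every control arm
  with one sign);
* which form a *unique co-stimulation signature* (changed vs 0 h, medium,
  hormone **and** vs the agonist alone);
* whether the hormone enhances, leaves alone, or abrogates the agonist's
  induced genes (response tertiles).

`epistim` implements this analysis end-to-end for analysts working with
such designs, together with a synthetic-data generator that plants every
effect class with a ground-truth table, so the whole pipeline is testable
without any data download.

## The statistics at its core

* **Methylation:** per-probe least squares on M-values
  (M = log2(β/(1−β))) with donor blocking, `M ~ group + donor`;
  empirical-Bayes variance moderation with the posterior variance
  s̃² = (d₀s₀² + ds²)/(d₀ + d), the prior moment-matched on log s²
  via the inverse trigamma. DMPs: |Δβ| > 0.05 and unadjusted p < 0.05
  (strict), with Δβ always the beta-scale difference of group means.
* **Expression:** RPKM; median-of-ratios size factors; per-gene
  `log2(count/sf + 0.5) ~ group + donor`. DEGs: |log2FC| > 0.58
  (linear 1.5-fold), p < 0.05, mean RPKM > 1, and a sign-agreement
  filter between model and RPKM fold changes. The co-stimulation vs
  agonist contrast instead requires a >1.5-fold change of mean RPKM with
  all donors agreeing in direction.
* **Categories:** pure set logic over the per-comparison statistics
  (induced / attenuated / specific / unique / tertiles), verified against
  an exhaustive truth-table oracle.
* **Regions:** DMRs by gap chaining (≤1 kb between same-sign significant
  CpGs, ≥3 CpGs, ≥1 CpG with |Δβ| > 0.05), Stouffer region p.
* **Annotation:** single nearest TSS within 1 Mb; promoter (≤5 kb) vs
  distal split.
* **Enrichment:** both-strand log-odds PWM scanning of ±100 bp probe
  windows; one-sided hypergeometric enrichment with the composite filter
  (p < 0.05, fold > 1.5, difference > 5 pp, ≥2 target hits, TF expressed);
  the same tail test for GMT term databases.

## Worked example

```r
library(epistim)
study <- simulate_study(n_probes = 6000, n_genes = 2000, seed = 42)
cfg   <- validate_config(list(seed = 42,
           synthetic = list(n_probes = 6000, n_genes = 2000)))
run   <- run_pipeline(cfg, study = study)
print(run)
```

```
pipeline_run (config 5aef6773b255a693 , seed 42 )
  probes: 6000 / 6000 after filtering; genes: 2000
  differentiation DMPs: 396 | T3-specific: 106 | LPS-induced: 210
  diff attenuated by T3: gain 45/199 (22.6%) , loss 45/197 (22.8%)
  unique co-stimulation: 45/170 (26.5%)
```

The manifest reports every category in "x/y (z%)" form: of the 199
gain-of-methylation differentiation DMPs, 45 (22.6%) are significantly
attenuated by the hormone — the generator planted 45 such probes among
6,000, so the engine recovered the planted structure. Per-comparison
statistics are ordinary data frames:

```r
head(call_dmps(run$meth_stats[["T3_vs_RPMI@24h"]])[, c("feature_id","delta_beta","t","p")], 3)
```

```
  feature_id  delta_beta         t            p
1  cg0000032  0.09615931  6.018974 1.755263e-09
2  cg0000042 -0.07873261 -5.141010 2.732654e-07
3  cg0000048  0.10619302  6.371617 1.870456e-10
```

and the motif stage recovers the planted motif against the decoy:

```
  motif_id pct_target pct_background     fold            p passes_filter
1  PLANTED   66.03774           5.90 11.19284 1.270697e-52          TRUE
2    DECOY    0.00000           0.15  0.00000 1.000000e+00         FALSE
```

A thin CLI wraps the same functions
(`Rscript inst/scripts/epistim.R simulate|run-all ...`).

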