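---
title: "Models and design choices in the epistim pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in the epistim pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

`epistim` analyses paired DNA methylation (EPIC-style beta values) and
RNA-seq read counts from short in vitro stimulation time courses in which a
small number of donors (typically three) contribute samples to every arm:
an untreated attachment control collected at 0 h, and four treatment arms
(culture medium alone, a hormone such as T3, an agonist such as LPS, and
the co-stimulation) profiled at 4 h and 24 h for RNA and at 24 h for
methylation. The biological questions are set-algebraic: which features
change during in-culture monocyte-to-macrophage differentiation, which of
those changes a modifier attenuates, which features respond specifically to
one treatment relative to every control, and which respond only to the
co-stimulation. The package implements the probe/gene-level statistics,
the multi-arm category engine, region calling, annotation, enrichment and
reporting needed to answer those questions, together with a synthetic-data
generator that plants every effect class with a known truth table.

# Differential methylation model

Per-probe hypothesis tests are run on the M-value scale,
$M = \log_2\!\big(\beta/(1-\beta)\big)$, while effect sizes are reported as
the beta-scale difference of group means ($\Delta\beta$). The modeling
scale is a genuine free choice — beta values are variance-compressed near 0
and 1, M-values are approximately homoscedastic — so the scale is exposed
as a configuration switch (`meth_scale`), with M as the default and
$\Delta\beta$ always computed on the beta scale so that the 0.05 threshold
keeps its "5% methylation change" meaning. Betas are clipped to
$[10^{-6}, 1-10^{-6}]$ before the logit so simulated extremes stay in
domain.

Each probe is fit by least squares as `response ~ group + donor`. Donor
blocking is stated by the source analysis for the expression model; we
treat the methylation model symmetrically because the design is fully
paired, and expose `block_donor` as a switch. With three donors and two
arms this leaves two residual degrees of freedom per probe, which makes
variance moderation matter.

Moderation uses the standard empirical-Bayes posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with the prior
$(d_0, s_0^2)$ estimated by moment matching on $\log s^2$: under a scaled-F
marginal the variance of $\log s^2$ in excess of $\psi'(d/2)$ identifies
$d_0$ through the inverse trigamma, and the mean identifies $s_0^2$. When
the observed spread does not exceed what the residual degrees of freedom
alone imply, the prior df is infinite and all posterior variances collapse
to $s_0^2$; when the spread is numerically zero the prior variance is the
common $s^2$ itself (the only consistent fixed point). The moderated t
uses $d_0 + d$ degrees of freedom (normal when infinite). This machinery
is implemented in the package rather than delegated, and the test suite
cross-checks the estimated prior and posterior variances against
`limma::squeezeVar` on heterogeneous-variance fixtures.

A caveat the test suite reflects: because every probe shares the one
estimated prior, moderated p-values are very slightly dependent across
probes. The per-probe t-test p-values are exactly uniform under the null;
the moderated ones are uniform to within that shared-estimate wobble, which
a Kolmogorov–Smirnov test at tens of thousands of probes can occasionally
notice. The unit test of uniformity therefore targets the unmoderated
fitter, while the acceptance-level calibration check runs the full
moderated stage at 20,000 probes.

DMPs are probes with $|\Delta\beta| > 0.05$ and unadjusted $p < 0.05$,
both strict. No multiple-testing correction enters the calling logic (a BH
column is emitted for transparency only), because the category engine's
set definitions are stated in terms of unadjusted p-values.

# Differential expression model

RPKM is computed from raw counts and gene lengths with per-sample library
sizes. Donor sex is assigned from XIST expression (mean RPKM strictly
above 1 across a donor's samples = female); the default simulated study is
male, so the planted XIST gene is near-silent.

For testing, counts are normalized by median-of-ratios size factors
(explicitly geometric-mean-centered so they multiply to 1), shifted by a
0.5 pseudocount, log2-transformed and fit as `log2(count/sf + 0.5) ~ group
+ donor`. The original analysis used a negative-binomial Wald test; we use
this log-linear model deliberately: the downstream category logic consumes
only the triple (log2FC, p, mean RPKM), the paired three-donor design
leaves little information for per-gene dispersion estimation, and the
log-normal approximation is accurate at the read depths simulated here.
DEG calling applies four strict criteria: $|\log_2 FC| > 0.58$ (the linear
1.5-fold cut), unadjusted $p < 0.05$, mean RPKM over the samples of the
two compared groups $> 1$ (an all-samples variant is a switch), and the
sign-agreement noise filter that discards genes whose model fold change
opposes the fold change of group-mean RPKM.

The co-stimulation vs agonist expression contrast uses a different,
deliberately non-parametric criterion mirroring its source: linear fold
change of group-mean RPKM strictly above 1.5 (or below 1/1.5) with every
donor's individual ratio agreeing in direction. The threshold is applied
on the linear scale; note $\log_2 1.5 = 0.585$, so a log-scale test at
0.58 would (just) pass an exact 1.5-fold change that the strict linear
rule rejects. Zero denominators get a 0.1 RPKM pseudocount.

# The category engine

All categories are set logic over per-comparison statistics sharing one
feature universe:

* **Induced** (differentiation-associated, treatment-specific,
  co-stimulation-specific): the feature passes its thresholds against
  *every* reference arm with one shared effect sign.
* **LPS-induced** is the union of two routes — agonist vs medium and 0 h,
  or co-stimulation vs hormone and 0 h — deduplicated, with route
  provenance retained; the rare feature whose two routes disagree in
  direction is dropped with a message.
* **Attenuated**: a member of an induced set is attenuated when the
  modifier comparison (hormone vs medium, or co-stimulation vs agonist) is
  itself significant at the same thresholds with sign *opposite* to the
  base direction. The modifier's own p-value and effect are used — not an
  interaction term — matching the pairwise structure of the source
  cut-off table.
* **Unique co-stimulation**: a co-stimulation-specific feature that also
  passes the contrast against the agonist alone, with the same sign.

Counts are reported as "x/y (z%)" with one decimal, using `round()`
(half-even). The source text itself prints one such fraction
inconsistently (2.6% in the body, 2.7% in a caption, for a true value of
2.64%); this engine always reports the half-even rounding, i.e. 2.6.

Response tertiles rank genes by the ratio of group-mean expression
(co-stimulation / agonist), descending, splitting into
enhanced/no-effect/abrogated thirds. The remainder rule (extras assigned
top-first) and the tie rule (lexicographic gene id) are not stated by the
source and are fixed here for determinism.

The engine is verified against an exhaustive truth-table oracle — an
independent per-feature evaluation of the logical definitions — with exact
set equality required, both on random comparison tables and end-to-end on
synthetic studies.

# DMR calling

Regions are built by gap chaining: candidate probes (p below threshold)
are chained along a chromosome while consecutive candidates share an
effect sign and lie within 1,000 bp of each other; non-candidate probes in
between are ignored (the alternative — breaking chains at any
non-candidate — is stricter than the stated criteria and is not used). A
chain is a DMR when it has at least three CpGs and at least one member
exceeds the $\Delta\beta$ threshold. The original kernel-based region
statistic is replaced by this chaining because the stated acceptance
criteria are exactly the three rules above and chaining enforces them by
construction; the 1,000 bp gap mirrors the original tool's default
bandwidth. The region p-value is a sign-aligned Stouffer combination of
member p-values — a summary, not a calibrated region-level test. Interval
intersection is half-open 0-based, implemented over `IRanges` and verified
against a quadratic all-pairs oracle.

# Annotation

Probes map to the single nearest TSS within 1 Mb (not a full
basal-plus-extension regulatory-domain model, which the source does not
invoke); ties resolve to the lexicographically smallest gene id. Signed
distance is genomic (positive downstream on the gene's strand). The
promoter/distal split is at 5 kb; the source's strict < and > leave
exactly 5,000 bp undefined, which we assign to PROMOTER and document.
The synthetic annotation has one TSS per gene, so the canonical-vs-isoform
TSS question does not arise.

# Motif and term enrichment

Sequences of 201 bp (±100 bp around each probe) are scanned on both
strands at every offset with log-odds PWM scoring (N scores as
background); a sequence is a hit when its best score reaches the motif
threshold, by default 80% of the maximum attainable score. Enrichment of
target vs background hit fractions uses the one-sided hypergeometric tail
rather than the original tool's binomial/ZOOPS machinery — the source
defines its filter purely by thresholds (p < 0.05, fold > 1.5, difference
> 5 percentage points, at least two target hits), and the hypergeometric
is the exact test for the 2×2 counts we actually form. The background
defaults to non-target probe windows from the same universe (the original
background construction is unstated; this is configurable). Motifs whose
TF shows log2 mean RPKM below 0 in every treatment arm are excluded with
an explicit reason. Term enrichment is the same tail test per term with a
two-gene minimum; no curated term content ships with the package — the
generic operation reads GMT files, and synthetic runs build a random term
database with one deliberately enriched term.

# Reporting

Z-scored matrices are row-standardized with constant rows zeroed and
flagged. PCA projects samples onto eigenvectors of the feature-centered
covariance, with the sign convention that each component's
largest-magnitude loading is positive; the input scale (raw beta vs
z-scored) is recorded in the output, defaulting to raw. The
median-trajectory summary follows the order of operations "per-feature
group mean, then median over features" for expression (the grammatically
ambiguous alternative, per-sample median then mean, is a flag) and the
median over all member beta values for methylation.

# The synthetic-data generator

Methylation is simulated on the M scale: per-probe baseline (uniform
betas in 0.2–0.8 by default), a donor random intercept shared across arms
within a donor (SD 0.25 in log2-odds units), planted group offsets, and
Gaussian noise (SD 0.12). Offsets are computed exactly so the expected
beta-scale difference equals the requested $\Delta\beta$; magnitudes that
would push an expected beta outside (0.01, 0.99) are rejected. The donor
intercept exists precisely so donor blocking has something to remove; the
noise level was chosen once, before any recovery measurement, by a power
analysis of the paired three-donor design: at 0.12 log2-odds units the
null spread of $\Delta\beta$ stays safely inside the 0.05 calling
threshold (empirical FDR well under 0.2) while a planted 0.15 effect is
detected with near-certain sensitivity. It corresponds to a beta-scale
replicate SD of roughly 0.02 at mid-methylation, in line with short-term
technical-plus-culture variability on methylation arrays.

Expression is negative binomial with lognormal baseline means (median
around 800 counts, spread sdlog 1.2), donor-specific library-size factors
(sdlog 0.1), planted log2 offsets, and dispersion 0.01 — the residual
within-donor dispersion after donor blocking for aliquots of one
isolation, chosen by the same a priori power reasoning (null
$|\log_2$ ratio of group means$|$ has median below 0.1 at these depths).
An XIST gene is always present (near-zero mean for the default male
donors; high for the female option).

Planted effect classes mirror the category engine: differentiation
effects apply to all stimulated arms; attenuation classes apply the base
effect and remove two-thirds of it (`atten_frac = 2/3`, so a 0.15 base
effect is attenuated by 0.10, comfortably clearing the 0.05 attenuation
threshold) in the modifier arms; treatment-specific and unique classes
apply offsets only in the relevant arms. The default desk-scale plan
plants 2,300 of 20,000 probes and 870 of 5,000 genes, scaling
proportionally for other sizes, plus twelve 4-probe runs of consecutive
probes carrying a shared gain so the DMR caller has real regions to find
(consecutive simulated probes are 300–1,500 bp apart, so some planted
runs legitimately exceed the 1,000 bp chaining gap and stay uncalled).

What the generator does **not** emulate: array chemistry and IDAT-level
artifacts, between-array normalization residue, bisulfite-conversion
error, probe cross-hybridization structure, genuine genomic CpG density
(probe spacing is uniform-random), read-level RNA-seq features (mapping
bias, isoforms), or correlated biological modules. Passing recovery tests
therefore demonstrates that the statistics and set logic behave correctly
under the stated noise model — not that the thresholds are optimal for
any particular real data set.

# Numerical and determinism choices

Beta clipping $10^{-6}$; pseudocounts 0.5 (normalized counts before log2)
and 0.1 RPKM (ratio denominators); PWM probabilities floored at $10^{-10}$
inside log-odds; tie-breaks are lexicographic everywhere a rank can tie;
tertile extras go top-first. Every stochastic step takes an explicit
integer seed, assay-level seeds are derived from the master seed by small
offsets, and two runs with one configuration are byte-identical — the
test suite compares complete output directories at the byte level. Each
output file is stamped with a 16-hex-digit hash of the configuration
(excluding the output directory itself, so identical analyses written to
different places carry the same stamp).

Problem sizes in the shipped tests were chosen to keep the default suite
fast while leaving at least 10,000 true-null probes in calibration runs:
20,000 probes / 5,000 genes for the calibration and recovery checks,
2,500–3,000 probes for the end-to-end determinism runs, and at most
1,000-element instances for the exact-oracle suites.

# Known limitations

* The region p-value is a Stouffer summary without region-level error
  control; no FDR is computed over regions, matching scope.
* With three donors, the unmoderated per-gene t has two residual df;
  power at small fold changes is limited and the acceptance recovery
  conditions (log2FC 1.5 at dispersion 0.01) reflect that.
* The category engine treats each comparison's pass/fail as given; it
  does not model the correlation between comparisons sharing arms.
* Nearest-gene assignment is single-gene; features between two genes'
  regulatory domains are attributed to one gene only.
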