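---
title: "Methods: dosage and regulatory effects of rare structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage and regulatory effects of rare structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A rare structural variant (SV) is carried by at most a handful of
individuals in a cohort, so its effect on gene expression cannot be
estimated per variant. What can be estimated is the average relationship
between *what* an SV overlaps and *how far* carrier expression departs
from the noncarrier distribution. `svdosage` operationalizes that idea in
four stages: interval annotation, per-pair effect quantification, a joint
linear model, and an intolerance-weighted aggregate for prioritization.

# Definitions and model

**Coordinates.** All intervals are 0-based half-open, so
`length = end - start` with no ambiguity. VCF input (1-based) is converted
on read and back on write. Insertions (INS/ALU/LINE1/SVA) are represented
as 1-bp points at the insertion site; their `length` field carries the
insert size. The point representation is the conservative choice for
overlap purposes: an insertion interrupts a single position, and padding
it would manufacture regulatory overlaps that the data do not support.

**Pairs.** An SV × gene pair exists whenever the gene's TSS lies within
1 Mb of the SV interval — the standard *cis*-eQTL window, measured to the
TSS (the regulatory anchor used throughout) rather than the gene body.
The window is configurable.

**Covariates.** For each pair:

* `p_exon` ∈ [0, 1] — fraction of the gene's *unioned* exonic bp (across
  isoforms) inside the SV. Using the union makes the value invariant to
  how isoforms partition the exons; isoform-level weighting would need
  isoform-level expression, which the pipeline does not consume.
* `p_prom` ∈ [0, 1] — fraction of the promoter overlapped. Promoters are
  the 2 kb window upstream of the TSS, strand-aware, truncated at the
  contig start (so a TSS at position *b* < 2000 has a promoter of length
  *b*).
* `enh_sum` ≥ 0 — sum over enhancers linked to the gene of
  (overlap bp / enhancer length). This is a sum of per-element fractions,
  so it can exceed 1 when several linked enhancers are hit; it is *not*
  invariant to re-segmenting an enhancer, which is inherent to the
  definition (what is preserved under splitting is the length-weighted
  overlap).
* `within_tad` ∈ {0, 1} — one TAD contains both the gene's TSS and at
  least 1 bp of the SV. Anchoring on the TSS keeps the indicator
  consistent with the pairing rule.
* `sv_length` — bp, entering the model in raw bp (coefficients are
  naturally of order 1e-7 per bp).

**Expression measures.** On the CPM scale, relative expression is the
mean carrier CPM divided by the mean noncarrier CPM. On the
covariate-adjusted scale, the carrier z-score standardizes the mean
carrier value by the *noncarrier* mean and SD — using noncarriers only
prevents the carriers themselves from inflating the reference SD at
higher allele frequencies. When an SV has several carriers the mean
carrier value is standardized (the mean is more stable than the maximum;
per-carrier z-scores would pseudo-replicate a single variant). A floor of
20 noncarriers (configurable) is required for the SD estimate; outliers
are |z| > 2.

**Enrichment tests.** Outlier enrichment is tabulated per SV type ×
annotation class × direction (z > 2, z < −2, |z| > 2) with one-sided
Fisher tests against the intergenic pairs of the same SV type, and a
Bonferroni family of exactly 5 × 4 × 3 = 60 tests (threshold
0.05/60 ≈ 0.00083). Class assignment is pair-level for the genic classes:
a pair is `coding`/`other_transcribed` only when the SV overlaps exonic
sequence *of that gene*, while intronic and intergenic SVs contribute
every windowed gene. The pair-level rule is what makes genic outlier
proportions interpretable — under SV-level assignment every genic SV
would drag its ~dozens of unaffected neighbours into the numerator class
and dilute the signal far below anything observable.

**The joint dosage model.** Per CNV type (deletions and duplications are
always fitted separately, never pooled with an interaction),

z = β_exon·p_exon + β_enh·enh_sum + β_prom·p_prom + β_len·L + β_tad·TAD + intercept + ε

fitted by OLS. An intercept is included even though the reference
coefficient table carries none: carrier z-scores need not be mean-zero,
and omitting the intercept would bias slope recovery; it can be switched
off (`intercept = FALSE`). Rank-deficient designs are refused with the
collinear columns named. Cross-cohort evaluation fits per cohort and
reports the squared Pearson correlation between predicted and observed z
on the test cohort; squared Pearson (rather than regression R²) is used
because the prediction is applied unchanged, with no re-calibration on
the test set.

**Selection statistics.** Functional SVs are compared with intergenic
controls of the same SV type after greedy nearest-length matching without
replacement, processed in seeded random order, with tolerance
min(500 bp, 10% of the functional SV's length); matching without
replacement avoids reusing one control's allele frequency many times.
The AF comparison is a one-sided Wilcoxon (functional rarer), matching
the directional claim being tested. Singleton proportions (exactly one
carrier) are bootstrapped over SVs within class (percentile 2.5/97.5,
default 1000 replicates); the bootstrap unit is the variant because the
interval describes variant-sampling uncertainty. Intolerance quintiles
are equal-size gene bins from least to most intolerant with ties broken
by gene id for reproducibility.

**Regulatory disruption.** `S = Σ_g ẑ_g · w_g` over protein-coding genes
in the window that have both a model prediction and an intolerance
weight. Weights come from a min-max transform of the LoF metric,
orientation-corrected so 1 = most intolerant (a rank-based transform is
available via `method = "rank"`; min-max is the default because it
preserves the metric's spacing). Pathogenic labeling requires the SV to
cover ≥ 50% of a known pathogenic CNV of the same type — the denominator
is the known variant's length, not reciprocal overlap, because the
question is whether the known lesion is recapitulated. Prioritization
curves rank deletions by most-negative S and duplications by
most-positive S; ties (ubiquitous for allele frequency, where singletons
dominate) are ordered randomly under a supplied seed.

# The synthetic-study generator

The generator produces the full input bundle — annotation, SV callset,
intolerance table, two-cohort expression on both scales, and a truth
table — so every stage of the pipeline can be exercised and calibrated
without controlled-access data.

* **Genome and annotation.** One synthetic chromosome (default 120 Mb)
  tiled by 1200 genes with 1–20 exons each (log-normal exon/intron
  lengths), exponential intergenic gaps, ~30% of genes receiving 1–5
  linked enhancers within 1 Mb of their TSS (mirroring the roughly 30%
  gene coverage of Hi-C-derived enhancer-gene maps), TADs partitioning
  the chromosome, and CTCF sites split between TAD boundaries and free
  intergenic positions.
* **SVs.** 20,000 SVs by default (40% deletions, 20% duplications, the
  rest insertions/mobile elements/inversions/complex), uniform positions,
  log-normal lengths (median 280 bp, a heavy right tail), all rare and
  heterozygous: carrier counts are 1 plus a truncated Poisson, capped so
  the carrier fraction stays below 1% and AF below 0.5%. SVs overlapping
  a gene body, enhancer or CTCF site have their expected extra-carrier
  count multiplied by `exp(-af_shift)` (default 0.3), the generator's
  selection knob; `af_shift = 0` is the null. An optional placement-bias
  mode re-draws CNVs that land on exons of the most intolerant gene
  quintile, used to exercise the quintile-deficit analysis.
* **Expression.** The adjusted scale is generated *from the joint model
  itself*: noncarriers are N(0, 1) per gene; carriers receive
  μ = Xβ added, with β defaulting to the reference deletion/duplication
  coefficient sets and residual SD `noise_sd = 1` (the variance of
  carrier expression around the fitted mean is not constrained by any
  reported value, so unit noise — the same scale as the noncarrier
  distribution — is the natural default). Using the inference model as
  the simulator makes parameter recovery the natural end-to-end test.
  The CPM scale has log-normal per-gene baselines and mean-one log-normal
  measurement noise (sdlog 0.15, a ~15% coefficient of variation typical
  of expression measurements after library-size normalization; set
  `cpm_noise_sdlog = 0` to disable), and carriers of a CNV covering
  exonic fraction p are multiplied by 1 − 0.5p (deletion) or 1 + 0.5p
  (duplication) — linear interpolation between no effect and the
  heterozygous full-gene expectation of 0.5× / 1.5×.
* **Cohorts.** Two cohorts (default 300 + 300 samples) share the
  annotation and callset but have disjoint samples; per-cohort
  perturbation of the generative β (`cohort_beta_sd`) exercises
  asymmetric cross-cohort transfer.
* **Determinism.** The seed is part of the configuration; identical
  configurations yield bit-identical studies.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage and recombination structure,
sequence context (no FASTA, no reads), isoform-level expression,
covariate/batch structure (the adjusted scale is generated directly,
whereas real adjusted expression is the residual of a normalization
pipeline), genotyping error, and any correlation between SV length and
placement. Effects of CNVs on expression are purely additive across
variants and linear in the covariates, by construction.

# Numerical choices and degenerate inputs

* Interval unions and overlaps go through `GenomicRanges`; empty inputs
  yield empty, valid outputs.
* Quartile fences for sample QC use R's default quantile definition
  (type 7) and refuse fewer than 4 samples.
* Undefined statistics are reported as missing, never silently dropped:
  relative expression with a zero noncarrier mean, z-scores with zero
  noncarrier SD or too few noncarriers, Spearman correlations of constant
  vectors.
* Wilcoxon tests fall back to the normal approximation with ties (R's
  default); agreement with exact enumeration is asserted for n ≤ 8.
* Min-max intolerance normalization refuses a constant metric.
* Ties in rankings and quintile assignment are broken deterministically
  (by id) or by a seeded shuffle where the procedure calls for random
  order; both re-run identically under the same seed.

# Problem sizes used by the test suite

The test and acceptance workloads are sized for a single CPU: shared
studies of ~120 genes and ~2000–2500 SVs across 600 samples; parameter
recovery at 50,000 SV × gene rows per CNV type (20 seeds); null
calibration over 100 seeded studies of ~100 genes and ~3100 SVs; the
dosage-expectation check over ≥ 1000 simulated full-gene deletion pairs
(1200 genes, 7000 deletions with a 40 kb median length so that full
coverage is common); and the prioritization property over 100 seeded
deletion-only studies. Where a check needs allele-frequency diversity the
full 600-sample default is kept, because the rarity cap (carrier fraction
< 1%) makes every SV a singleton in small cohorts.

# Known limitations

* The model is linear and unregularized by design; it will not capture
  saturating or gene-specific dosage responses.
* CTCF-site disruption is annotated and tested for selection but carries
  no term in the prediction model, since a CTCF site has no principled
  single-gene assignment; its expression consequences are therefore
  invisible to the disruption score.
* Noncarriers of one SV may carry other SVs near the same gene; no
  cross-SV exclusion is applied, which slightly contaminates reference
  distributions in dense simulated callsets.
* Whether an SV×gene pair's multi-carrier z should use the mean, median
  or per-carrier values is a genuine open choice; the mean is
  implemented.
* Insertions are points; if insertion padding matters for a user's
  annotation set, the interval convention must be changed upstream.
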