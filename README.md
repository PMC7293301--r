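# svdosage

Rare structural variants (SVs) — deletions, duplications, insertions,
inversions and mobile-element insertions — can change how much a gene is
expressed, either by altering its exonic dosage directly or by disrupting
the *cis*-regulatory landscape around it (promoters, enhancers, CTCF
insulator sites, topologically associating domains). Because each rare
variant is seen in only one or a few carriers, per-variant association
tests are hopeless; what can be estimated is the *average* relationship
between what an SV overlaps and how carrier expression shifts.

`svdosage` implements that analysis as a reusable R pipeline for anyone
working with matched SV callsets and expression matrices (e.g. from
post-mortem brain cohorts):

* **Annotation** — interval arithmetic between SVs and gene models,
  2 kb promoters, Hi-C-linked enhancers, CTCF consensus sites and TADs,
  yielding per SV × gene covariates: exonic proportion `p_exon`, promoter
  proportion `p_prom`, summed enhancer fraction `enh_sum`, a within-TAD
  indicator and SV length, for every gene with a TSS within 1 Mb.
* **Selection statistics** — length-matched allele-frequency comparisons
  between functional and intergenic SVs (one-sided Wilcoxon), singleton
  proportions with bootstrap CIs, the annotation-count/AF trend, and
  gene-intolerance quintile analyses.
* **Expression effects** — per pair, relative expression (mean carrier
  CPM / mean noncarrier CPM), carrier z-scores standardized by noncarrier
  mean and SD, outlier calls at |z| > 2, and one-sided Fisher enrichment
  tests against the intergenic baseline with a 60-test Bonferroni family
  (p < 0.05/60 ≈ 0.00083).
* **The joint dosage model** — per CNV type, OLS of carrier z-scores on
  the five covariates:

  `z = β₁·p_exon + β₂·enh_sum + β₃·p_prom + β₄·L + β₅·TAD + ε`

  A full heterozygous deletion is expected to halve CPM (relative
  expression 0.5) and a full duplication to raise it 1.5-fold; on the
  z-score scale the reference coefficients are β₁ ≈ −1.78 for deletions
  and +0.78 for duplications, with promoter effects −0.17 / +0.37 and a
  small negative enhancer-sum effect.
* **Regulatory disruption** — per SV, `S = Σ_g ẑ_g · w_g` over nearby
  protein-coding genes, where `ẑ_g` is the model-predicted z-score and
  `w_g` a loss-of-function intolerance weight normalized to [0, 1]
  (1 = most intolerant). SVs covering ≥ 50% of a known pathogenic CNV of
  the same type are labeled pathogenic, and cumulative-pathogenic curves
  compare rank-orderings by disruption, length, gene counts and allele
  frequency.
* **A synthetic-study generator** — annotation, rare heterozygous SV
  callset, intolerance metrics and two-cohort expression on both the CPM
  and covariate-adjusted scales, generated from the dosage model itself so
  that every downstream stage is testable without controlled-access data.

## Worked example

```r
library(svdosage)

cfg <- sim_config(seed = 42L, n_genes = 120L, genome_length = 2.4e7,
                  n_svs = c(DEL = 900L, DUP = 450L, INS = 300L,
                            ALU = 200L, INV = 120L, CPX = 60L),
                  n_ctcf = 250L, n_tads = 16L)
study <- simulate_study(cfg)
study
#> synthetic_study: 120 genes, 2030 SVs, 600 samples (cohortA+cohortB), 19752 SVxgene pairs

eff <- expression_effects(study$svs, study$features, study$cpm, study$adjusted)
fit_dosage_model(study$features, eff, "DEL")
#> dosage_fit (DEL): n = 8722 rows
#>          term       beta        se       t         p
#> 1 (Intercept)  1.892e-02 1.924e-02  0.9831 0.3256043
#> 2      p_exon -1.556e+00 4.536e-01 -3.4308 0.0006047
#> 3     enh_sum  1.498e-01 3.002e-01  0.4991 0.6176980
#> 4      p_prom  2.128e-01 4.131e-01  0.5151 0.6065200
#> 5   sv_length -3.514e-07 1.001e-06 -0.3511 0.7255137
#> 6  within_tad -3.987e-02 2.191e-02 -1.8194 0.0688812
```

The exonic-proportion coefficient (−1.56 ± 0.45) recovers the generative
value −1.78 within its standard error at this small scale; the regulatory
terms are individually underpowered here and sharpen as the number of
SV × gene rows grows (see the acceptance script, which fits 50,000 rows).

Selection against functional SVs shows up as lower allele frequencies
after length matching:

```r
cl   <- classify_svs(study$svs, study$annotation)
func <- study$svs[cl$n_functional_classes > 0, ]
ctrl <- study$svs[cl$classes == "intergenic", ]
af_comparison(match_by_length(func, ctrl, seed = 1), study$svs)
#> mean AF functional = 0.00115, intergenic controls = 0.00140,
#> one-sided Wilcoxon p = 0.000639 (n = 110 pairs)
```

A command-line wrapper is installed at `exec/svdosage` with subcommands
`simulate`, `annotate`, `effects`, `fit`, `predict`, `score` and
`prioritize`; run it with no arguments to see usage.

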