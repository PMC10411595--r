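---
title: "Methods: multi-strain RNA-seq differential expression with reference-bias screening"
author: "strainexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-strain differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainexpr)
```

# The problem

When gene expression is compared across wild isolates of *Caenorhabditis
elegans* (or any organism quantified against a single reference genome), two
distinct questions interact. First, which genes differ in expression between
strains, and does the transcriptional response to a perturbation such as RNAi
depend on the strain? Second, which apparent expression differences are
artifacts of **reference bias** — sequence divergence from the reference
genome impairing read alignment, so that a gene looks silent in a strain
simply because its reads cannot be mapped or the locus is absent from that
strain's genome?

`strainexpr` implements both halves as a tested pipeline: negative binomial
(NB) likelihood-ratio tests for strain and strain-by-treatment effects,
within-strain treatment contrasts with fold-change shrinkage, identification
of strain-specific unexpressed ("off") genes, a DNA-coverage screen that
resolves each off call into *truly off* / *missing from the genome* /
*uncertain (low coverage)*, and the overlap statistics that relate the DE and
poor-coverage gene sets. A synthetic-data generator with full ground truth
drives end-to-end validation.

# The count model

Counts for gene $i$ in sample $j$ are modeled as

$$K_{ij} \sim \mathrm{NB}(\mu_{ij},\ \alpha_i), \qquad
\mu_{ij} = s_j\, q_{ij}, \qquad
\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

where $s_j$ is a per-sample size factor and $\log_2 q_{ij}$ is a linear
predictor in the design. Three screens are built on this model:

* **Strain screen** (control samples only):
  $\log_2 q_{ij} = \beta_{1i} x_j + \beta_{0i}$ versus the intercept-only
  null, tested per gene by a likelihood-ratio test (LRT) with degrees of
  freedom equal to the number of non-reference strains (4 for 5 strains).
* **Interaction screen** (all samples):
  $\log_2 q_{ij} = \beta_{1i} x_j + \beta_{2i} y_j + \beta_{3i} x_j y_j +
  \beta_{0i}$ versus the additive model without $\beta_3$; with 5 strains
  and 3 treatments the LRT has 8 degrees of freedom.
* **Within-strain contrasts**: for each strain, the NB GLM
  `~ treatment` is fitted on that strain's samples alone and each RNAi
  treatment is compared to the control by a two-sided Wald test.

Fitting uses the natural-log link internally (IRLS via `glm.fit` with the
`MASS` NB family); all reported coefficients are log2.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| low-count filter | 10 reads | genes with fewer summed reads across all samples are excluded |
| FDR | 0.1 | Benjamini–Hochberg adjusted-p threshold for all screens |
| fold change | 1.5 (linear) | DE calls additionally require \|shrunken log2 FC\| > log2 1.5 ≈ 0.585 |
| coverage low | 0.25 | median-normalized DNA coverage below this (strictly) is "low" |
| dispersion floor | 1e-8 | lower clamp on per-gene $\hat\alpha$ |

The fold-change threshold is interpreted on the linear scale ("greater than
1.5-fold"), i.e. $|\log_2 \mathrm{FC}| > \log_2 1.5$, with *down* meaning
$\log_2 \mathrm{FC} < -\log_2 1.5$. Significance for every screen means
*adjusted* p below the FDR threshold.

## Normalization and dispersion

Size factors use the standard median-of-ratios estimator with
zero-containing genes excluded from the reference set; the unit test suite
cross-checks it against `DESeq2::estimateSizeFactorsForMatrix`. Transcript
length offsets from upstream quantifiers are out of scope — counts are taken
as given.

Dispersions are estimated per gene by profile likelihood: coordinate ascent
alternating a GLM fit at the current $\alpha$ with a one-dimensional
likelihood maximization in $\log\alpha$ given the fitted means, clamped at a
floor of $10^{-8}$. No empirical-Bayes moderation is applied by default.
This is a deliberate simplification relative to packages that shrink
dispersions across genes: it is transparent and exactly testable, but it
means gene lists on real data will not numerically match moderated
pipelines, especially for genes with few replicates and weak signal.

## Degenerate cells and the pseudo-guard

A design cell whose counts are all zero (exactly what an off gene produces)
drives its coefficient to $-\infty$: complete separation, under which the
Wald standard error explodes and the test loses all power against the most
extreme differences. When a fit detects an all-zero cell alongside nonzero
counts elsewhere, a pseudo-count of 0.125 is added *inside the optimizer
only* — reported log-likelihoods are evaluated with the original counts, and
the guard never appears in any emitted count table. An entirely zero gene is
returned as a flagged degenerate fit and excluded from calls.

## Fold-change shrinkage

Raw log2 fold changes are shrunk with a zero-centered normal prior whose
scale is estimated by marginal maximum likelihood across genes
($\hat\beta \sim N(0, \tau^2 + \mathrm{se}^2)$); the posterior mean is
$\hat\beta\,\tau^2 / (\tau^2 + \mathrm{se}^2)$. This keeps the
shrink-toward-zero contract of adaptive-shrinkage estimators (never
inflating, recovering the raw value as the standard error vanishes) in a
closed form that a unit test can verify exactly. It does not reproduce
adaptive shrinkage's mixture prior, so shrunken effect sizes on real data
will differ in detail.

## Multiple testing and independent filtering

BH adjustment is applied per screen. Optional independent filtering chooses
a base-mean threshold over a quantile grid (0–95% in 5% steps) maximizing
rejections at the target FDR; filtered genes receive no adjusted p-value.
It defaults to on in the orchestrated pipeline (mirroring how genome-scale
screens exclude weakly detected genes from adjustment) and off in unit
tests, where the plain BH path is checked against a brute-force oracle.

## PCA

Counts are transformed as $\log_2(k_{ij}/s_j + 1)$ — a simple
variance-stabilizing transform chosen over the fitted dispersion-based
transform for transparency — the 500 most variable genes are selected,
centered per gene, and decomposed by SVD.

# The coverage screen

Per gene, all exon intervals across transcripts are merged into
nonoverlapping, nonduplicated intervals (GTF 1-based inclusive coordinates
in, BED 0-based half-open out; `GenomicRanges::reduce` underneath, verified
against a per-base set-union oracle). Per-gene coverage is the
length-weighted mean of per-merged-exon mean depth,

$$\mathrm{cov}_g \;=\; \frac{\sum_e \mathrm{depth}_e \cdot \ell_e}
{\sum_e \ell_e},$$

which equals the plain mean of per-base depth when per-base records are
supplied. Within each strain, coverage is normalized by the median over
*all* genes (zeros included; the simplest reading of within-strain median
normalization) and classified: **missing** iff raw coverage is exactly 0;
**low** iff positive but normalized coverage < 0.25 (strictly — exactly
0.25 is adequate); **adequate** otherwise. Merging is per gene only:
intervals shared between overlapping genes are counted for both, since a
per-gene denominator is what the coverage statistic needs. Depth records
are expected to already exclude unmapped, duplicate and QC-fail reads;
that filtering belongs to the depth producer.

# Off genes

A gene is **off** in a strain when every sample of that strain — all
treatments, all replicates — has a count of exactly zero. The exact-zero
criterion is conservative by construction: a single estimated read
disqualifies the strain, which keeps low-expression genes from being
misclassified as absent. The off-gene *set* additionally requires evidence
of expression elsewhere: significant pairwise strain DE (Wald adjusted
p < 0.1, all strain pairs on control samples, no fold-change threshold) and
a zero-strain set that is a *proper* subset of the strains. Genes zero
everywhere can never be pairwise-DE and are excluded by construction.

Each off (gene, strain) is then resolved against that strain's DNA coverage
class: adequate → `truly_off`; zero raw coverage → `missing_genome`
(putatively absent from the strain's genome); low →
`uncertain_low_coverage`. The three categories partition every off call.
Finally, off genes are flagged **RNAi-responsive** when they carry a
significant RNAi contrast call in at least one strain outside their silent
set.

# The synthetic-data generator

`sim_config()` defaults encode the emulated study design: 5 strains × 3
treatments (control, *par-1* RNAi, *pos-1* RNAi) × 3 biological replicates;
2,000 genes (a desk-scale stand-in for a genome-wide ~19k); 34% of genes
strain-DE, 5% with interactions, 2.6% off (always a subset of the strain-DE
genes, with silent-strain counts skewed toward one); 1.5% of genes missing
and 2.5% low-coverage in one strain; planted effects of |log2 FC| = 2.
Values the emulated design does not pin down are documented conventions
chosen once: baseline log2 means N(6, 2²) (median ≈ 64 counts), NB
dispersion α = 0.05 (a typical bulk RNA-seq magnitude for well-replicated
experiments; the generator accepts any scalar, vector or sampling rule),
library-size factors log-uniform over a 3-fold range, and a floor of 200 on
the baseline mean of off genes so that presence/absence is identifiable at
desk scale. A `frac_treatment_de` fraction (default 10%) of genes receive
treatment main effects so within-strain contrasts have planted signal.

Counts are integer NB draws, which makes the NB likelihood exact for
testing (real pseudoalignment estimates are fractional). Off genes are
structural zeros — expected count exactly 0 — matching the exact-zero
calling criterion. Coverage tracks place each gene's merged exons on one
synthetic chromosome; missing genes get depth exactly 0, low genes are
scaled to a normalized coverage in (0.02, 0.18), comfortably inside the
(0, 0.25) low band, and multiplicative lognormal noise (sd 0.15 by default,
0 for exact round-trips) perturbs adequate genes while leaving them above
the 0.25 line with high probability.

What the generator does *not* emulate: read-level artifacts (alignment,
positional bias), fractional estimated counts, correlated gene-gene
expression, hyperdivergent haplotype structure, and strain-specific
transcriptome sequence. Passing tests therefore demonstrate statistical
correctness of the methods under the stated model, not robustness to every
real-data pathology.

# Validation strategy and problem sizes

The suite favors independent oracles over re-implementation checks: exon
merging against a per-base set union, coverage against per-base means, BH
against a brute-force step-up, the hypergeometric tail against subset
enumeration, the corrected proportion test against `prop.test`, and the
strain LRT against DESeq2 (rank agreement; the dispersion treatments differ
by design). Statistical acceptance runs at sizes chosen to keep the whole
suite in a few minutes on one core while leaving Monte-Carlo error small:
2,000-gene null simulations for type-I calibration (both screens within 3
binomial SEs of the nominal 0.05, with known dispersions so that the test
statistic itself is on trial), ~500 planted strain effects for recovery
(signed bias within ±0.05 log2, MAE < 0.2 — measured on the full additive
fit, which uses all 9 samples carrying each strain's effect), and a
2,000-gene off-gene round-trip with zero coverage noise and 8-fold partner
expression (sensitivity and precision ≥ 0.95).

# Numerical choices and edge cases

* LRT statistics are clamped at 0; full = reduced gives statistic 0 and
  p = 1.
* Dispersion optimization compares the interior optimum against the floor
  and keeps whichever likelihood is higher, so constant-count genes land
  exactly on the floor.
* `norm_cov = 0.25` is adequate (strict `<`); `raw_cov = 0` beats the low
  rule (missing), so the classes are mutually exclusive by construction.
* Coverage intervals with no depth record raise an error naming the gap —
  silent zero-fill would masquerade as "missing genome".
* The continuity correction is clamped at the observed difference so the
  corrected chi-squared is 0, never negative, at near-equal proportions;
  the degenerate pooled proportions 0 and 1 return p = 1.
* Off genes absent from the coverage table are categorized
  `uncertain_low_coverage` and reported, not dropped.

# Known limitations

Dispersion moderation, outlier replacement and Cook's-distance filtering
are intentionally absent, so real-data gene lists will differ from
moderated pipelines. The Wald pseudo-guard makes separation testable but
the resulting standard errors for all-zero cells are approximations. The
hypergeometric universe for overlap statistics is whatever gene universe
the caller supplies; with filtered inputs the choice of universe matters
and is the caller's responsibility.
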