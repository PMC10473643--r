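---
title: "Methods: imputation-based PWAS/TWAS from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputation-based PWAS/TWAS from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

An imputation-based proteome- or transcriptome-wide association study asks,
for each gene $g$: is the *genetically predicted* level of the gene's
protein (or expression) associated with a trait? It needs no cohort that
measures both the omic layer and the trait. Two data sets are combined:

1. a **training cohort** with genotypes and omic measurements, on which a
   sparse linear prediction model of the omic level from cis-window variant
   dosages is fit, and
2. an external **GWAS** of the trait, summarized as per-variant marginal
   effects and standard errors, plus an **LD reference panel** providing
   the dosage covariance $\Gamma$ among the model's variants.

The gene-level association statistic is

$$ z_g \;=\; \sum_{l} w_l \,\frac{\sigma_l}{\sigma_g}\, z_l,
   \qquad \sigma_g^2 = w^\top \Gamma w, $$

where $w_l$ is the model weight of variant $l$ (per-dosage scale),
$z_l = \hat\beta_l/\mathrm{se}(\hat\beta_l)$ the marginal GWAS z-score,
$\sigma_l = \sqrt{\Gamma_{ll}}$, and $\sigma_g$ the standard deviation of
the predicted omic level in the reference panel. Under the null of no
association $z_g$ is approximately standard normal; we report two-sided
normal p-values and control the false discovery rate by Benjamini–Hochberg
within each (omic layer, trait) stratum, at level 0.05 by default.

This is equivalent (up to terms of order $r^2$ in the per-variant
trait correlations) to regressing the trait on the model-predicted omic
value in the GWAS cohort itself — the package's central oracle: on
synthetic data where the LD reference *is* the GWAS cohort, `gene_zscore()`
agrees with the individual-level regression z-score to a Pearson
correlation above 0.99 and a maximal absolute difference well under 0.2
(the acceptance suite re-measures both on a 200-gene cohort of 2,000
samples).

## Why a summary-only statistic can disagree with intuition

$z_g$ is a weighted average of GWAS signals, oriented by the model
weights. Two omic layers of the same gene (protein vs expression) can use
nearly disjoint cis-variant sets with differently signed weights, so the
same GWAS locus can yield significant associations of opposite sign in the
two layers. The concordance module quantifies this: per-gene weight
decompositions, nonzero-weight overlap counts, joint-significance
classification, and layer-wise Spearman correlation of signed
$\log_{10}$ p-values with an exact binomial sign test across tissues.

### The weight-decomposition weighting scheme

For a single gene, after orienting every variant's alleles so all GWAS
effects are positive ($\tilde z_l \ge 0$), we display the weighted average

$$ \mathrm{WA} = \frac{\sum_l \tilde z_l \sigma_l \tilde w_l}
                     {\sum_l \tilde z_l \sigma_l}
             = z_g \cdot \frac{\sigma_g}{\sum_l \tilde z_l \sigma_l}. $$

Weighting by $\tilde z_l \sigma_l$ rather than by $\tilde z_l$ alone is a
deliberate design choice: it makes "WA has the same sign as, and is
proportional to, the predicted effect" an exact algebraic identity under
the $z_g$ formula above, which the test suite asserts for 100% of testable
genes in every simulated run. Plain-$z$ weighting is available via
`weight_decomposition(view, use_sigma = FALSE)`; it preserves the sign
identity only approximately when reference variances differ across
variants.

# Preprocessing

Omic matrices pass through a fixed, logged order:

1. **Rank-based inverse normal transform** per feature,
   $\Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with average ranks for
   ties. The offset is $c = 0.5$ by default (Blom's $3/8$ is offered); the
   choice only shifts extreme quantiles slightly and does not change rank
   order.
2. **Top-k PC scores** (left singular vectors of the centered matrix) and
   **top-k surrogate values**, both unit variance, $k = 10$ by default.
   Surrogate values are computed as the top singular vectors of the
   *covariate-residualized* matrix — a deterministic two-step variant of
   surrogate variable analysis. It serves both stated purposes (outlier
   detection, adjustment for unobserved factors) while being exactly
   reproducible and directly testable: an injected hidden factor is
   recovered with $|r| > 0.9$ in the test suite.
3. **Chi-squared outlier removal**: per sample
   $d = \sum_j s_j^2 \sim \chi^2_k$ over standardized scores; samples with
   upper-tail $p < 0.001$ on *either* the PC scores or the surrogate
   values are removed (removal threshold $d^\ast \approx 29.588$ at
   $k = 10$). Scores are standardized first so the reference distribution
   is correct; zero-variance score columns contribute nothing.
4. **Recompute scores on the retained samples**, then **residualize** each
   feature on covariates plus surrogate values by ordinary least squares.
   Residuals are orthogonal to every design column to $10^{-8}$.

Recomputing the scores after outlier removal (step 4) is a choice the
published orderings leave open; both behaviors are supported
(`recompute_scores`), with recomputation the default because the
post-removal factor estimates are what the residualization should use.
The pipeline is deliberately not idempotent in the strict sense — removing
outliers changes the score distribution — but re-running it on the
retained samples removes essentially no further samples, which the test
suite checks.

# Prediction models

For each gene the candidate predictors are dosages of variants inside the
cis window (gene body ± 1 Mb, closed 1-based interval, clamped at the
chromosome start; strand does not alter the window), **restricted to
variants present in the harmonized GWAS** so every trained weight is
usable downstream. The fit is an elastic net with mixing
$\alpha = 0.5$ and 10-fold cross-validation, both configurable; fold
assignment is seeded and recorded.

Numerical/selection choices worth stating:

* **Penalty strength** defaults to the one-standard-error rule
  (`lambda_choice = "1se"`): the strongest penalty whose CV error is
  within one SE of the minimum. This yields genuinely *trivial* models
  (all weights zero) for features without cis signal — matching the
  workflow in which a substantial fraction of features get no model — and
  recovers cis heritability as well as the CV-minimum rule in our
  simulations (mean out-of-fold $r^2 \approx 0.23$–0.29 at true
  $h^2_{cis} = 0.3$, $n = 900$). `"min"` is available.
* **Dosage scale**: predictors enter on the raw 0–2 dosage scale (glmnet
  standardizes internally and back-transforms), so weights transfer
  directly into the summary-statistic formula with the counted (alt)
  allele as effect allele.
* **Performance**: `cv_r2` is the squared correlation between out-of-fold
  predictions and the response; `cv_pval` is the one-sided (positive)
  correlation test, since predictive skill is directional. BH q-values
  over all non-trivial models per layer flag "significantly predictable"
  features at FDR 0.05; externally imported model sets are filtered at
  predictive $p < 0.05$ (strict inequality).
* A duplicated predictor column changes the fit slightly (duplication
  halves the effective ridge penalty along that direction), so exact
  invariance is not asserted; near-invariance of the prediction function
  is, together with exact agreement between the training wrapper and a
  direct `cv.glmnet` oracle on the same design and folds.

# Allele harmonization

GWAS records are matched to model variants by chrom:pos:sorted-allele-pair
(robust to id scheme differences). Swapped effect/other alleles negate
$\beta$ and $z$; allele-mismatched records are dropped with a count;
model variants absent from the GWAS are flagged and excluded from training
and from the $z_g$ sum. Harmonization is an involution on allele swaps.
Strand-ambiguous palindromic (A/T, C/G) variants are kept by default —
correct for synthetic and strand-aligned data — with a `drop_palindromic`
flag for real-data use, where strand errors are undetectable for these
variants.

# The synthetic cohort generator

The generator is first-class, tested code; it produces every input the
pipeline consumes with the statistical structure the analysis assumes.

* **Genotypes.** One LD block per gene, no cross-gene LD (matching the
  per-gene cis analysis and keeping the individual-level oracle exact).
  Within a block, two latent Gaussian AR(1) haplotype chains per sample
  are thresholded at MAF quantiles into allele indicators whose sum is the
  dosage. The latent adjacent correlation is *calibrated* (bivariate
  normal tail probability by Gauss–Legendre quadrature, inverted with
  `uniroot`) so the realized **dosage** correlation of adjacent variants
  equals `ld_decay`; naive use of `ld_decay` as the latent correlation
  would understate dosage LD through threshold attenuation (latent 0.9 at
  MAF 0.3 gives dosage $r \approx 0.77$). When adjacent MAFs are too far
  apart for the target to be attainable, the latent correlation caps at
  its maximum. Per-variant MAFs are uniform on `maf_range`; positions are
  uniform in each gene's ±1 Mb cis window.
* **Omics.** Each feature is
  $y = X b + C\gamma + H\delta + \varepsilon$ with empirical variance
  shares `cis_h2` (genetic), `covariate_var` (known covariates, default
  0.10), `hidden_var` (shared hidden factors, default 0.15), and noise
  summing to 1. Causal sets are shared across layers; protein vs
  expression effect vectors are drawn with correlation
  `cross_layer_effect_corr`.
* **Trait and GWAS.** An independent GWAS cohort is drawn from the same
  law; the trait is $T = \sum_g \alpha_g m_g + \varepsilon$ with $m_g$ the
  gene's genetic omic component on the mediating (protein) layer,
  standardized to variance 1 so $\alpha_g^2\, h^2_{cis}$ is the trait
  variance share a gene mediates. Null genes have $\alpha_g = 0$ exactly.
  Marginal per-variant OLS effects, standard errors and explicit
  effect/other alleles form the GWAS summary table. Only $z = \beta/se$
  enters the downstream statistic, so the unstated trait scaling of real
  GWAS consortia is immaterial; we standardize for interpretability.

**Defaults as study conditions.** `n_train_samples = 900` mirrors the
post-QC proteomics cohort scale; `n_gwas_samples = 20,000` is a desk-scale
stand-in for a consortium GWAS (the power analysis uses 50,000);
`cis_h2 = 0.3` sits in the middle of reported predictive $r^2$ ranges;
`maf_range = (0.05, 0.5)` reflects the MAF > 0.05 filter;
`mediation_effect_sd = 0.1` with half the genes null gives per-gene
mediated variance shares of a few tenths of a percent, the regime where
summary-based association is the method of interest.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: realistic haplotype structure and long-range
LD, cross-gene LD and pleiotropy, imputation error, related individuals,
ancestry mismatch between training cohort and GWAS, assay-specific
measurement error, and missing gene–tissue pairs. The concordance module's
pairwise-complete handling of missing genes is exercised only lightly.

# Problem sizes and determinism

Every simulation consumed by the test and acceptance suites is a
deterministic function of one integer seed (layout, cohorts, omics, and
trait use separated seed streams derived from it). The acceptance runs
use: 200 genes × 30 variants at $n = 2{,}000$ for the summary/individual
oracle; 20 replicates × 30 genes for null calibration (600 gene–trait
pairs); 25 genes at $n_{gwas} = 50{,}000$ for power; 100 genes at
$n = 900$ for heritability recovery; and two 10-tissue cohorts of 60
genes for concordance recovery. These sizes were chosen once as the
smallest cohorts at which the Monte-Carlo tolerances quoted above are
comfortably inside sampling noise.

# Known limitations

* The chi-squared outlier test assumes approximately multivariate normal
  scores; on heavy-tailed real omic data it removes more samples than the
  nominal level suggests.
* The summary statistic inherits SPrediXcan-class assumptions: marginal
  GWAS effects from an approximately linear model, an LD reference that
  matches the GWAS population, and weights estimated independently of the
  GWAS cohort.
* `cv_r2` is a downward-biased estimate of cis heritability (estimation
  error in the weights); the acceptance band for recovery is accordingly
  one-sided around the truth.
* No conditional/joint multi-gene analysis, colocalization, or causal
  (Mendelian-randomization-style) interpretation is attempted.
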