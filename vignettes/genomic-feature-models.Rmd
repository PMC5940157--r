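---
title: "Genomic feature models for inbred panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic feature models for inbred panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gfblup` analyses quantitative traits measured with replication on panels
of fully inbred lines — the design popularised by the Drosophila Genetic
Reference Panel (DGRP), where every line is homozygous genome-wide and a
trait can be measured on many individuals per line. The package covers
the full chain: SNP filtering and annotation, broad-sense heritability
from the replicated records, genomic prediction with GBLUP and its
feature-set extension GFBLUP, a cross-validated scan over GO terms,
gene-level partitioning of a term's genomic variance (CVAT) with a
circular-permutation null, and a marginal per-SNP scan as the
single-marker baseline. A synthetic-data generator reproduces the
statistical structure of this design so that every stage is testable
without any external download.

# Models

## Line model and broad-sense heritability

Replicated records are modelled as

$$Y = \mu + d + b + p + L + E,$$

with fixed nuisance effects for measurement day ($d$), block ($b$) and
plate ($p$), a random line effect $L \sim N(0, \sigma^2_L)$ and residual
$E \sim N(0, \sigma^2_E)$. `fit_line_model()` estimates the components by
REML through lme4. Broad-sense heritability at the individual level is
$H^2 = \sigma^2_L/(\sigma^2_L + \sigma^2_E)$; at the line-mean level,
with $\bar n$ replicates per line, the residual averages out and
$H^2_{\bar y} = \sigma^2_L/(\sigma^2_L + \sigma^2_E/\bar n)$. With an
individual-level $H^2$ of 0.40 and $\bar n = 23$ this gives 0.94 — line
means are almost fully repeatable even when individuals are noisy, which
is why line-mean prediction is the natural target in this design.

## Genomic relationship matrices

Allele counts of homozygous lines are coded 0/2 (copies of the minor
allele). Column $i$ of the centered/scaled matrix $W$ is
$w_i = (a_i - 2p_i)/\sqrt{2p_i(1-p_i)}$ with $p_i$ the within-panel
frequency of the counted allele, and $G = WW'/m$ over $m$ SNPs. Under
this coding the expected diagonal of $G$ is 2, reflecting the doubled
additive relationship of fully inbred lines; variance components
estimated against $G$ are therefore on the per-unit-of-$G$ scale, and
tests that compare them with simulated variances map them through the
centered trace of $G$ (the model-implied sample variance of the line
effects). A genomic feature splits the columns into a feature set $f$
and remainder $r$ with $G_f = W_f W_f'/m_f$, $G_r = W_r W_r'/m_r$; the
identity $m_f G_f + m_r G_r = mG$ is exact and is asserted in the tests
at $10^{-10}$.

Scaling uses the panel's own allele frequencies, and $G$ is not bent or
regularised at construction; numerical safety is handled in the solver by
bounding variance components away from zero.

## GBLUP, GFBLUP and AI-REML

Phenotypes are first adjusted for fixed effects:
$\tilde y_{ij} = \hat g_i + \hat e_{ij} = (y - X\hat b)_{ij}$, an exact
identity of the BLUP decomposition that the tests assert at $10^{-8}$.
The adjustment is computed once on the full data before any resampling;
the mild train/test leakage this implies is deliberate — it preserves the
replicate structure that makes the adjusted records exchangeable across
cross-validation splits, and it matches the procedure the package is
designed to reproduce.

The genomic models on adjusted records are
$\tilde y = Zg + e$ with $g \sim N(0, G\sigma^2_g)$ (GBLUP) or
$g = g_f + g_r$ with independent $N(0, G_f\sigma^2_f)$ and
$N(0, G_r\sigma^2_r)$ components (GFBLUP). Estimation is
average-information REML written against the line-level reduction: with
one incidence $Z$ and $H = \sum_k \sigma^2_k G_k$,

$$V^{-1} = \sigma_e^{-2}\left(I - ZHS^{-1}Z'\right), \qquad
  S = \sigma_e^2 I_q + (Z'Z)H,$$

a push-through identity that holds for singular $H$ (feature GRMs are
usually rank-deficient), so every iteration costs $O(q^3)$ in the number
of lines rather than $O(n^3)$ in records. Numerical policy: components
start at $\mathrm{var}(y)/(\text{number of components})$; an AI step that
would lower the restricted likelihood is halved up to 10 times before an
EM-type multiplicative update
$\sigma^2_k \leftarrow \sigma^2_k \, (y'PV_kPy)/\mathrm{tr}(PV_k)$ is
taken instead; proposals below $10^{-8}\,\mathrm{var}(y)$ are clamped to
that bound; convergence requires both the restricted log-likelihood change
and the largest relative parameter change to fall below $10^{-6}$, with a
cap of 200 iterations. The restricted likelihood of accepted iterations
is non-decreasing, and on small problems the converged likelihood agrees
with a dense numeric REML oracle to $10^{-6}$.

Fixed effects use reference-level indicator coding with an explicit
intercept; the intercept reported for prediction is the GLS solution
under the converged covariance. The identity-kinship special case of the
solver reproduces the lme4 line model on the same data, which the test
suite uses as a genuinely independent cross-check of the two routes.

## Prediction and cross-validation

Hold-out genomic values use the cross-block rows of the GRM:

$$\hat g_v = (G_{v,t}\hat\sigma^2_g)\,Z_t'
  \left[Z_t G_{t,t} Z_t'\hat\sigma^2_g + I\hat\sigma^2_e\right]^{-1}
  (\tilde y_t - \hat\mu_t),$$

and the two-component analogue replaces $G\hat\sigma^2_g$ by
$G_f\hat\sigma^2_f + G_r\hat\sigma^2_r$ in both blocks. Cross-validation
masks whole lines — the only unit under which predicting an unseen line
is meaningful — with a validation fraction of 0.10 and 50 repeats by
default. Variance components are re-estimated on each training portion.
Predictive ability (PA) is the Pearson correlation between the validation
lines' mean adjusted phenotype and $\hat g_v$; observed values are line
means because the genomic value is a line-level quantity. Splits are
drawn once from the scheme's seed and shared by every model compared in
a scan (common random numbers), which removes split-to-split noise from
the model contrast. The GFBLUP-vs-GBLUP comparison is a one-sided Welch
unequal-variance t-test (the scientific question is whether the feature
*increases* predictive ability), with Benjamini–Hochberg FDR control
across terms. Because the maximum attainable squared correlation with
line means is $H^2_{\bar y}$, a model with mean predictive ability PA
accounts for $PA^2/H^2_{\bar y}$ of the line-mean heritability
(`summarize_percent_heritability()`).

## CVAT: gene-level partitioning of a term's genomic variance

For a predictive GO term, SNP effects are recovered from the term's
feature BLUP by the minimum-norm back-solve
$\hat s = W_{GO}'(W_{GO}W_{GO}')^{+}\hat g_{GO}$ (eigen-pseudo-inverse,
relative cutoff $10^{-10}$; $\hat g_{GO}$ always lies in the column space
of $W_{GO}$ because $G_f \mathbf{1} = 0$). A gene's genomic value is
$\hat g_{gene} = \sum_{i \in gene} w_i \hat s_i$ and its statistic is the
covariance $T = \hat g_{GO}\cdot\hat g_{gene}$, which decomposes exactly
into per-SNP contributions $T = \sum_{i\in gene} o_i$ with
$o_i = \hat s_i\,(w_i'\hat g_{GO})$.

The empirical null treats the genome as circular: the contribution vector
is rotated along the term's genome-ordered SNPs by a random offset in
$\{1,\dots,m-1\}$, so gene boundaries stay fixed while each position
receives the contribution of another SNP, preserving the serial
correlation of the effects while decoupling them from gene membership.
Each permuted $T^*$ is thus the gene's share of the term's genomic
variance under a random relocation — exactly the comparison "is this gene
larger than a random same-sized stretch of the term". Two designs that
look equivalent on paper are not calibrated and were rejected after
measurement: keeping the observed $\hat g_{GO}$ and rotating only the
effects destroys the effect-alignment present at every position of the
observed statistic (rejecting essentially every gene under an
exchangeable null), and recomputing both sides from rotated effects still
leaves a $W'W$-aligned correlation in the back-solved effects
(≈25% null rejection). Rotating the contributions attains the nominal
level (measured 3% at nominal 5% under the null conditions below).

The one-tailed p-value uses add-one smoothing,
$p = (1 + \#\{T^* \ge T\})/(1 + n_{perm})$, with ties counting against
significance, so $p = 0$ is impossible; when
$n_{perm} \ge m - 1$ the $m-1$ distinct rotations are enumerated
exhaustively instead of sampled. The rotation is applied over the GO
term's SNPs, where the back-solved effect vector is defined; a
genome-wide rotation would require genome-wide effects, which belong to
the whole-genome variant of the test, not implemented here. Genes are
ranked by ascending p, ties broken by descending $T$, then gene id.
Default 10,000 permutations.

## Marginal scan

The single-marker baseline regresses the full-data GBLUP $\hat g$ on each
SNP's allele count and t-tests the slope ($n-2$ df), vectorised through
$t = r\sqrt{n-2}/\sqrt{1-r^2}$. No genome-wide threshold being canonical
for such scans, the output records Bonferroni $\alpha/m$ so users can
re-threshold; monomorphic SNPs are skipped with a warning.

# The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults emulate the
inbred-panel design: 200 homozygous lines, 5,000 biallelic SNPs spread
over the six chromosome arms (2L, 2R, 3L, 3R, 4, X, with arm 4 small),
MAF drawn uniformly from [0.05, 0.5] (the real panel's spectrum is not
published with the design, so a flat spectrum over the post-filter range
is used), 100 non-overlapping genes covering ~70% of SNPs with intergenic
gaps, 10 GO terms of Poisson(6) genes, 23 replicate records per line,
and day/block/plate levels (6/4/8) with effects of SD 0.25 phenotype
units.

The architecture sets variance fractions $\sigma^2_f$ (feature term),
$\sigma^2_r$ (remainder) and $\sigma^2_e$ (residual) summing to 1. By
default every SNP of a component is causal with i.i.d. Gaussian effects —
the assumption under which GBLUP/GFBLUP variance estimation is correctly
specified, so parameter-recovery tests measure the estimator rather than
model mismatch. Effects (and residuals) are rescaled so the realized
in-sample component variances hit the configured fractions exactly,
removing Monte-Carlo slack from recovery tests. Concentrated
architectures are opt-in: `n_causal_f`/`n_causal_r` restrict the causal
sets, and `causal_gene = TRUE` places all feature causals in the term's
largest gene — the condition under which gene ranking has a ground truth.
Genotypes are independent across SNPs by default (the simplest null for
the circular permutation); an optional block-LD mode copies founder
haplotype blocks among lines to produce serially correlated SNPs.

What the generator does *not* emulate: linkage disequilibrium of real
chromosomes (beyond the optional block mode), population structure,
Wolbachia infection or inversion polymorphisms of the real panel,
dominance or epistasis, and non-Gaussian residuals. Passing tests
therefore demonstrate correctness of the machinery under the stated
generative model, not robustness to these real-data features.

# Test and verification scales

Problem sizes were chosen once as the smallest scales at which each
property is informative: oracle-equivalence and algebraic identities run
on 5–9-line toys; parameter recovery runs 20 seeds at the full study
scale (200 lines × 23 replicates, 5,000 SNPs, architecture
0.30/0.20/0.50, plus a 0.40-heritability line architecture on the same
panels), comparing seed-mean estimates with truth at 3 Monte-Carlo
standard errors; the power condition (GFBLUP beats GBLUP) uses 20 seeds
of 100 lines × 6 replicates, 1,000 SNPs with $\sigma^2_f = 0.3$ on one
GO term; gene ranking and the marginal contrast use 20 seeds of 2,000
SNPs with $\sigma^2_f = 0.2$ in a single gene (weak per-SNP effects);
null calibration uses 20 seeds of 80 lines, 800 SNPs with effects
uniform genome-wide, 10 CV repeats and 999 permutations.

# Known limitations

- Standard errors of variance components and of $H^2$ are not computed;
  the REML information matrix is not exposed.
- Only one- and two-component genomic models are supported (no
  multi-feature decompositions, dominance or epistasis kinships).
- The GO scan refits every term independently; terms sharing most of
  their SNPs produce correlated tests, which FDR control across terms
  does not model.
- The adjusted-phenotype step deliberately uses the full data (see
  above); with strong fixed-effect imbalance across CV splits this
  slightly flatters all models equally, not the model contrast.
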