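---
title: "From parenchymal enhancement to pathways and survival: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From parenchymal enhancement to pathways and survival: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpepath)
```

## The analysis in one paragraph

Contralateral parenchymal enhancement (CPE) is a dimensionless DCE-MRI
statistic: the mean of the top-10% voxelwise delayed enhancement ratios
(S~late~ − S~early~)/S~early~ inside the fibroglandular tissue of the breast
opposite a tumor. `cpepath` asks whether CPE carries a transcriptomic
signature: genes are ranked by the strength of their association with CPE,
gene sets are scored against that ranking by permutation GSEA, the
best-supported set is condensed into a one-number pathway activity score
(PC1 of the z-scaled member expression), and that score — together with CPE
itself — enters multivariable Cox proportional-hazards models adjusted for
age, tumor size, grade, and an adjuvant-systemic-therapy × nodal-status
construct covariate. A second cohort, possibly measured on a different
platform, is brought onto the reference expression scale by per-gene
mean/variance matching before the reference PC1 loadings are applied.

## CPE computation

`enhancement_ratio_map()` evaluates (S~late~ − S~early~)/S~early~ per voxel,
by default between the first post-contrast series (90 s) and the fourth
(360 s); both times are configurable and matched against the study's
acquisition times. Voxels whose early signal falls below a positivity floor
(10^−6^ of the early volume's maximum) cannot support a meaningful ratio;
they are excluded and counted rather than clamped, so near-zero denominators
cannot dominate the top decile. `compute_cpe()` sorts the valid in-mask
ratios in descending order and averages the top `ceiling(0.10 * m)` voxels
(minimum one voxel; the rounding rule is a package choice, as is boundary
tie-breaking by voxel linear index — both make the statistic deterministic).
Because the ratio cancels any global intensity gain, CPE is invariant to
volume rescaling; this is tested directly. Registration, bias correction and
fibroglandular segmentation are upstream inputs, not computations this
package performs.

## Gene ranking

Counts are transformed to log2 counts-per-million with pseudocount 0.5 (the
denominator carries twice the pseudocount so a gene holding an entire
library stays consistent). Each gene is then regressed on standardized CPE
by ordinary least squares and summarized by t = slope/se. An optional
empirical-Bayes moderation (prior df 4, prior variance the 10%-trimmed mean
of residual variances) shrinks unstable variance estimates at small n; the
default is the plain OLS t, since the downstream enrichment depends on the
ranking contract rather than on a particular shrinkage recipe, and both
modes are exposed. Perfect fits are capped at the largest representable
statistic; zero-variance genes get t = 0 and a flag. Ties in the ranking
break by gene id so output files are byte-stable.

## Gene set enrichment

`enrichment_score()` walks the ranked list: a member at rank i adds
|t~i~|^p^ normalized by the member total, a non-member subtracts 1/(N − k).
The ES is the walk value of maximal absolute excursion; `max_es_at` is its
1-based position, defined as the *first* position whose |excursion| reaches
the maximum within a 10^−9^ tolerance. The tolerance matters: in the
unweighted walk (p = 0) exact ties are common, and without it the reported
position would depend on floating-point accumulation order. The leading-edge
fraction counts members at or before the extremum (at or after, for negative
ES) over the member count.

The default weight exponent is p = 1 (the standard weighted statistic);
p = 0 is available and is what the small exact oracles use. The default
permutation scheme permutes the CPE vector and recomputes the entire ranking
per permutation, which preserves gene–gene correlation and matches the
regression-based ranking design; label permutation on the fixed ranking is
offered as a fast fallback and is what the exhaustive-enumeration check
exercises. NES divides ES by the mean same-sign null ES of the same set;
the FDR q follows the sign-stratified convention (pooled null tail fraction
over observed tail fraction, clipped to [0, 1]). Sets with no same-sign null
values get an undefined NES and are flagged rather than silently dropped.
Size filters default to [5, 500] members after intersection with the
measured universe.

## Pathway selection

Among sets with FDR below the threshold (default 0.25, the conventional
discovery cut-off for GSEA), the pipeline selects the set with the largest
**|NES|**, breaking ties by higher leading-edge fraction and then name. The
absolute value is deliberate: the scientific signal of interest here is
*negative* association (higher CPE, lower pathway expression), which puts
the set at the bottom of the ranking with a negative NES; a signed maximum
could never select it. `select_by = "nes"` restores the signed rule for
analyses that only consider positively enriched sets. When no set passes,
the survival stages are skipped and the report says so explicitly.

## Pathway PCA and cross-cohort translation

`fit_pathway_pca()` z-scales each member gene by its training mean and SD
(n − 1 denominator) and eigendecomposes the sample covariance. PC1's sign is
arbitrary, so it is anchored: when a covariate (here CPE) is supplied, the
loadings are flipped to make cor(PC1, covariate) ≤ 0 — encoding the
discovered direction (high CPE, low pathway expression) as a convention —
otherwise the largest-magnitude loading is made positive. Constant genes
cannot be scaled and are dropped with a warning.

`translate_cohort()` rescales each shared gene of a second cohort to the
reference mean and variance, which is what makes microarray-scale data
projectable with RNA-seq-derived loadings; the transform is idempotent and
is verified to reproduce the reference moments to 10^−10^. Only the model's
genes are translated (translating the full transcriptome would change
nothing for the projection). Model genes missing from the target are dropped
and the remaining loadings renormalized to unit norm; zero-imputation was
rejected because it biases scores toward zero. Genes constant in the target
are pinned at the reference mean and flagged.

## Survival models

`cox_fit()` maximizes the Breslow partial likelihood by Newton–Raphson with
step-halving (the objective never decreases; convergence at max |score| <
10^−6^ or objective change < 10^−9^). With `penalize = "firth"` the
objective gains half the log-determinant of the observed information — the
Jeffreys-prior penalty — whose maximizer stays finite under monotone
likelihood, the situation that arises with few events or separated
covariates. The penalty gradient is computed by central finite differences
of the analytic information's log-determinant (step 10^−5^); the Newton
direction uses the unpenalized information. This avoids the third-derivative
trace expression while keeping the objective itself exact; the cost is a few
extra information evaluations per iteration, negligible at the model sizes
involved. Correctness is pinned by two independent checks: the unpenalized
fit must match `survival::coxph` to 10^−5^, and the penalized fit must agree
with the unpenalized one to 0.02 at n = 1000 where the penalty is
asymptotically irrelevant.

Unpenalized fits whose coefficients pass |β| = 15 while the likelihood still
climbs are flagged monotone and not reported as converged. Wald intervals
are the default; profile penalized-likelihood intervals (bisection on the
likelihood-ratio boundary, inner Newton re-maximization of the other
coefficients) are available, and are the better choice near separation. A
warning is emitted below 5 events per parameter rather than refusing to fit.

The clinical design encodes grade as two indicators against grade 1 and
combines AST with nodal status into a single four-level construct
(reference: no AST, node-negative), because the two variables are strongly
correlated and separate terms would be near-collinear. CPE and PC1 enter
standardized, so hazard ratios are per SD. Missing values are handled by
complete-case exclusion at table construction — no imputation.

## The synthetic cohort generator

The generator exists so every stage can be tested against known truth; its
defaults are the study conditions the pipeline targets, not tuning knobs.

* **Imaging.** 226 subjects by default; five series (pre + four
  post-contrast, 90 s apart) of 32³ voxels. Fibroglandular voxels follow
  S(t) = S0·(1 + A~v~·f(t)) with a linear uptake to the first post-contrast
  timepoint and a persistent linear slope thereafter — only the early and
  late values matter for CPE, so the curve between them is free and kept
  simple. Per-voxel amplitudes are drawn uniformly and rescaled so that the
  top-decile mean of the implied enhancement ratios equals the requested
  CPE exactly; a zero target sets the late slope to zero so the statistic
  is exactly 0. Fat enhances negligibly (A = 0.01), air carries a small
  positive baseline, and baselines are log-normal around tissue-typical T1
  intensities. No motion, coil bias, or anatomy is emulated — passing tests
  says nothing about segmentation or registration quality on real data.
* **Fast mode** skips volume synthesis and draws CPE from
  0.1 + 0.9·Beta(2, 3), spanning ~0.1–1.0 with median near 0.44 — matching
  the observed median and range of the statistic in the cohort this design
  emulates. The distribution is a stand-in, not an estimate; nothing
  downstream depends on its exact shape.
* **Expression.** Negative-binomial counts; gene baselines log-normal
  (log-mean log 50, sd 1.5), gene-wise dispersions log-normal around a
  median of 0.15, library sizes log-normal (sd 0.2). Planted genes add
  `gene_effect`·CPE~z~ (default −0.5) plus a shared latent factor
  (sd 0.3) to their log-mean, making the pathway score correlated with —
  but not collinear to — CPE, so the joint survival model remains
  identifiable. Background genes are independent of CPE, and background
  gene *sets* are drawn from background genes only: they are true
  negatives, which is what makes "the planted set wins" a meaningful
  recovery criterion. (Sets contaminated with planted genes genuinely carry
  signal under response permutation and would not be false positives.)
* **Survival.** Weibull proportional hazards (shape 1.2, scale 400 months)
  with default log-hazards age 0.04, size 0.015, grade 0.2/0.5, CPE −0.5
  per SD and pathway factor +0.3 per SD; exponential censoring whose rate
  is solved numerically so the expected censoring fraction hits the target
  (default 0.9 — the few-events regime that motivates Firth penalization;
  statistical tests that need more events set the rate they state).

Generators are deterministic given their seeds; cohort files round-trip
through the package's own TSV/CSV/GMT/JSON readers.

## Problem sizes used by the checks

The test suite and the acceptance script run at sizes chosen to make the
statistical properties measurable while keeping a full run in minutes on
one core: CPE oracle equivalence on 100 random 32³ volumes; 1000 random
walk-oracle instances at N ≤ 50; exhaustive enumeration of all C(20,3) =
1140 subsets against a 2000-draw sampled null; planted-pathway recovery on
20 cohorts of 200 subjects × 2000 genes × 50 sets at 200 response
permutations; Firth calibration over 200 replicates at n = 300; Fisher-z
coverage over 2000 replicates at n = 200. The acceptance script reports the
quantities these runs compute — recovery error, NES/FDR/leading edge of the
planted set, PC1 variance explained and CPE correlation, per-SD hazard
ratios in discovery and validation, Cox bias and coverage.

## Known limitations

* The enhancement model is kinetic-free by design; the package cannot be
  used to study uptake-curve shape.
* The response-permutation null re-ranks all genes per permutation; at
  MSigDB scale (thousands of sets) the gene-permutation fallback or fewer
  permutations trade exactness for speed.
* The empirical-Bayes moderation is a simple shrinkage toward a trimmed
  mean, not a full mean–variance trend fit.
* Firth profile intervals use repeated inner maximizations and are the slow
  path; Wald intervals remain the default.
* The generator's clinical covariates are mutually independent apart from
  the AST–nodal coupling; real cohorts are messier.
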