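# cpepath

Radiogenomic analysis linking **contralateral parenchymal enhancement
(CPE)** on breast DCE-MRI to tumor gene-expression pathways and survival.

In unilateral ER+/HER2− breast cancer, the enhancement of the *healthy*
contralateral parenchyma is prognostic, but the tumor biology behind it is
an open question. `cpepath` implements the full analysis chain a
radiogenomics group needs to probe that question: compute the imaging
statistic, find gene sets whose tumor expression tracks it, condense the
best-supported set into a pathway activity score, and ask whether that score
stratifies survival — in the discovery cohort and in an independent cohort
measured on a different expression platform. A synthetic-cohort generator
with complete ground truth backs every stage with recovery tests.

## The statistics at the core

* **CPE** — with registered pre/post-contrast volumes and a fibroglandular
  mask, the voxelwise delayed enhancement ratio is
  (S_late − S_early)/S_early (early = 90 s, late = 360 s post-contrast by
  default); CPE is the mean of the top 10% of in-mask ratios. Dimensionless
  and invariant to global intensity scaling.
* **Gene ranking** — per-gene OLS regression of log₂-CPM expression on
  standardized CPE, summarized by t = slope/se (optional empirical-Bayes
  variance moderation).
* **GSEA** — weighted running-sum enrichment score over the ranked list
  (members add |t|^p normalized, non-members subtract 1/(N−k)); NES by
  same-sign null normalization, permutation p, sign-stratified FDR q,
  extremum position ("Max ES at") and leading-edge fraction. The default
  null permutes CPE and re-ranks all genes.
* **Pathway PC1** — first principal component of the z-scaled member-gene
  expression, sign-anchored to correlate negatively with CPE; cross-cohort
  use via per-gene mean/variance translation, then projection with the
  reference loadings.
* **Firth Cox** — Breslow partial likelihood, optionally penalized by
  ½·log det I(β) (Jeffreys prior), which keeps estimates finite when events
  are few or a covariate separates; hazard ratios per SD for CPE and PC1,
  adjusted for age, size, grade and an AST × nodal-status construct
  covariate.

## Worked example

Generate a synthetic discovery cohort (200 subjects, 1000 genes, a planted
30-gene set whose expression *decreases* with CPE, heavy censoring) and run
the discovery pipeline:

```r
library(cpepath)

cfg <- synth_config(n_subjects = 200, n_genes = 1000, planted_set_size = 30,
                    n_gene_sets = 20, gene_effect = -0.5,
                    censoring_rate = 0.75, seed = 42)
cohort <- gen_cohort(cfg, mode = "fast")
report <- run_discovery(cohort$counts, cohort$clinical, cohort$cpe,
                        cohort$collection, n_perm = 200, seed = 42)
report
#> run_report
#>   selected set: PLANTED_PATHWAY (NES -1.95, FDR 0.002, LE 100%)
#>   PC1: 62% variance explained, cor with CPE -0.841
#>   model cpe_only: cpe HR 0.43 (0.31, 0.61), p = 0.000
#>   model pc1_only: pc1 HR 2.00 (1.47, 2.72), p = 0.000
#>   model both: cpe HR 0.50 (0.30, 0.84), p = 0.009
#>   model both: pc1 HR 1.19 (0.73, 1.94), p = 0.486
```

Reading the output: the planted set is recovered as the top pathway (largest
|NES|, FDR well under the 0.25 discovery threshold, every member in the
leading edge). Its PC1 score is anchored to correlate negatively with CPE.
In the adjusted Firth Cox models, higher CPE is protective (HR 0.43 per SD;
the generator planted log-hazard −0.5) and higher pathway expression is
adverse (HR 2.00 per SD — the planted direct effect plus the share of the
CPE effect it absorbs); jointly, the two attenuate each other, as collinear
prognostic signals should.

The imaging arm works the same way from volumes:

```r
g <- gen_dce_study(cfg, target_cpe = 0.45, subject_seed = 1)
cpe_from_study(g$study, g$masks)
#> CPE = 0.4500 (top 10% of 1568 valid voxels: 157 used, 0 excluded)
```

Real data enter through `read_dce_study()`/`read_tissue_masks()` (NIfTI),
`read_expression_tsv()`, `read_clinical_csv()` and `read_gmt()`; validation
cohorts go through `translate_cohort()`, `project_pathway()` or the
`run_validation()` wrapper.

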