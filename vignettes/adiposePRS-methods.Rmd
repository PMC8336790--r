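---
title: "Methods: unweighted adiposity PRS, risk-set filtering and the synthetic cohort"
author: "adiposePRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unweighted adiposity PRS, risk-set filtering and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-cohort generator does and
does not emulate, and the numerical and design choices made where more
than one convention exists.

## 1. The analysis in brief

The pipeline asks whether polygenic scores built from published
anthropometric-trait variants (BMI, WC adjusted for BMI, WHR adjusted for
BMI, BF%) predict regional adiposity phenotypes (BF%, subcutaneous and
visceral adipose tissue volume, and their ratio VSR = VAT/SAT) in a
cohort with imputed genotype dosages. The stages are: variant QC →
internal per-variant replication screen → risk-set construction under
three filtering approaches → unweighted PRS → covariate-adjusted
association models → Ward clustering of per-variant effects.

## 2. Quality control

`applyVariantQc()` retains variants with

| parameter | default | unit/meaning |
|---|---|---|
| `maf_min` | 0.01 | minimum minor allele frequency |
| `call_rate_min` | 0.90 | minimum fraction of non-missing genotypes |
| `hwe_p_min` | 1e-6 | variants with HWE p at or below this are dropped |
| `imp_r2_min` | 0.9 | minimum imputation quality r² |

These are the standard thresholds for imputed array data; all live in
`qcConfig()` together with the analysis constants (`gwas_sig = 5e-8`,
`ld_r2 = 0.1`, `nominal_p = 0.05`, `n_pcs = 10`).

Numerical choices: the HWE test is a 1-df chi-square without continuity
correction, computed on hard calls (fractional dosages rounded to the
nearest integer). At QC sample sizes the 10⁻⁶ threshold is insensitive to
the choice between chi-square and exact tests, and the chi-square is
monotone in the deviation from equilibrium. Monomorphic variants return
p = 1 by convention (they are removed by the MAF filter instead). MAF is
estimated as mean dosage / 2 over non-missing samples, the standard
estimator for imputed data. All four filters are evaluated on the input
state, so the retained set is independent of filter order and the
operation is idempotent.

Sample exclusions (pregnancy, missing/biologically implausible values)
are *input flags*, not recomputed rules: the plausibility rules of a real
cohort are study-specific, so the package treats them as upstream
decisions and simply removes flagged rows, logging the retained count.

## 3. Risk sets and LD pruning

A catalog entry is admitted only if its published p-value is at or below
genome-wide significance (5×10⁻⁸). LD is quantified as the squared
Pearson correlation of dosages (composite LD) computed **in-sample**
rather than from an external reference panel — a deliberate substitution
that keeps the package self-contained and reproducible offline; with
r² ≥ 0.1 as the linkage threshold the two conventions rarely disagree on
pruning decisions, but results are not guaranteed identical to
panel-based pruning.

Pruning is greedy with sentinel prioritization. Entries are ranked by
published p-value (ascending), then study size (descending), then study
year (descending), then variant key; walking down the ranking, an entry
is kept iff its r² with every kept entry is **below** 0.1 (a pair at
exactly the threshold counts as linked). The full tie-break key makes the
output deterministic and invariant to the input order of the catalog. A
pair whose LD is undefined (constant dosage) is treated as unlinked with
a warning rather than silently dropped.

The three approaches: (1) all pruned catalog loci; (2) the subset whose
internal effect for the published effect allele is positive (directional
replication); (3) the approach-2 subset with internal p < 0.05. Filtering
is applied **before** pruning, matching the construction of separate risk
sets per approach. A caveat follows: because removing a sentinel can let
a linked, lower-priority entry survive pruning in a later approach, the
nesting approach 3 ⊆ 2 ⊆ 1 is guaranteed only when linked entries do not
disagree on replication status; in the default simulated architecture
linked variants share their causal signal, so the nesting holds in
practice.

## 4. The internal replication screen

`runInternalGwas()` fits, per variant, OLS of the inverse-normal
phenotype on dosage with age, sex (and BMI for the WHR/WC analyses, plus
optional ancestry PCs) as covariates, with a two-sided Wald t test at
residual degrees of freedom. BMI and WC are analysed at visit 1 (the
larger sample), the remaining traits at visit 2; the visit pairing is
configurable. Missing dosages are mean-imputed per variant, which
preserves n and is standard for imputed data.

This screen stands in for a mixed-model association test with a full
genetic relationship matrix. That replacement is intentional: the screen
is used only as a sign-and-significance filter, the interface
(`GwasResult` tables keyed by variant) leaves room for a drop-in mixed
solver, and the family-structure correction that matters for the headline
PRS models *is* available there (Section 6). p-values come from the t
distribution, not a normal approximation, so they are exact at the small
n used in tests.

## 5. Unweighted PRS

`computePrs()` scores each individual as the sum of effect-allele dosages
over the risk set: `g` when the effect allele is the alt allele, `2 − g`
when it is the reference allele; an effect allele matching neither is
excluded with an audit entry. Every variant has weight 1 — the unweighted
choice trades efficiency (when published effect sizes transfer) for
robustness (when they do not, as across ancestries with differential LD).

- Missing dosages are imputed at twice the **in-sample** effect-allele
  frequency, not the catalog frequency, because catalog frequencies are
  typically ancestry-mismatched.
- Strand-ambiguous (A/T, C/G) variants are retained with a warning by
  default, since alignment is by ref/alt identity rather than strand; a
  strict mode excludes them. The synthetic catalog contains none.
- Scores are reported as raw allele counts, not standardized, so the
  association slope keeps the "per 1 trait-increasing allele"
  interpretation; β×100 is then the percent change in outcome z-score
  per allele. This raw-count scaling is dictated by that interpretation;
  standardization, when wanted, belongs downstream.

## 6. Association models

Outcomes are transformed by the rank-based inverse-normal transform with
the Blom offset, `Φ⁻¹((r − 3/8)/(n + 1/4))`, average ranks for ties,
missing values preserved — the convention of genetic epidemiology. The
transform is applied **after** sample exclusions and within the analysis
visit, so the scores reflect the analysed sample. Degenerate input (all
values identical) is an error, not a silent zero vector.

Ancestry PCs are computed from the variant-standardized dosage matrix
(centred by 2f, scaled by √(2f(1−f)), monomorphic variants excluded,
missing entries zero after centring) via SVD; the default of 10
components matches common practice for admixed cohorts.

`fitPrsAssociation()` fits OLS of the outcome z-score on the raw PRS plus
covariates (optionally BMI), reporting β×100 with a t-quantile 95% CI and
the incremental R² of the PRS over the covariate-only model. Incremental
(rather than marginal) R² is the interpretable notion of "variance
predicted by the PRS" once age, sex and ancestry are accounted for.

The mixed alternative, `mixedRandomIntercept()`, adds a per-family random
intercept and fits by REML profiled over the single variance ratio
λ = σ²_family/σ²_residual, with GLS slopes at the optimum. The profile is
one-dimensional, the λ = 0 boundary is evaluated explicitly (so null
family variance reproduces OLS exactly, and the balanced one-way case
reproduces the closed-form ANOVA estimator), and non-convergence at the
upper profiling bound is an error that reports the interval. The linear
model is the primary analysis and the mixed model the robustness check;
with family clustering entering the simulated phenotypes only through a
shared intercept — and genotypes independent across family members — the
two give very similar slopes, which is why OLS results are the default
output. Two-sided p-values are used throughout and no multiple-testing
correction is applied; callers should interpret nominal significance
accordingly.

## 7. Effect clustering

`buildEffectMatrix()` assembles β×100 of each adiposity trait on each
risk-set variant (oriented to the published effect allele), dropping and
auditing variants with missing estimates. `wardLinkage()` clusters rows
and/or columns under Ward's minimum-variance criterion on Euclidean
distances in the Ward.D2 convention — each merge minimizes the increase
in total within-cluster sum of squares and the recorded height is
√(2·ΔSSE) — which is the convention consistent with the method's
definition; heights are therefore monotone non-decreasing. Ties are
resolved deterministically by merge index; with continuous effect
estimates, exact ties have probability zero. The heatmap writer always
emits a TSV of the matrix in dendrogram leaf order so that clustering
results can be checked without parsing an image. Whether rows, columns
or both are clustered is configurable; both are clustered by default.

## 8. The synthetic cohort generator

The generator exists so that every downstream stage has inputs with known
ground truth. Its default (`defaultArchitecture()`) encodes one plausible
generating model of the qualitative structure the analysis is designed to
detect — it is **encoded, not discovered**: BMI- and BF%-attributed
variants load predominantly on SAT and overall BF%, WHR-attributed
variants raise WC, lower HC and load predominantly on VAT. Passing the
pattern tests therefore shows the pipeline recovers a structure that is
true by construction, not that any real cohort has that structure.

Design of the default architecture (all values chosen once, as a
plausible desk-scale cohort, and fixed):

- 2554 individuals (the visit-2 pool; 10 pregnancy and 124
  missing/implausible flags leave 2420 analysed), 600 families, family
  intercept SD 0.3 z-units.
- 30 BMI, 12 WHR, 10 WC and 8 BF% causal variants plus 15 null variants;
  MAFs spread deterministically over 0.05–0.49; two 2-variant LD blocks
  (dosage r² = 0.5) exercise pruning; every third causal variant has its
  alt-allele effects negated so its trait-increasing allele is the
  reference allele, exercising allele alignment.
- Per-allele effects of 0.005–0.06 z-units chosen so that β×100
  magnitudes land in the low single digits at n ≈ 2400, the realistic
  order for adiposity PRS.
- One shared latent adiposity factor (loadings 0.35–0.55) plus age and
  sex effects; residual SDs chosen so each latent phenotype has unit
  variance net of covariate terms.
- Latent z-scores map to natural units by fixed location/scale values
  typical of a middle-aged, majority-female cohort with high adiposity
  (e.g. BMI 32.2 ± 7.2 kg/m², SAT 2336 ± 1015 cm³, VAT 839 ± 383 cm³);
  age ~ uniform(35, 84), 36.9% male.

Genotypes are simulated per LD block by thresholding correlated latent
Gaussians, one per haplotype: allele = {latent > Φ⁻¹(1 − maf)}, so the
allele frequency is exact, and the latent correlation is solved
numerically (1-d root finding on the bivariate-normal quadrant
probability) so the realized allele-level — hence dosage-level — r² hits
the target. Dosages are hard calls {0,1,2}; fractional imputed dosages
are exercised separately by the VCF round-trip path. A single master seed
splits into deterministic per-stage substreams, so any stage re-run in
isolation reproduces its in-pipeline draws.

What the generator deliberately does **not** emulate: realistic human LD
maps (blocks are small and equicorrelated), admixture and local ancestry
(so ancestry PCs capture sampling noise, not structure), dominance or
epistasis, genotype inheritance within families (relatives share only a
phenotype intercept, not alleles — which also means OLS standard errors
remain essentially correct despite family clustering), multi-factor
phenotypic covariance (a single shared factor gives weaker trait-trait
correlations than real cohorts, e.g. Spearman BMI–WC ≈ 0.3), and
measurement floors (SAT/VAT are truncated below at 1 cm³, BF% clamped to
[3, 75]). Conclusions from passing tests are therefore about the
*pipeline's correctness*, not about the generalizability of any
biological claim.

## 9. Problem sizes used by the test suite

Simulation-based checks use sizes chosen to give stable Monte-Carlo
margins at desk scale: frequency/LD convergence at n = 10,000–50,000;
null rejection rates over 2000 replicates of n = 500 (two-sided band
0.040–0.060, i.e. ±2 binomial SE); PRS effect recovery and CI coverage
over 100–200 cohorts of n = 2420; the qualitative adiposity pattern over
100 cohorts at the full default size; oracle equivalence (PRS double
loop, greedy pruning enumeration, exhaustive Ward search at n ≤ 6) over
100 random draws each. Brute-force oracles are implemented independently
of the code paths they check.

## 10. Known limitations

- In-sample composite LD replaces reference-panel LD (Section 3).
- The internal screen is OLS-based; a GRM mixed model would be preferable
  for genome-wide use on strongly related samples.
- The exclusion flags are trusted inputs; no plausibility rules are
  recomputed.
- Approach nesting can fail in adversarial LD configurations
  (Section 3).
- Sex-stratified models, weighted/LDpred-style scores and
  conditional-joint signal selection are out of scope.
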