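---
title: "Methods: one-sample multivariable MR for correlated metabolite exposures"
author: "bcaamvmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample multivariable MR for correlated metabolite exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The branched-chain amino acids (BCAAs) leucine, isoleucine and valine
circulate at highly correlated concentrations (r of roughly 0.83-0.91),
because they share synthesis and degradation enzymes, dietary sources, and
genetic regulation.  Observational studies that regress an outcome on one
BCAA at a time cannot distinguish the effect of that BCAA from the effects
of the other two or from shared lifestyle confounders, and so tend to
report homogeneous associations for all three.  Experimental work instead
suggests the individual BCAAs have distinct and sometimes opposing
metabolic effects.

`bcaamvmr` implements the estimation strategy that can resolve this:
one-sample multivariable Mendelian randomization (MVMR) by two-stage least
squares (2SLS), with per-exposure polygenic scores (PRS) as instruments.
Because no individual-level biobank data can ship with a package, it also
implements a synthetic-cohort generator that realizes the assumed causal
structure with known ground truth, so every stage of the pipeline is
testable end to end.

## Causal model

For individual $i$, exposures $X_{ij}$ ($j = 1,2,3$), genetic variants
$G$, observed covariates $C$, a latent confounder $U$, and an outcome $Y$:

$$X_{ij} = \sum_l \pi_{jl} G_{il} + \delta_j U_i + \gamma' C_i +
  \varepsilon_{ij}, \qquad
  Y_i = \sum_j \beta_j X_{ij} + \beta_U U_i + \eta' C_i + e_i .$$

The variants affect $Y$ only through the exposures (the exclusion
restriction holds *by construction* in the generator: no direct $G \to Y$
path is ever simulated), $U$ affects all exposures and the outcome, and
the exposure noise $\varepsilon$ is cross-correlated.  Binary outcomes
replace the second equation by a liability-threshold (probit) model: the
individual is a case when the latent liability exceeds the quantile
matching the configured prevalence.

A design note on $U$ versus $C$: we deliberately separate the *observed*
covariates (age, sex, center analogues, included in every regression) from
the *latent* confounder (never available to the estimators, only to
tests).  This makes "adjusting for covariates" and "robustness to
unobserved confounding" two distinct, separately testable phenomena.

## The synthetic-cohort generator

Dosages are drawn Binomial(2, MAF) at linkage equilibrium; linkage is
emulated only by an optional duplicate-with-noise variant copier
(`add_variant_copy()`), which is all that stepwise conditional selection
needs to be exercised.  Effects are built on the standardized-genotype
scale as block matrices $W$ with $W'W$ fixed exactly:

* a **shared block** (default 8 loci) whose per-locus effect vectors have
  cross-exposure correlation `genetic_correlation` (default 0.79),
  constructed as $Q \,\mathrm{chol}(\Sigma)$ with $Q$ column-orthonormal,
  so realized population genetic variances equal the heritability targets
  *exactly* rather than in expectation;
* an **exposure-specific block** (default: 4 valine-only loci carrying 5%
  of valine's genetic variance), mirroring a genetic architecture in which
  one exposure harbors loci the others lack;
* a **polygenic background** (default 600 small-effect shared variants
  carrying 17% of each exposure's genetic variance), present so that
  estimated PRS explain *slightly less* variance than the heritability —
  the realistic gap between a PRS and $h^2$;
* **null variants** (default 188) so that p-value-thresholded score
  construction and genomic control see realistic null content.

Default calibration (chosen analytically from the generating covariance
algebra before any estimator was run, then frozen): heritabilities
(0.66, 0.65, 0.67), confounder loadings 0.45, residual correlation 0.95.
These put measured pairwise exposure correlations near 0.84-0.86, within
the 0.83-0.91 range such exposure panels exhibit, genetically predicted
correlations near 0.75-0.79, and score partial $R^2$ a few points below
the heritability ceiling.

What the generator does **not** emulate: population structure and
relatedness, realistic LD blocks, imputation beyond a per-variant quality
scalar, genome-scale variant counts, and time-to-event outcomes.  Passing
tests therefore demonstrate correctness of the estimators under the
assumed causal structure; they do not certify robustness to stratification
or LD misspecification in real biobank data.

## Phenotype curation

Continuous phenotypes: the adjusted Fisher-Pearson sample skewness is
computed; when $|skew| > 0.75$ the phenotype is inverse rank-normalized
with rankit offsets $\Phi^{-1}((r - 0.5)/m)$ and average ranks for ties
(the rankit convention rather than Blom's; the difference is immaterial at
study sample sizes).  Values beyond 4 SD from the mean are then set
missing.  Two open choices were closed as follows: the outlier step runs
*after* the transform when the transform fires (before otherwise), and it
is *iterated to its fixed point*, which makes curation exactly idempotent
— a single pass is not, because removing a point shrinks the SD and can
expose new boundary points.  A fully tied vector maps to all zeros (every
value sits at the median rank), which is what the rankit formula itself
gives.  Binary phenotypes with fewer than 200 cases, and continuous
phenotypes with fewer than 200 observations, are excluded; "fewer than
200" is read strictly, so exactly 200 is retained.  Diagnosis events map
to phecode case/control phenotypes through a mapping table; only
primary-position events create cases, and unmapped codes are logged, not
fatal.

## Association scans and signal selection

Each exposure is inverse rank-normalized and regressed on every variant's
dosage plus covariates (OLS via covariate residualization, which equals
the joint fit exactly).  Variants are filtered on imputation quality
$< 0.4$ or effective sample size $2\,\mathrm{MAF}(1-\mathrm{MAF})NQ < 30$,
with MAF folded to the minor allele first.  Genomic control estimates the
inflation factor $\lambda$ as the median test statistic over 0.4549 (the
median of $\chi^2_1$); statistics are divided by $\lambda$ only when
$\lambda > 1$ — deflation is never applied.  Genome-wide significance is
$p_{GC} < 1.7\times 10^{-9}$.

One behavior worth knowing: on the compact default panel *most* variants
carry true signal, so the median-based $\lambda$ is large and the
correction is conservative.  That is a property of the panel, not a bug —
the genomic-control estimator assumes predominantly null tests, which a
real genome satisfies and a 800-variant simulation does not.  Null
simulations (no genetic effects) give $\lambda \approx 1$.

Independent signals are found by greedy forward selection on
individual-level data: repeatedly add the candidate with the smallest
conditional p-value (exposure on selected variants + candidate +
covariates) while that p-value stays below the genome-wide threshold,
skipping candidates whose dosage is $r^2 > 0.9$ explained by the selected
set.  Ties break deterministically by (p-value, variant id).  The
selection threshold equals the genome-wide threshold — the natural choice
where a conditional-selection threshold is otherwise unspecified.

## Cross-fitted polygenic-score instruments

For each of K = 5 folds (seeded assignment), the scan is rerun on the
other four folds, and held-out individuals are scored with training-fold
marginal betas of variants with training $p < 0.05$.  Cross-fitting is the
load-bearing choice: weights estimated in-sample would absorb the
confounded exposure noise and the "instrument" would no longer be
excludable.  The scores stand in for penalized single-population PRS
machinery; what downstream estimation needs from them — out-of-sample
predicted exposures, standardized to mean 0 and variance 1 — is preserved,
and effects are interpreted per 1 SD of score.  A fold that selects zero
variants is an error advising larger effects or a looser inclusion
threshold.

## MVMR estimation

**First stage.**  Each (inverse rank-normalized) exposure is regressed on
*all three* scores plus covariates — the scores share variants, so every
exposure's first stage uses the full instrument set.  Exposures enter
rank-normalized by default (matching the scan's exposure scale); a
raw-scale option is provided.  Two diagnostics per exposure: the
individual F (joint null that the three score coefficients vanish) and
the Sanderson-Windmeijer conditional F, computed by regressing the
exposure on the *other* exposures' fitted values plus covariates, then
regressing that residual on the scores, and rescaling the joint test to
its conditional numerator degrees of freedom (#instruments − #other
exposures = 1 here).  With one exposure the statistic reduces *exactly* to
the individual F.  An exposure whose genetic value is a linear combination
of the others' collapses the conditional F toward its null level while the
individual F stays enormous — precisely the failure the diagnostic exists
to catch.  A gate at F > 10 produces warnings, never fatal errors.

**Second stage, continuous.**  2SLS: the phenotype is regressed on the
fitted exposures plus covariates; standard errors use residuals
recomputed with the *observed* exposures (the standard 2SLS correction).
With three scores and three exposures the system is just identified and
the estimate equals the closed-form IV solution
$(Z'X)^{-1}Z'y$ — an equality the test suite checks to $10^{-8}$ on random
small instances.  95% CIs are normal-approximation; p-values are
two-sided normal.

**Second stage, binary.**  Plug-in IV-probit: probit ML of the outcome on
the fitted exposures plus covariates.  Plug-in analytic standard errors
ignore first-stage noise, so SEs come from a seeded nonparametric
bootstrap over individuals (default 200 replicates) in which both stages
are refit.  Perfect separation is detected and reported;
non-convergence is an error carrying the iteration count.  Estimates are
reported on the probit scale and as approximate odds ratios via
$\mathrm{OR} = \exp(1.6\,\beta_{probit})$, the standard logit≈1.6×probit
scaling; the factor is configurable and both scales are always reported.

**Missingness** is handled per phenotype (complete case), and
`fit_all_methods()` forces MVMR, univariable MR and the observational
regression onto one identical analysis sample so cross-method contrasts
are never a sample artifact.

## Comparators and what they estimate

Univariable MR instruments one exposure with its own score only.  Under
shared instruments its estimand is not $\beta_j$ but the
correlation-weighted mixture
$\sum_k \beta_k \Sigma^g_{jk} / \Sigma^g_{jj}$, where $\Sigma^g$ is the
genetic covariance of the exposures.  With strongly shared architecture
this mixture has the *same sign for all three exposures* even when the
true effects are mixed-sign with a null — the homogenization bias.  The
package computes this estimand from the generator's realized covariances
(`homogenization_study()`), so the bias is verified against algebra, not
just observed.  The observational comparator regresses the phenotype on
one measured exposure plus covariates and is additionally subject to
classical confounding through $U$ ($\delta_j \beta_U$ for a null
phenotype) and to mutual confounding by the correlated exposures
($\beta_1 r_{12}$ leaking into exposure 2).

## Reporting

Significance uses the computed two-sided p-values against the Bonferroni
threshold $\alpha / (\text{phenotypes} \times 3)$; with 441 phenotypes
this is $3.78\times10^{-5}$.  Per phenotype, the number of significant
exposures is counted under MVMR and under UVMR and cross-tabulated (4×4,
UVMR rows by MVMR columns).  "Directionally consistent" means all
significant estimates share one sign; the report flags the discordance
pattern in which UVMR gives two or more significant, same-signed effects
while the MVMR estimates for those exposures carry both signs.
`published_concordance_counts()` ships the cross-tabulation of a published
UK Biobank BCAA phenome-wide analysis (441 phenotypes) as a reference
input for the same arithmetic.

## Numerical and degenerate-case choices

Monomorphic variants are flagged and never tested.  Rank-deficient
designs raise errors naming the collinear columns.  Dosages outside
[0, 2] on input are an error naming the variant.  Score standardization
uses the sample SD (variance exactly 1).  Stepwise ties break by
(p, variant id).  The conditional-F denominator degrees of freedom
subtract the number of conditioning fitted values.  Cohort serialization
writes doubles with 17 significant digits so a written cohort re-reads
bit-identically, and the recorded seed regenerates it bit-identically.

## Study sizes used by the packaged experiments

The packaged simulation studies use: calibration checks at n = 100,000
under the full default panel (800 variants); CI-calibration at n = 20,000
with the 12-locus architecture across 200 replicates (the replicated
coverage study re-draws architecture and sampling jointly — its per-run
estimates are pooled over the three coefficients, since a 200-draw
binomial cannot resolve per-coefficient coverage tighter than a few
points); the homogenization contrast at n = 50,000; and null-calibration
scans at n = 1,500 × 1,000 variants × 20 replicates.  These sizes were
chosen so each experiment's Monte Carlo error is small relative to the
quantity it checks.

## Known limitations

* The probit second stage is the plug-in (fitted-exposure) estimator the
  field's applied work describes, not a full-information control-function
  IV-probit; its bootstrap SEs are honest but slower.
* No horizontal-pleiotropy sensitivity estimators (MR-Egger, median-based
  methods) — few exist for 2SLS-with-PRS, and they are out of scope here.
* Two-sample MVMR, mixed-model association (relatedness), GREML
  heritability estimation, and LD-aware score shrinkage are out of scope.
* The generator's exclusion restriction is exact by construction; real
  data offer no such guarantee, and the package's estimates inherit
  whatever pleiotropy the instruments carry.
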