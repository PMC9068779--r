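---
title: "Methods: consensus pairwise epistasis detection with epipair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus pairwise epistasis detection with epipair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipair)
```

## The problem

Pairwise statistical epistasis is a joint effect of two loci on a
phenotype that deviates from the sum of their single-locus effects. No
single statistic captures every form such a deviation can take: a
product-term regression is sensitive to multiplicative allele-dose
interactions, an omnibus two-locus ANOVA to any patterning of cell means,
an allele-count odds-ratio contrast to case/control differences in
inter-locus allelic association, and MDR-family classifiers to
penetrance patterns (such as xor-like checkerboards) that have little or
no marginal signal. `epipair` therefore runs several statistics over the
same panel, assesses each by permutation, and reports only pairs
supported by a configurable number of methods, followed by a replication
gate in an independent cohort. The package treats BMI as the reference
phenotype — quantitative for the regression/ANOVA/GMDR paths, and
dichotomized at 25 kg/m² (the WHO overweight boundary, applied
inclusively: BMI ≥ 25 is "high") for the class-based methods.

## Statistics and their assumptions

**Regression interaction.** OLS of
$Y=\beta_0+\beta_1 g_A+\beta_2 g_B+\beta_3 g_A g_B$ (+ covariate columns
when requested), with a two-sided $t$ test of $\beta_3$. Assumes
approximately homoscedastic residuals; covariates default to *off* in the
pairwise scan, mirroring the common tooling convention, but age and sex
are accepted anywhere a covariate matrix is. Rank-deficient designs
(monomorphic locus, collinear covariates) are errors, not silent drops.
The variance partition reports raw and adjusted $R^2$ of the
covariates+main model and the covariates+main+interaction model; the raw
difference `delta_r2` is non-negative by nesting, while the adjusted
difference may be negative when the interaction adds nothing.

**Allele-count odds-ratio Z.** Within each BMI class every sample
contributes the outer product of $(g_A, 2-g_A)$ and $(g_B, 2-g_B)$ to a
2×2 pseudo-allele table; the statistic is
$Z=(\log R-\log S)/\sqrt{V_R+V_S}$ with $R,S$ the two class odds ratios.
We read the "standard error" terms of this classical formula as Woolf
variances (sums of reciprocal cell counts), the convention of the
established fast-epistasis implementation; the flag is noted here because
the name suggests a square root that the convention does not take. Zero
cells receive the Haldane–Anscombe +0.5 on all four cells of the affected
table. The statistic is exactly antisymmetric under class swap, and the
constant scaling of the outer-product construction cancels in the odds
ratio.

**Two-locus ANOVA.** One-way ANOVA across the occupied cells of the 3×3
joint-genotype grid. This is deliberately an *omnibus* two-locus
association test — it responds to main effects as well as interactions —
which is why it complements rather than duplicates the regression path. A
two-way decomposition is intentionally not attempted. Degenerate inputs
are defined, not errors: a constant phenotype returns $F=0,p=1$; perfect
separation returns the smallest representable p rather than 0 so that
$p\in(0,1]$ always holds.

**MDR.** For each pair and cross-validation fold, a 3×3 cell is labelled
high-risk when its training case:control ratio is at least the overall
training ratio. Ties label high-risk (a documented constant — the
boundary case is arbitrary and must simply be fixed); cells with cases
but no controls are high-risk; empty cells are unclassifiable. Balanced
accuracy excludes samples in unclassifiable cells from both numerator and
denominator, which keeps the null expectation centred at 0.5 — counting
them as errors would bias all accuracies downward in sparse grids. The
comparison `cases*n_controls >= controls*n_cases` is carried out in
integer arithmetic so ties are exact.

**GMDR.** Score statistics are response-scale residuals of the
covariate-only GLM (identity link for the quantitative trait, logit for
the class), computed once per cohort. When labelling cells within a
training fold the scores are re-centred on that fold's training samples.
This choice does two things: it prevents the held-out fold from leaking
into the labelling through the global mean, and it makes GMDR with a
binomial family and no covariates reduce *exactly* to MDR's training
case:control rule — without the re-centring the two rules diverge on
folds whose class ratio drifts from the cohort ratio. Floating-point ties
at the zero threshold resolve to high-risk within a relative tolerance of
1e-9, matching MDR's tie convention.

**Search and model choice.** All pairs compete in each of $k$ folds
(default 10, stratified by class or score sign so no fold loses a class);
the per-fold winner is the best training balanced accuracy, with exact
ties resolved by canonical (chromosome, position) pair order. The
reported model is the modal pair; CVC is the number of folds that chose
it; ties on CVC break to higher mean testing balanced accuracy, then
canonical order. The reported risk map is trained on the full data.

## Permutation significance

All permutation procedures shuffle phenotype rows *with their covariates*
against genotype rows, preserving the covariate–phenotype relationship
under the null of no genotype effect. For closed-form scans the
family-wise adjustment uses the min-p (max-statistic) null: per
permutation the minimum nominal p over all pairs is recorded, and
$p_{adj} = (1+\#\{\text{null min-p} \le p_{obs}\})/(1+B)$, so
$p_{adj}\ge 1/(B+1)$ always. For MDR/GMDR the null statistic is the best
testing balanced accuracy of a full re-run search; cutoffs are empirical
$1-\alpha$ quantiles of that null. The add-one convention keeps
permutation p-values valid (never zero) and approximately uniform under
the null, which the test suite checks by Kolmogorov–Smirnov.

## Consensus and replication

A pair enters the consensus when at least `min_methods` (default 2)
distinct methods flag it at permutation-adjusted $p<0.05$; pair identity
is order-free. Replication re-tests each consensus pair in the second
cohort. The MDR/GMDR path must first pass a cross-validation consistency
gate of at least 7 of 10 folds; because a pair re-tested in isolation
wins every fold vacuously, the gate is evaluated by letting all
discovery loci present in the replication cohort compete in one search
and counting per-pair fold wins. A pair replicates when any method
reaches adjusted $p<0.05$ in cohort 2. Directional consistency of the
interaction effect across cohorts is reported but not enforced — the
workflow being emulated does not state such a requirement.

## Quality control

Variants pass, in order: a biallelic check, a call-rate filter (default
> 99%; discovery-grade strictness "no missing calls" is
`min_call_rate = 1`), the Hardy–Weinberg exact test (exclusion at
$p \le 10^{-6}$), and an imputation-$r^2$ filter (≥ 0.7, applied only
where an $r^2$ is recorded). The HWE test is the standard two-sided
conditional-on-allele-counts exact test (non-mid-p): probabilities of all
heterozygote counts of the correct parity are built by the numerically
stable two-sided recurrence and normalised, and the p-value sums those
not exceeding the observed probability (within a relative tie tolerance
of 1e-9). Locus pruning is greedy by ascending association p with an
inclusive 500 kb window; the most significant locus is always retained.
The stratum allele-frequency bias check generalises a
diagnosis-group confounding check: per variant, all pairwise strata 2×2
allele-count Fisher tests, minimum p per variant, BH adjustment across
variants, flagging below 0.01. Allele-count (2×2) rather than genotype
(2×3) tables were chosen as the sharper test for *allelic* bias; this is
an interpretation the configuration exposes rather than hides.

## The simulator

`simulate_genotypes()` draws each call as the sum of two Bernoulli(MAF)
alleles — independent variants in exact Hardy–Weinberg proportions, no
linkage disequilibrium, mirroring a panel pruned to well-separated loci.
`simulate_phenotype()` builds
`bmi = beta0 + beta_age*age + beta_sex*sex + main effects + interaction +
N(0, noise_sd²)` with age uniform on [40, 70] and sex Bernoulli(1/2).
Three interaction forms are supported: `product` ($\beta_3 g_A g_B$),
`xor` ($\beta_3\,1[g_A+g_B\ \mathrm{odd}]$, the marginal-free
checkerboard), and `threshold` ($\beta_3\,1[g_A=2 \wedge g_B=2]$).

The canonical fixtures fix the study conditions once:

- `null` — n = 1000, 10 variants, MAF 0.3, no genotype effects,
  residual SD 1.
- `planted_product` — n = 2000, 20 variants, MAF 0.3, β₃ = 0.5 (half a
  residual SD) between rs5 and rs12, no main effects.
- `planted_xor` — n = 900, 10 variants, a 10 kg/m² xor effect against
  residual SD 0.5: complete penetrance of the class, MAF 0.5 at the
  causal pair so all cells are populated.
- `two_cohort` — two independent `planted_product` cohorts; the second
  cohort's interaction can be switched off to emulate a non-replicating
  discovery.

Fixture intercepts are set to 22.3 kg/m² so that after the expected
covariate contribution (0.04 × 55 + 1 × 0.5) the mean sits on the 25
kg/m² class boundary and both classes are well populated. What the
simulator does *not* emulate: linkage disequilibrium (so phantom
epistasis from partially tagged causal variants cannot arise here),
population structure, genotyping or imputation error, and non-Gaussian
phenotype tails. Passing tests on these fixtures therefore demonstrate
the statistical machinery's correctness and calibration, not robustness
to those real-data complications.

## Numerical and design choices

- Genotypes are stored as ALT-allele counts; effect-allele orientation is
  a reporting-layer relabel, never a recode.
- Missing calls are a distinct state; each statistic applies a
  pairwise-complete policy rather than imputing zeros.
- P-values are clamped to the smallest representable positive double so
  every reported p lies in (0, 1].
- Permutation depth defaults to the conventional 1000 in the pipeline
  configuration; the test suite and the acceptance script use B between
  99 and 200 with correspondingly granular p-value floors — these sizes
  are the package's own validation-scale choice and are reflected in the
  reported `n` fields.
- Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical seeds give byte-identical fixtures and
  identical pipeline output.

## Known limitations

- The scan is brute-force over all $\binom{m}{2}$ pairs, intended for
  pruned panels of a few hundred loci, not genome-wide scans; the
  index-based pruning strategies of specialised exhaustive scanners are
  out of scope.
- Only second-order interactions are searched; MDR orders > 2 are not
  implemented.
- Dosage/probabilistic genotypes, phased data and multi-allelic sites
  (beyond skip-with-warning in the VCF reader) are unsupported.
- The allele-count Z test inherits the allelic-model assumption that
  within-sample allele pairings are exchangeable; it is a screening
  statistic, not an estimator of a biological interaction parameter.
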