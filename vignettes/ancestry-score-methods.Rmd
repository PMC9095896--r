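---
title: "Ancestry-aware polygenic prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-aware polygenic prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A polygenic score (PGS) is a weighted sum of allele dosages with weights
taken from GWAS effect sizes. In a multi-ancestry setting part of the
genetic variance of a trait is carried by variants whose frequencies differ
systematically between populations. A GWAS that corrects for population
structure — as it must, to avoid confounding — includes ancestry principal
components (PCs) among its covariates, and thereby suppresses exactly those
variants: a variant fixed in one population and absent in the others is an
exact linear function of population membership and cannot be separated from
the PC covariates at all. The variance such variants explain never reaches
the PGS, and predictions degrade as the target cohort's ancestry
composition drifts away from the discovery cohort's.

`ancestryscore` adds that missing component back as a separate predictor.
Position in a shared ancestry space is itself predictive of the phenotype
whenever ancestry-linked causal variants exist; the **ancestry score (AS)**
estimates that component directly and enters the final predictive model
next to the PGS.

# The model, stage by stage

## Mapped PCs

PC coordinates computed separately in two cohorts are not comparable.
All cohorts are therefore projected into the PC space of a single **map
cohort** (in practice a public reference panel; in simulation the base
cohort doubles as its own map). `fit_map_pca()` standardizes each reference
SNP of the map cohort (mean-centered, divided by the observed dosage
standard deviation), takes the top `n_pcs` eigenvectors of the resulting
correlation matrix as SNP loadings `L`, and stores the centering and
scaling vectors alongside. `project_mapped_pcs()` applies exactly those
stored parameters to any other cohort, so projection needs no access to
map genotypes.

Two numerical conventions make results reproducible:

* per-SNP scaling uses the *observed* dosage standard deviation rather than
  the binomial `sqrt(2 maf (1 - maf))`; the observed scale is
  self-consistent for any input (including imputed dosages) and is stored,
  so the choice is transparent to downstream stages;
* each PC's sign is fixed by requiring its largest-magnitude loading to be
  positive, removing the sign indeterminacy of eigenvectors.

The reference SNP set is the intersection of base-cohort SNPs passing an
imputation-quality filter (`INFO > 0.9`) with map-cohort SNPs passing
`MAF > 0.01` and greedy LD pruning at `r² ≤ 0.5` within a 250 kb sliding
window — conventional values for PCA SNP panels, all configurable. Pruning
walks SNPs in genomic order and keeps the lower-coordinate member of a
correlated pair, a deterministic tie-break. `r²` is the squared Pearson
correlation of dosages.

## Association studies

`run_gwas()` fits, per SNP, ordinary least squares of the phenotype on
dosage, covariates and an intercept. Computation residualizes the phenotype
and all dosage columns on the covariate space once (Frisch–Waugh–Lovell),
which is algebraically identical to the per-SNP regression and vectorizes
across SNPs; p-values come from the t distribution on `n − k − 1` degrees
of freedom. Zero-variance SNPs are reported with `NA` estimates and a note
rather than dropped, keeping output rows aligned with input metadata.

A **collinearity guard** is essential here. A population-specific variant
whose alternate allele is fixed in its population has dosage
`2·1[pop = p]`: once ancestry PCs are covariates, its residual dosage
variance is a sliver of PC sampling noise, and the OLS coefficient on that
sliver is a hugely amplified artifact (empirically, effect sizes around 7
with nominally tiny p-values for truly null variants — enough to destroy
any downstream PGS). Standard GWAS software refuses to report such fits;
`run_gwas()` does the same: any SNP whose dosage has a variance-inflation
factor above `vif_max` (default 50, i.e. more than 98% of its variance
explained by the covariates) is reported `NA` with the note
`"collinear_with_covariates"`. This is precisely the mechanism by which
population-specific causal variants are *nullified* in a
structure-corrected GWAS — and why their phenotypic contribution must be
recovered through the AS.

`run_pcas()` — the principal-component association study — is a single
joint regression of the phenotype on the first `p` mapped PCs (plus
non-PC covariates). Its per-PC effect sizes `b̂` are the AS weights. The
PC covariates of the GWAS are *not* added here: they would be collinear
with the predictors under test.

## Score construction

`clump_snps()` implements greedy LD clumping: SNPs are visited by ascending
GWAS p-value; each unclaimed SNP becomes an index SNP and claims all
unclaimed SNPs within 250 kb at `r² ≥ 0.01` (defaults). For simulated
panels the SNPs are independent by construction, so the scenario driver
skips clumping and passes all tested SNPs to thresholding directly.

`optimize_pgs_threshold()` scores the calibration cohort at each candidate
p-value threshold (default grid `5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1,
0.5, 1`) and keeps the threshold maximizing the calibration coefficient of
determination. Ties break toward the smaller threshold (the sparser
score), and thresholds admitting no SNP are recorded with a score of zero
but never selected. `compute_pgs()` and `compute_as()` are then plain
weighted sums; both are invariant to sample and column order, and
`compute_pgs()` tolerates at most 5% missing formula SNPs (scored as
dosage 0 with a warning — beyond that it errors and tagging substitution
should be used instead).

When a target cohort lacks reference SNPs, `substitute_tagging_snps()`
replaces each missing SNP by the available SNP maximizing
`INFO × r²` in the map cohort's LD window, reporting as dropped any SNP
with no candidate above a floor.

## Calibration, prediction and evaluation

`calibrate_model()` fits `Y ~ β_PGS·PGS (+ β_AS·AS) (+ γC)` by OLS on the
calibration cohort; `predict_phenotype()` applies the coefficients to
target-cohort scores. `evaluate_predictions()` reports the phenotypic
variance explained as the coefficient of determination
`1 − SS_res/SS_tot` — deliberately *not* the squared correlation. The
distinction matters: a model whose intercept is miscalibrated for the
target (the typical failure when a population present at calibration is
missing from the target, or vice versa) predicts with a constant offset
that squared correlation would forgive and the coefficient of
determination correctly penalizes.

# The simulator

`build_cohorts()` generates base, calibration and target cohorts from
three populations A, B, C with a shared genetic architecture:

* **non-specific SNPs** — one frequency from U(0, 1) shared by all
  populations: no ancestry information;
* **population-specific SNPs** — alternate allele present in exactly one
  population (frequency U(0.4, 1), or fixed at 1 with probability ½; the
  carrier population rotates A→B→C so each receives about a third);
* **stratified SNPs** — an ancestral frequency Rf ~ U(0, 1) dispersed into
  per-population frequencies by the Balding–Nichols model
  `Af ~ Beta(Rf(1−Fst)/Fst, (1−Rf)(1−Fst)/Fst)`, which has mean `Rf` and
  variance `Rf(1−Rf)·Fst`. Defaults assign Fst 0.02 to populations A and B
  and 0.2 to C, making C the genetically distant population.

Genotypes are drawn per SNP and sample under Hardy–Weinberg equilibrium
(dosage probabilities `(1−Af)²`, `2Af(1−Af)`, `Af²`). Phenotypes take 10%
of SNPs per category as causal with effects `β ~ N(0, 1)`:
`Yg = G_causal β`, and `Ye ~ N(0, σ²_Yg (1 − h²)/h²)` with `h² = 0.6` by
default, so the realized narrow-sense heritability matches `h²` in
expectation. The environmental variance is scaled to each cohort's own
realized `σ²_Yg`: cohorts are drawn independently, and per-cohort scaling
keeps the heritability — and hence the PVE ceiling on the target — at `h²`
regardless of the cohort's population composition. Causal SNP identities
and effects are drawn once and shared by all three cohorts.

Monomorphic sampled SNPs are retained in the genotype matrix (downstream
stages must cope with zero-variance columns, and do); synthetic SNPs sit
on one chromosome at 1 Mb spacing so a 250 kb LD window never spans two
of them, with INFO fixed at 1.

## Scenario presets

Defaults follow the study conditions throughout: 500 SNPs, cohort sizes
20,000 / 7,000 / 3,000, `h² = 0.6`, 10% causal per category, Fst
0.02/0.02/0.2.

The *architecture* family varies the SNP category mix under equal-thirds
population composition everywhere: `control` (500 non-specific),
`specific` (250/250/0), `stratified` (250/0/250) and `mixed`
(168/166/166). The exact splits of the mixed designs are an even division
of the 500-SNP total; they are configurable, not structural assumptions.

The *composition* family fixes the mixed architecture and varies cohort
composition. The graded scenarios interpolate from agreement to reversal:
`homogeneous` uses equal thirds everywhere; `shifted` and `reversed` give
base/calibration an A-dominated mix (0.6, 0.3, 0.1) with a balanced and a
C-dominated (0.1, 0.3, 0.6) target respectively. These proportions are a
design choice of this package — any graded family between agreement and
reversal exercises the same mechanism — and are configurable per cohort.
`extreme` puts population C at 3% of base/calibration and 97% of the
target; `absent` removes population A from the target entirely.

One modelling tension is worth noting: describing the three populations as
equidistant while assigning Fst 0.02/0.02/0.2 is internally inconsistent —
population C is deliberately the outlier. The Fst assignment is taken as
the operative definition and equidistance is not enforced.

## What the simulator does and does not emulate

It reproduces the statistical structure that the method targets:
ancestry-differentiated allele frequencies, ancestry-linked causal
variants, controlled heritability, and cohort-composition mismatch. It
deliberately omits LD within cohorts (SNPs are independent, which is why
the scenario driver skips clumping), genotyping/imputation error (INFO is
fixed at 1), covariates such as age or sex, binary traits, and
environmental components correlated with ancestry. Passing simulation
tests therefore demonstrates the mechanism — recovery of ancestry-linked
genetic variance — not performance on real biobank data, where LD
structure, pleiotropy and ancestry-correlated environment add failure
modes of their own.

# The scenario driver

`run_scenario()` executes, per replicate: cohort generation → PCA on the
base cohort's polymorphic SNPs (2 PCs by default — sufficient to separate
three populations; 40 is a common choice for biobank-scale data) →
projection of all cohorts → GWAS with PC1 and PC2 as covariates → PCAS on
2 PCs → threshold optimization on the calibration cohort → PGS and AS for
calibration and target → calibration of a PGS-only and a PGS + AS model →
evaluation of both on the target. Replicate seeds derive deterministically
from the master seed, so identical configuration and seed reproduce
results bit for bit.

`summarize_results()` aggregates replicates into means, variances and
empirical 95% intervals; `plot_scenario_summary()` renders the standard
two-bar comparison.

## Behavior across scenarios

With homogeneous cohorts and no ancestry-linked causal variants
(`architecture-control`), the AS is noise and its coefficient calibrates
to zero: the combined model neither helps nor hurts. With
population-specific causal variants, the GWAS nullifies the fixed-allele
ones (collinearity guard above), the PGS misses their variance, and the
AS restores it. With only stratified causal variants the PGS itself
carries the between-population signal (within-population effect estimates
applied to frequency-differentiated dosages reproduce the population
means), so the AS adds at most a sliver — the part lost by sub-threshold
causal SNPs and finite-sample noise in between-population components.
That residual benefit is real but an order of magnitude below plotting
resolution; a sufficiently powered significance test over many replicates
can detect it even though it is negligible in magnitude, which is worth
remembering when "no gain" is operationalized as a hypothesis test.

Under cohort-composition mismatch the PGS-only model degrades through a
second channel: systematic between-population components of PGS error that
calibration cannot see become large on a differently-composed target, and
in the extreme minority scenario the across-replicate variance of PGS-only
PVE explodes. The AS gives the calibration model an explicit ancestry
axis, which both restores the mean PVE toward the heritability ceiling
and stabilizes it. The correction is not free of limits: with the target
dominated by a population nearly absent at calibration, the population's
intercept is an extrapolation along the ancestry axis, and occasional
replicates still take a visible PVE penalty from a residual constant
offset — variance is reduced by a large factor, not eliminated.

# Problem sizes, tolerances and degenerate inputs

The test suite validates estimators against brute-force normal-equations
oracles (agreement to 1e-8 on instances up to n = 500, s = 50), clumping
against an exhaustive reference implementation, self-projection against
native PCA scores (1e-6 after sign alignment), and generator moments
against closed-form Beta/binomial theory within 4σ Monte-Carlo bounds at
1e4–1e5 draws. End-to-end scenario checks run 20 replicates per scenario
at the full cohort sizes; `scripts/acceptance.R` re-runs the same study
from a user-supplied seed, using 50 replicates for the extreme minority
scenario, whose metrics have the highest replicate variance.

Degenerate inputs are rejected with specific errors: Beta shape parameters
degenerate at `rf ∈ {0, 1}` or `fst ∉ (0, 1)`; a causal set monomorphic in
a sampled cohort gives a degenerate-variance error; zero-variance SNPs in
a PCA reference set are named; rank-deficient covariate designs name the
collinear columns; constant PGS columns, mismatched model structures and
zero-variance phenotypes all error rather than silently producing
numbers.

# Limitations

* Effect sizes are assumed transferable across populations; pleiotropic
  or LD-mediated effect-size differences between ancestries are outside
  the model.
* The AS inherits whatever the mapped PCs capture — in real data that
  includes ancestry-correlated environment, so an AS association must not
  be read as purely genetic.
* Tagging-SNP substitution assumes the map cohort's LD structure applies
  to the target.
* The predictive model is linear with a single phenotype; binary traits
  and interaction models are out of scope.
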