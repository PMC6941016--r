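---
title: "Modelling dominance in genomic prediction and association analysis"
author: "domgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dominance in genomic prediction and association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domgp)
```

## The problem

Routine genetic evaluation of livestock treats genetic merit as purely
additive. Dominance — the interaction between the two alleles an individual
carries at a locus — contributes to phenotypic variance but not to what a
parent transmits, so it is usually folded into the residual. For traits such
as carcass weight in beef cattle, the dominance fraction of phenotypic
variance can be substantial (on the order of 5–16%), and ignoring it (i)
biases the additive variance upward, (ii) leaves predictive signal between
close relatives unused, and (iii) hides loci whose action is mostly or
wholly non-additive.

`domgp` implements a complete dominance-aware analysis for biallelic SNP
panels: genomic relationship matrices for additive and dominance effects,
two-component REML (GBLUP vs GBLUP-D) with a likelihood-ratio comparison,
BayesA/BayesAD marker-effect MCMC, a multi-locus mixed-model association
scan with both codings, and repeated cross-validation of predictive
ability. A synthetic-data generator with known architecture makes every
stage testable without access to animal data.

## Models

### Relationship matrices

Let dosages count copies of the second allele, with `p_i` its frequency at
SNP `i` and `q_i = 1 - p_i`. The additive coding centres the dosage at
`2 p_i`; the dominance coding is the heterozygote indicator centred at
`2 p_i q_i`:

* `G = M M' / sum_i 2 p_i q_i`
* `D = H H' / sum_i 2 p_i q_i (1 - 2 p_i q_i)`

With these scalings both matrices have expected diagonal 1 for a non-inbred
individual and expected off-diagonal 0 for unrelated individuals under
Hardy–Weinberg proportions; the package verifies this by simulation in its
test suite. Sample allele frequencies are used (the base-population
frequencies are unknowable from a single cohort) and are recorded in the
matrix object. Missing dosages contribute 0 after centring, i.e. mean
imputation; QC caps missingness at 5% so the impact is bounded. A small
diagonal ridge (`stabilize()`, default `1e-6`) guarantees positive
definiteness; it shifts every eigenvalue by exactly the ridge.

### GBLUP-D and REML

The phenotype model is `y = X b + a + d + e` with
`a ~ N(0, G sigma_a2)`, `d ~ N(0, D sigma_d2)`, `e ~ N(0, I sigma_e2)`;
dropping `d` gives GBLUP. Fixed effects are slaughter year, sex, body
weight at entry to the fattening unit, and the number of fattening days
(reference-level dummy coding with an intercept).

Variance components maximise the restricted likelihood. Updates are
average-information (AI) steps with step-halving so the criterion ascends
monotonically; when an AI step fails, the standard EM-REML fixed-point
update is taken instead. Components are floored at `1e-8 * var(y)`;
components pinned at the floor with a negative score are held there
(active-set projection) — without this, EM creeps toward the boundary in
ever-smaller steps and small-sample fits can exhaust the iteration budget.
Convergence requires both `|delta logL| < 1e-6` and a relative component
change `< 1e-4` among free components (200 iterations maximum). Standard
errors come from the inverse AI matrix at the optimum.

BLUPs solve the Henderson mixed-model equations with the estimated
components; a Jacobi (diagonal) rescaling of the coefficient matrix keeps
the solve stable when `sigma_e2 / sigma_d2` is extreme, which is exactly
the regime of the nested-model limit `sigma_d2 -> 0`.

Model comparison uses `chi2 = max(0, 2 (logL_D - logL_A))`. Because a
single variance component is tested at the boundary of its parameter
space, the reference distribution is the mixture `0.5 chi2_0 + 0.5 chi2_1`;
the plain 1-df p-value is reported alongside. At `chi2 = 0` the mixture
p-value is 0.5.

### BayesA / BayesAD

The marker-effect model is `y = X b + Wa alpha + Wb beta + e`, with `Wa`
the raw dosage coding (0/1/2) and `Wb` the heterozygote indicator (0/1/0),
both column-centred (centring constants are stored so predictions for new
individuals are intercept-consistent). Priors: per-SNP additive variances
`sigma_alpha_j^2 ~ scaled-inv-chi2(nu_alpha, s_alpha2)` with
`alpha_j | sigma_alpha_j^2 ~ N(0, sigma_alpha_j^2)` (a Student-t marginal);
dominance effects conditionally Gaussian,
`beta_j | alpha_j ~ N(mu_beta, s_D^2 sigma_alpha_j^2)`; flat priors on `b`
and `sigma_e2`.

Sampling is Gibbs with one Metropolis–Hastings step per SNP in BayesAD:
the proposal draws `alpha_j*` from the BayesA-style Gaussian full
conditional computed on the residual with SNP `j` entirely removed, and
`beta_j*` from its conditional prior. The prior terms cancel against the
proposal, leaving an acceptance ratio of residual likelihoods that reduces
to per-SNP dot products; typical acceptance rates are 0.7–0.9. The sweep
is implemented in C++ (Rcpp/RcppArmadillo) with a running residual vector,
so one sweep costs O(nm). Chains use R's RNG and are exactly reproducible
from the seed.

Defaults (`bayes_hyper()`): `nu_alpha = 4.2` (the conventional
heavy-tailed choice), `mu_beta = 0`, `s_D = 0.5`, 20,000 sweeps with 5,000
burn-in and thinning 10. The scale `s_alpha2` is derived from a target
additive fraction (0.5 by default) of the phenotypic variance by inverting
`var(alpha_j) = s_alpha2 nu_alpha / (nu_alpha - 2)` with heterozygosity
weights: `s_alpha2 = h2 var(y) (nu_alpha - 2) / (nu_alpha sum 2 p_i q_i)`.
None of these values is data-derived dogma; all are configurable and
logged. Two limiting cases anchor the implementation: `nu_alpha -> inf`
makes BayesA equivalent to GBLUP at the matched variance ratio (checked to
correlation > 0.99), and `s_D -> 0` collapses BayesAD onto BayesA.

A caution on calibration: the posterior of `sigma_e2` is only a clean
estimate of the noise variance when records clearly outnumber markers.
With `m >= n` the split of `y` into marker fit and residual is not
identifiable, and an informative marker-variance prior absorbs part of the
noise into the markers — a property of the model, not a sampler defect.
The calibration test therefore runs at `n = 600, m = 150`.

### Multi-locus mixed-model scan

The scan is stepwise: at each step every non-cofactor SNP is tested by
generalised least squares with covariance
`sigma_a2 G (+ sigma_d2 D) + sigma_e2 I`, both codings entered jointly and
each coefficient receiving a marginal Wald p-value; the most significant
SNP passing the threshold joins the fixed effects and the variance
components are re-estimated (`refit-per-step`; a cheaper
`fixed-after-null` strategy is available). After the forward phase,
cofactors that are no longer significant in the final model are removed
(backward elimination). Surviving hits are classified `A`, `D`, or `A+D`
by which coding(s) pass the threshold. Ties break by largest absolute
effect, then chromosome and position.

The whole scan whitens once per step with a Cholesky factor of the
covariance and residualises all SNP columns against the fixed effects, so
testing `m` SNPs costs one triangular solve with `m` right-hand sides plus
O(nm) accumulations.

The default threshold is Bonferroni `0.05 / (number of tests)`, where the
count includes the dominance test of every SNP that has heterozygotes —
with two marginal tests per SNP, dividing by the SNP count alone would
double the family-wise error rate. Any numeric threshold can be supplied
instead. Note that at low minor allele frequency the dosage and
heterozygote codings become nearly collinear (correlation → 1 as MAF → 0),
which inflates the joint-test standard errors; dominance classification is
only well-powered at intermediate frequencies.

Gene annotation follows the 100 kb nearest-gene rule: a hit inside a gene
interval is `within` (distance 0); otherwise the nearest interval end
within 100 kb is reported as `upstream`/`downstream`; farther hits carry an
explicit no-gene marker. Gene starts are 0-based half-open (BED
convention), SNP positions 1-based.

### Cross-validation

`cross_validate()` runs repeated k-fold cross-validation (default 5-fold)
of GBLUP, GBLUP-D, BayesA, BayesAD. Models are fitted on training
individuals only; validation genetic values come from the
relationship-matrix covariance between validation and training individuals
(GBLUP family) or from posterior-mean marker effects applied to
training-centred codings (Bayes family). Predictive ability is the
correlation with corrected phenotypes — the phenotype minus the
fixed-effect part, estimated by OLS on the full data (default; a
training-only correction is available by flag — the full-data choice
leaks no genetic information and mildly favours no model). `G` and `D` are
built once on all individuals and sub-matrixed per fold, standard practice
that keeps allele frequencies stable across folds; per-fold rebuilding is
a one-line change via `matrices = NULL` on subsets. Bayes chains inside
cross-validation default to 4,000 sweeps — a deliberate fidelity/runtime
trade-off at desk scale.

## The synthetic-data generator

`sim_config()`/`simulate_dataset()` define the study conditions the
package is tested under: a cohort of (by default) 1233 individuals, SNPs
with MAF uniform on (0.05, 0.5] in Hardy–Weinberg proportions, optional
full-sib families (HWE parents, Mendelian transmission), 100 additive and
100 dominance QTLs with standard-normal raw effects, and a
carcass-weight-like trait (`h2_additive = 0.42`, `h2_dominance = 0.158`,
non-fixed variance ~990 kg², mean ~272 kg) with fixed effects of year
(6 levels), sex (2 levels), entry weight and fattening days, whose
coefficients are fixed in the configuration.

Choices that matter for interpreting test results:

* **Same codings as the estimators.** True breeding values use the centred
  dosage coding and true dominance deviations the centred heterozygosity
  coding — so GREML is correctly specified and parameter-recovery checks
  are meaningful. Under HWE the two parts are orthogonal in expectation.
* **Exact in-sample rescaling.** Genetic parts are rescaled so the
  realised variance fractions equal the `h2` targets exactly, and the
  residual is drawn orthogonal (in sample) to both parts, topped up so the
  total non-fixed variance is exact. Recovery tolerances are then tight
  and interpretable rather than inflated by target noise.
* **Missingness after truth.** Missing calls are injected only after
  phenotypes are computed, so truth is unaffected.
* **One RNG stream per dataset**, seed recorded in the configuration.

What the generator does *not* emulate: linkage disequilibrium beyond
family co-segregation, multi-breed structure, genotyping error, selection,
or non-Gaussian trait distributions (trait summaries in the motivating
literature give no distributional detail; Gaussian is a decision, not
evidence). Passing tests therefore demonstrate correctness of the
machinery under a clean architecture, not robustness to the full messiness
of real cattle data.

## Numerical choices

* QC filters run in the fixed order individuals → SNP missingness → MAF →
  HWE with the strict inequalities MAF > 0.05, missingness < 0.05,
  HWE p > 1e-6, individual missingness ≤ 0.10, each SNP attributed to the
  first criterion it fails; passes repeat to a fixed point so QC is
  idempotent. The HWE test is the exact conditional test (no mid-p).
* Relationship matrices are dense; n up to a few thousand is the design
  point.
* REML: tolerances as above; translation invariance and scale equivariance
  are asserted by tests.
* The scan skips SNPs whose codings are collinear with the current
  cofactors and drops the dominance coding of heterozygote-free SNPs.
* All stochastic stages take explicit integer seeds; the pipeline derives
  stage seeds deterministically from one global seed so changing a later
  stage never perturbs an earlier one.

## Validation design

The test suite checks every operation against an independent route:
relationship matrices against a naive double loop; the restricted
likelihood against a dense error-contrast evaluation (the two REML
criteria differ by the constant `0.5 log|X'X|`); mixed-model-equation
BLUPs against direct GLS with the full covariance; GBLUP against SNP-BLUP
ridge regression at the matched variance ratio; scan p-values against
explicit-inversion GLS; the exact HWE test against configuration
enumeration; the Bayes sampler against its conjugate single-SNP case, its
prior marginal under an uninformative likelihood, and its GBLUP limit.

Parameter recovery runs 30 replicate cohorts at `n = 800, m = 3000` under
the carcass-weight architecture; mean bias of both heritability ratios is
below 0.03 (measured ~0.005). Scan error control runs 200 null cohorts at
the Bonferroni threshold (family-wise false-positive rate ≤ 0.08).

The predictive-ability comparison deserves a note. Within a single
simulated cohort, paired fold differences between GBLUP-D and GBLUP are
dominated by the cohort-level draw of QTL effects and genotypes, so a
fold-paired test on one cohort is answer-by-lottery (observed p-values
range from ~1e-8 to ~1 across cohort seeds). The package's acceptance test
therefore pairs folds across five replicate cohorts (5 cohorts × 5 folds ×
2 repeats), simulated with 200 full-sib families of 4 — full sibs are the
primary carriers of dominance relationships, without which `D` is nearly
diagonal and nothing is gained — and compares predictions of *total*
genetic values, which is precisely what a dominance model adds (corrected
phenotypes contain the dominance deviations). Under these conditions the
dominance models show a consistent advantage of about +0.006 in predictive
ability (paired one-sided p ≈ 0.002), the same order as reported gains in
the cattle literature. The package defaults remain `prediction_target =
"breeding"` and unrelated individuals.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 400–2000
individuals and 150–5000 SNPs — the scale at which every stage, including
30-replicate parameter recovery and 200-replicate error control, runs on a
single desktop core. All sizes are parameters of `sim_config()`; nothing
in the implementation is specific to them.

## Known limitations

* One record per individual (`Za = Zd = I`); repeated records would need
  incidence matrices.
* Dense linear algebra throughout; tens of thousands of individuals would
  need sparse or iterative solvers.
* Only the single stated dominance parameterisation (heterozygosity coding
  centred by `2pq`); genotypic-model alternatives are out of scope.
* The conditional dominance prior is implemented in its independence form
  (`mu_beta`, `s_D^2 sigma_alpha_j^2` constant in `|alpha_j|`); the
  general `|alpha_j|`-dependent form is noted in the interface but not
  guessed at.
* No VCF ingestion, imputation, or sex-chromosome handling.
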