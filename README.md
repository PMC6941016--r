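# domgp — genomic prediction and association analysis with dominance effects

`domgp` quantifies and exploits dominance (within-locus non-additive)
genetic variation in populations genotyped with dense biallelic SNP panels
— the setting of carcass- and growth-trait analyses in beef cattle, where
dominance can account for 5–16% of phenotypic variance yet is routinely
folded into the residual. The package is aimed at quantitative geneticists
and animal breeders who want to (1) partition phenotypic variance into
additive, dominance and residual components, (2) test whether a dominance
model fits better, (3) map loci with additive and/or dominance action, and
(4) measure what a dominance model buys in predictive ability.

## The models

With dosages counting copies of the second allele and `p_i` its frequency
at SNP `i` (`q_i = 1 - p_i`), the additive and dominance genomic
relationship matrices are

    G = M M' / Σ 2 p_i q_i            M: dosage centred at 2 p_i
    D = H H' / Σ 2 p_i q_i (1−2p_i q_i)   H: heterozygote indicator centred at 2 p_i q_i

and the phenotype model is

    y = X b + a + d + e,   a ~ N(0, G σa²),  d ~ N(0, D σd²),  e ~ N(0, I σe²)

fitted by average-information REML (GBLUP drops `d`; GBLUP-D keeps it),
with the dominance component tested by a likelihood-ratio test against the
boundary mixture ½χ²₀ + ½χ²₁. The Bayesian counterparts, BayesA and
BayesAD, model per-SNP effects with scaled-inverse-chi-square variances
(Student-t marginals) and, for BayesAD, conditionally Gaussian dominance
effects `β_j | α_j ~ N(μ_β, s_D² σ_αj²)`, sampled by Gibbs with a
Metropolis–Hastings step (Rcpp). A multi-locus mixed-model scan tests both
codings of every SNP under the polygenic covariance, with forward
inclusion / backward elimination of cofactors and Bonferroni control over
all tests performed; repeated k-fold cross-validation reports predictive
ability as the correlation between predicted genetic values and
fixed-effect-corrected phenotypes. A synthetic-data generator with exact
in-sample heritability targets makes the whole pipeline testable end to
end. See the vignette (`vignettes/dominance-genomic-analysis.Rmd`) for the
full methods account.

## Worked example

Simulate a Simmental-like fattening cohort (800 animals, 3000 SNPs,
carcass-weight architecture: hA² = 0.42, hD² = 0.158), run QC, build the
relationship matrices, and compare GBLUP with GBLUP-D:

```r
library(domgp)

cfg <- sim_config(n_individuals = 800, n_snps = 3000, seed = 11,
                  missing_rate = 0.01)
ds <- simulate_dataset(cfg)

qc <- apply_qc(ds$genotypes)
qc$report
#> QC: 800/800 individuals kept, 2983/3000 SNPs kept
#>   removed: 0 individuals (missingness), 0 SNPs (missingness), 17 (MAF), 0 (HWE)

geno <- qc$genotypes
ph <- ds$phenotypes[match(geno$individual_ids, ds$phenotypes$id), ]
design <- trait_design(ph$trait,
                       ph[, c("year", "sex", "entry_weight", "fattening_days")],
                       ids = ph$id)
G <- stabilize(build_G(geno), 1e-6)
D <- stabilize(build_D(geno), 1e-6)

vc_a  <- reml_fit(design, list(G))      # GBLUP
vc_ad <- reml_fit(design, list(G, D))   # GBLUP-D
vc_ad
#> GBLUP-D REML fit (4 iterations, logL = -3140.7321)
#>   sigma_a2 = 448.075  sigma_d2 = 157.745  sigma_e2 = 390.841

heritabilities(vc_ad)
#> h2_narrow = 0.450  h2_dominance = 0.158  h2_broad = 0.608  d/(a+d) = 0.260

likelihood_ratio_test(vc_a$logL, vc_ad$logL)
#> LRT: chi2 = 3.0266, boundary-mixture p = 0.04096 (plain 1-df p = 0.08191)
```

The dominance ratio is recovered at its simulated value (0.158), the
narrow-sense heritability within sampling error of 0.42, and the
likelihood-ratio test flags the dominance component at the 5% level.
`mlmm_scan()` then maps individual loci (classifying hits as `A`, `D` or
`A+D` and annotating them against a gene table with the 100 kb
nearest-gene rule), `run_chain()` fits BayesA/BayesAD, `cross_validate()`
compares predictive abilities, and `run_pipeline()` drives all stages from
one YAML configuration, writing a hash manifest for reproducibility.

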