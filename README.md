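# bifactorPRS

Links polygenic risk scores (PRS) to adolescent psychopathology modelled
as latent factors measured by ordinal questionnaire items. The package is
aimed at psychiatric-genetics and psychometrics researchers who want the
full analysis chain — scoring, ordinal confirmatory factor modelling,
reliability, and genetic association with principled sensitivity
analyses — as tested, scriptable R functions, exercised end to end on
synthetic cohorts with known truth.

## The model

Ordinal items $y_j$ (51 items in four instrument blocks: psychotic
experiences, negative dimension, depression, anxiety) are coarsenings of
latent normal responses at thresholds $\tau_j$:

$$y_j^* = \lambda_j^\top \eta + \varepsilon_j, \qquad
\mathrm{Var}(y_j^*) = 1,$$

with four competing structures for $\eta$: uncorrelated block factors, a
unidimensional factor, correlated block factors, and a **bifactor** model
(one general psychopathology factor plus four orthogonal specific
factors). Estimation is limited-information: univariate thresholds, then
pairwise polychoric correlations by maximum likelihood, then diagonally
weighted least squares (the WLSMV convention) with a Satterthwaite
mean-and-variance adjusted chi-square, RMSEA/CFI/TLI, and AIC/BIC/ssaBIC
from the quasi-Monte-Carlo marginal likelihood. Reliability is summarised
by the omega family ($\omega$, $\omega_H$, per-block $\omega_S$,
$\omega_{HS}$).

Genetic exposures are standardized polygenic scores
$\mathrm{PRS}_i = \sum_j g^*_{ij} \hat\beta_j$ over SNPs passing a
discovery P-value threshold $P_T$, with allele harmonization against the
counted allele. The association model is a MIMIC structural model: every
factor regressed simultaneously on the score,

$$\eta_f = \gamma_f\,\mathrm{PRS} + \zeta_f,$$

reported as standardized effects (SD of factor per SD of score) with
sandwich standard errors, max-T step-down permutation-adjusted p-values,
and inverse-probability-weighted (IPW) refits for selective missingness.

## Worked example

Simulate a cohort with a known bifactor truth and a schizophrenia-like
PRS effect, fit the measurement models, and test the association:

```r
library(bifactorPRS)

truth  <- true_model(seed = 42)            # 51 items, 4 blocks, PRS effects
cohort <- simulate_cohort(n = 1500, model = truth, seed = 42)
blocks <- setNames(truth$blocks, truth$item_names)

items <- apply_inclusion_filter(cohort$items_observed, min_per_block = 4)
poly  <- polychoric_matrix(items)
fit   <- fit_dwls(poly, build_model("bifactor", blocks))
compute_fit_indices(fit)
#> RMSEA 0.000 (0.000, 0.013)  CFI 1.000  TLI 1.000  (chi^2 252.39, df 252.6)

compute_omegas(fit)
#> omega = 0.988, omega_H = 0.886
#>   PE: omega_S = 0.952, omega_HS = 0.254
#>   NEG: omega_S = 0.961, omega_HS = 0.274
#>   DEP: omega_S = 0.963, omega_HS = 0.277
#>   ANX: omega_S = 0.969, omega_HS = 0.332

scz <- with(cohort, {
  ss <- select_snps(sumstats$SCZ, 0.05)
  compute_prs(genotypes, harmonize_alleles(ss, genotypes), p_threshold = 0.05)
})
assoc <- fit_structural(items, scz, build_model("bifactor", blocks))
assoc
#> Structural (bifactor) model, n = 1011
#>  outcome   beta    lci    uci      p
#>  GENERAL  0.080 -0.001  0.161 0.0537
#>       PE  0.054 -0.065  0.173  0.372
#>      NEG -0.043 -0.159  0.074  0.473
#>      DEP -0.075 -0.184  0.034  0.176
#>      ANX  0.043 -0.059  0.146  0.407
```

The RMSEA/CFI/TLI line says the bifactor structure fits the polychoric
correlations essentially perfectly (as it must — it generated them). The
omegas say most reliable item variance is general-factor variance
($\omega_H = 0.89$ of $\omega = 0.99$), with much less left to the
specific factors once the general factor is partialled out
($\omega_{HS} \le 0.33$). The association table reads like a regression
table: at this modest sample size the simulated general-factor effect
(truth 0.055) is estimated at 0.080 with a 95% CI of (−0.001, 0.161),
and no specific factor shows an effect beyond the general one — the
generating configuration.

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) chains
all stages — scoring at several thresholds, model comparison with
information criteria, omegas, per-trait associations with permutation
adjustment, and IPW refits — into one provenance-stamped output bundle.

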