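---
title: "Latent psychopathology factors and polygenic risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent psychopathology factors and polygenic risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifactorPRS)
```

## The scientific problem

Adolescent psychopathology is measured with banks of ordinal questionnaire
items — here four instrument blocks indicating psychotic experiences (PE,
ten 3-category items), a negative symptom dimension (NEG, eleven
4-category items), depression (DEP, thirteen 3-category items) and anxiety
(ANX, seventeen items). Symptom domains are strongly comorbid, and raw sum
scores confound shared variance, domain-specific variance and measurement
error. Confirmatory factor models of the ordinal items separate these
components; a *bifactor* structure in particular decomposes every item
into a general psychopathology factor (the "p-factor") plus one of four
orthogonal domain-specific factors.

Polygenic risk scores (PRS) summarize common-variant liability for a
psychiatric disorder as a weighted allele count, with weights from an
external discovery GWAS. Regressing all latent factors simultaneously on a
standardized PRS (a MIMIC structural model) asks whether genetic risk is
manifested as general psychopathology, as domain-specific symptoms, or
both — the substantive question this package's pipeline addresses, with
standardized effects on the order of |beta| = 0.03–0.09 SD of factor per
SD of score.

## Measurement model and estimation

Each ordinal item $j$ with $K_j$ categories is the coarsening of a latent
normal response $y_j^*$ at thresholds $\tau_{j1} < \dots <
\tau_{j,K_j-1}$. We use the *delta* parameterization throughout: $y_j^* =
\lambda_j' \eta + \varepsilon_j$ with $\mathrm{Var}(y_j^*) = 1$, so
loadings are standardized and the residual variance is $1 -
\lambda_j'\Phi\lambda_j$. Four structures are entertained: uncorrelated
block factors, a single unidimensional factor, correlated block factors,
and the bifactor model (general + orthogonal specifics). Factor variances
are fixed at 1 for identification; factor correlations are free only in
the correlated structure.

Estimation is limited-information, in the WLSMV tradition:

1. **Thresholds** from univariate cumulative proportions,
   $\hat\tau_{jk} = \Phi^{-1}(\hat F_{jk})$.
2. **Polychoric correlations** pairwise by maximum likelihood with
   thresholds held fixed (Brent search on $(-0.995, 0.995)$; bivariate
   normal rectangle probabilities via a 48-point Gauss–Legendre rule on
   the arcsin-transformed correlation integral, accurate to ~1e-10).
   Missing data are handled by pairwise deletion; the inclusion filter
   used before association analyses (at least four answered items per
   block) keeps blocks near-complete, which is what makes pairwise
   moments a reasonable basis.
3. **Diagonally weighted least squares**: the free parameters minimize
   $\sum_s w_s\,(r_s - \sigma_s(\theta))^2$ over the non-redundant
   correlations, with $w_s$ the inverse asymptotic variance of each
   polychoric estimate. The minimizer is a Levenberg-damped Gauss–Newton
   iteration with an analytic Jacobian; convergence requires the gradient
   norm to fall below `1e-6` scaled by the mean weight (the objective is
   weighted by inverse sampling variances, so the raw gradient scales
   with them). Communalities are constrained below 1; an item that ends
   at the boundary is reported as a Heywood case with a warning, and a
   stall at an active boundary counts as (constrained) convergence.

### Asymptotic covariance and the adjusted test statistic

The sampling covariance $\Gamma$ of the stacked correlation vector is
estimated from per-observation influence functions. For a two-stage
polychoric estimate the stage-1 threshold error propagates into stage 2;
the influence of an observation in cell $(a,b)$ is
$u_{ab} = (s_\rho(a,b) - T_1(a) - T_2(b))/I_\rho$, where $s_\rho$ is the
correlation score, $I_\rho$ the Fisher information, and $T_1, T_2$ carry
the threshold influences through the cross-information
$I_{\rho\tau}$. For polyserial correlations (item × standardized score)
the same construction additionally propagates the in-sample
standardization of the exposure (location and scale influences). In
simulation these corrections bring the estimator's nominal variance in
line with its sampling variance (ratios within a few percent; a small
higher-order residual remains, making Wald intervals very slightly
anticonservative at the percent level).

The DWLS discrepancy is referred to a Satterthwaite mean-and-variance
adjusted chi-square: with $U = W - W\Delta(\Delta'W\Delta)^{-1}\Delta'W$,
the statistic is rescaled by $c = \mathrm{tr}((U\Gamma)^2) /
\mathrm{tr}(U\Gamma)$ with estimated degrees of freedom
$\mathrm{tr}(U\Gamma)^2/\mathrm{tr}((U\Gamma)^2)$ — deliberately *not*
the naive moment count. Fitting the generating structure in simulation
gives adjusted statistics close to their degrees of freedom. RMSEA uses
$\sqrt{\max(\chi^2 - df, 0)/(df\,n)}$ with $n$ the total weight (the
$n$ vs $n-1$ convention is recorded in the fitted object), and its 90%
interval comes from noncentral chi-square root finding. CFI and TLI use
the independence baseline (free thresholds, zero correlations) fitted to
the same moments.

### Information criteria

AIC, BIC and sample-size-adjusted BIC ($-2\ell + p\ln((n+2)/24)$) come
from the *marginal* ordinal likelihood, integrating the latent factors
out of the conditional category probabilities by randomized quasi-Monte
Carlo: Halton points (bases 2–11) with a seeded Cranley–Patterson
rotation, mapped through the normal quantile function and colored by the
Cholesky factor of the fitted factor correlation. The default 8000
integration points follow common practice for models of this dimension;
model-comparison experiments in the test suite use 2000 points, which is
ample for BIC gaps that run in the hundreds.

A deliberate design choice: the marginal likelihood is **evaluated at the
limited-information (DWLS) estimates**, not re-maximized. Full-information
maximization of ~200 parameters under 4–5-dimensional integration is far
more expensive and, because the DWLS estimates are consistent under the
fitted model, changes the criteria by $O_p(1)$ — negligible against the
between-structure gaps the criteria are used to compare. The parameter
count $p$ is the full count (loadings + thresholds + factor
correlations), so structures differ by the expected amounts (the bifactor
adds one general loading per item; the correlated structure adds the six
factor correlations).

## Reliability

Omega coefficients are computed from the standardized bifactor solution
on the latent-response scale:
$\omega = \frac{(\sum\lambda_g)^2 + \sum_s(\sum_{i\in s}\lambda_s)^2}
{(\sum\lambda_g)^2 + \sum_s(\sum\lambda_s)^2 + \sum(1-\lambda_g^2-\lambda_s^2)}$,
with $\omega_H$ crediting only the general factor, and the per-block
$\omega_S$/$\omega_{HS}$ applying the same algebra to one block's items
($\omega_{HS}$ credits only the block's specific factor). These are
population formulas of the fitted loadings — not sum-score variants — and
satisfy $\omega_H \le \omega$ and $\omega_{HS} \le \omega_S$ by
construction. A caution surfaced by the test suite: adding a *weak*
general-only item (loading below roughly the existing average) can lower
$\omega_H$, because it adds more residual than shared variance;
monotonicity arguments hold only for sufficiently strong items.

## Structural (MIMIC) model

Associations are estimated one exposure at a time by extending the moment
vector with the item–exposure polyserial correlations and the model with
regressions of every factor on the standardized exposure. Factor residual
variances are set to $1-\gamma_f^2$ so factors stay standardized and the
coefficients are directly SD-per-SD; in the bifactor structure the
factors correlate through the shared exposure ($\gamma\gamma'$), which is
the intended MIMIC behavior. Standard errors are sandwich estimates from
the influence-function covariance; Wald 95% intervals and p-values
follow. Exposures are (re)standardized within the analysis sample, so
results are invariant to the input scale of the score.

## Permutation adjustment and IPW

As sensitivity analyses mirroring the main fit:

* **Max-T step-down permutation.** Maximum a posteriori (MAP) factor
  scores (per-respondent Newton mode-finding under the fitted model,
  missing items marginalized) are regressed on the exposure; the exposure
  vector is permuted jointly against all outcomes, preserving the
  inter-factor correlation, and each observed |t| is compared to the
  permutation distribution of the running maximum (Westfall–Young
  step-down) with $p = (1+\#\mathrm{exceedances})/(1+B)$ and enforced
  monotonicity. The family is the set of factor outcomes for one
  exposure; the scheme is seeded and bit-reproducible. Because the
  procedure is valid conditional on any fixed scoring rule, the
  family-wise error calibration experiment scores respondents under the
  generating model, which keeps 200-dataset calibration runs affordable.
* **Inverse-probability weighting.** A logistic model of inclusion on
  auxiliary covariates (observed for included and excluded respondents)
  yields weights $1/\hat p$ for the included, truncated by default at
  the 99th weight percentile (flagged). All estimating equations —
  thresholds, polychoric and polyserial likelihoods, and the influence
  functions behind the standard errors — are case-weighted; weights are
  normalized to mean 1, making the fit invariant to rescaling, and unit
  weights reproduce the unweighted fit exactly. Missingness in the
  generator is missing-at-random given the covariates (never the latent
  factors directly), so IPW is a consistent correction by construction.

## The synthetic-data generator

The generator is first-class, tested code that emulates the study's
structure so every stage is testable offline:

* **Items**: 51 items in blocks of 10/11/13/17 with 3/4/3/3 categories.
  The anxiety instrument's response format is configurable (default 3
  categories) because such semi-structured instruments vary; this is the
  one structural quantity we fixed by choice rather than by source.
* **Loadings**: general loadings jittered uniformly in 0.5–0.8 and
  specific loadings in 0.3–0.6 (communality capped at 0.95), spanning the
  strong-general/weaker-specific pattern typical of adolescent
  psychopathology batteries. Thresholds imply skewed symptom marginals
  (roughly 70%/22%/8% for 3-category items).
* **Genotypes**: unlinked biallelic SNPs under Hardy–Weinberg with MAF
  uniform in (0.05, 0.5), split into one panel per discovery trait;
  simulated discovery weights N(0, 0.08) with a 30% "associated" P-value
  mixture so thresholding is meaningful. No linkage disequilibrium,
  relatedness or population structure is simulated — so the generator
  cannot exercise clumping, ancestry adjustment, or stratification
  robustness, and passing tests say nothing about those aspects of real
  data.
* **PRS effects**: the default factor-by-trait effect matrix uses small
  standardized values (|beta| 0.001–0.071, e.g. schizophrenia-PRS on the
  general factor 0.055) of the magnitude reported in adolescent-cohort
  studies.
* **Missingness**: sex (Bernoulli 0.5) and a family-background score
  correlated −0.4 with the general factor drive a logistic inclusion
  model (default intercept 0.6, sex 0.4, background 0.5: roughly
  three-quarters included, skewing female and advantaged), plus 2%
  sporadic item-level missingness.

Orthogonal specific factors are simulated (the standard bifactor
identification), which makes the omega algebra exact; a residual factor
correlation matrix can be supplied to generate correlated-factors truths.

## Problem sizes and numerical choices

The test and acceptance experiments run at deliberately chosen scales:
measurement recovery at n = 3000 (20 replicates), model selection at
n = 2000 with 2000 integration points (20 replicates), structural
recovery and coverage at n = 3000 (50 replicates), permutation
family-wise error at n = 500 with 200 permutations (200 datasets), and
IPW bias reduction at n = 5000 in 50 paired replicates. The IPW
experiment needs care: a gentle selection mechanism leaves the
*standardized* coefficient almost unbiased (restandardization of the
factor largely cancels the covariance shrinkage), while a very sharp one
produces extreme weights whose noise swamps the comparison (and under
quantile truncation the weight tail grows with n). The design therefore
uses inclusion `plogis(2u)` on a covariate correlated 0.95 with the
general factor, an exposure effect of 0.3, and the default
99th-percentile weight truncation — strong enough that the selection
bias (about −0.06 on the standardized coefficient) dominates the
IPW-versus-unweighted difference noise (about 0.016) while keeping the
weights bounded. Truncation deliberately trades a little residual bias
for variance; the weighted estimate recovers roughly half the bias
here, and the paired error comparison is what the experiment measures.

Other numerical choices: polychoric search bound 0.995 and Brent
tolerance 1e-7; asymptotic variances floored at 1e-10 before inversion
into DWLS weights; QMC nodes clamped away from 0/1 before the quantile
transform; MAP scoring Newton iterations capped at 100 with step
halving and a gradient tolerance of 1e-8; permutation p-values use the
add-one convention $(1+\#)/(1+B)$, so they are bounded below by
$1/(B+1)$.

## Known limitations

* The polychoric/polyserial machinery assumes an underlying (bivariate)
  normal latent response; violations (e.g. skewed latent liabilities)
  bias the correlations and everything downstream.
* Wald intervals inherit a small (<~5%) residual underestimate of
  variance from higher-order two-stage effects; the permutation path is
  exact under exchangeability and is the recommended confirmatory check.
* The scoring module implements thresholding, harmonization and
  mean-imputation of missing dosages, but no linkage-disequilibrium
  clumping (an optional concern out of scope here) and no ancestry
  adjustment.
* Information criteria evaluated at limited-information estimates are
  suited to comparing structures, not to reporting absolute likelihood
  values to publication precision.
* MAP factor scores are shrunken (regression of scores on true factors
  has slope < 1, about 0.8 for the well-determined general factor at the
  default loadings); analyses that need unattenuated coefficients should
  use the one-step structural model, as the main path here does.
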