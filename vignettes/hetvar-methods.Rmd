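---
title: "Methods: models, priors and numerical choices in hetvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, priors and numerical choices in hetvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hetvar` tests whether a covariate is associated with the *variance* of a
quantitative trait. This vignette is the package's own account of the
statistical machinery: the model behind the Bayesian test, the comparison
tests, the permutation-based FDR calibration, the simulation families, the
distribution classifier, and the numerical conventions that a maintainer or
a careful user should know about. It states no empirical claims beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## The heteroskedastic trait model

For a trait vector $y \in \mathbb{R}^n$ and a covariate $x \in \mathbb{R}^n$
(genotype copy number in $\{0,1,2\}$, an imputed dosage in $[0,2]$, or any
binary/continuous covariate), the ideal model is

$$y_i \sim \mathcal{N}\!\left(\beta_0 + \beta x_i,\; \sigma^2
\alpha^{-x_i}\right).$$

$\beta$ is the mean effect; $\alpha$ is the heteroskedastic effect. At
$\alpha = 1$ the variance does not depend on the covariate. The exponential
form $\sigma^2 \alpha^{-x_i}$ makes the variance a *monotone* function of
the covariate, which buys power for ordered covariates (dosages, age) at
the cost of not representing non-monotone group-variance patterns.

### Priors and hyperparameters

| parameter | prior | default | role |
|---|---|---|---|
| $\beta_0$ | flat (improper) | — | intercept |
| $\beta$ | $\mathcal{N}(0, 1/\gamma)$ | $\gamma = 1$ | mean effect, marginalized in closed form |
| $\sigma^2$ | $\mathrm{InvGamma}(\theta_1, \theta_2)$ | $\theta_1 = 1,\ \theta_2 = 2$ | residual variance |
| $\log\alpha$ | $\mathrm{Cauchy}(x_0, \nu)$ | $x_0 = 0,\ \nu = 5$ | variance effect; heavy tails keep large effects plausible |

The flat intercept prior appears in both the numerator and denominator of
the Bayes factor, so its improper normalizing constant cancels; individual
`log_marginal` values from `laplace_log_marginal()` are defined only up to
that shared constant and are never calibrated evidence on their own.

### The Bayes factor

`bth_bayes_factor()` reports

$$\log_{10} \mathrm{BF} = \log_{10}
\frac{\Pr(y \mid x, H_A: \alpha \neq 1)}{\Pr(y \mid x, H_0: \alpha = 1)},$$

with the null a *point* null at $\alpha = 1$, not a narrow prior. Because
$\beta$ is integrated out under both hypotheses, the test addresses the
union of "weak" and "strong" hypotheses: it is designed to ignore pure mean
effects and respond only to variance structure.

Computation proceeds in two stages:

1. **Closed-form marginalization of $\beta$**
   (`log_marginal_beta_integrated()`). With observation weights
   $w_i = \alpha^{x_i}/\sigma^2$, Gaussian conjugacy gives the integral
   over $\beta$ analytically; this is exact.
2. **Laplace approximation over $(\beta_0, \log\sigma^2, \log\alpha)$**
   (`laplace_log_marginal()`). The objective adds the $\sigma^2$ prior
   (with the $\sigma^2 \to \log\sigma^2$ Jacobian) and, under $H_A$, the
   Cauchy prior on $\log\alpha$. Working on log scales removes positivity
   constraints without barrier terms. The marginal likelihood is
   $g(\hat\theta) + \tfrac{d}{2}\log 2\pi - \tfrac12 \log\det(-H)$ with
   $d \in \{2, 3\}$ free parameters.

### Numerical choices in the Laplace fit

* Optimizer: BFGS with deterministic starts — OLS intercept, log OLS
  residual variance, $\log\alpha = 0$ — followed by Newton polishing using
  a central finite-difference Hessian (per-coordinate step
  $10^{-4}\max(1, |\theta_j|)$). Up to three deterministic perturbed
  restarts are tried if the gradient has not collapsed.
* Convergence is declared at gradient max-norm $\leq 10^{-5}$. A tighter
  tolerance is not meaningful here: with finite-difference gradients on an
  objective of magnitude $O(n)$, the attainable accuracy floor sits near
  $10^{-6}$–$10^{-7}$.
* Everything is deterministic, so repeated calls on the same data agree to
  $10^{-10}$; joint reordering of $(x_i, y_i)$ pairs changes results only
  through floating-point summation order (below $10^{-6}$).
* Non-positive-definite curvature at the mode is jittered and flagged
  `converged = FALSE`; such fits are excluded from FDR calibration by
  default rather than silently trusted.

The test suite validates the two-stage computation against an independent
oracle that marginalizes *both* $\beta_0$ and $\beta$ analytically through
the $2\times 2$ weighted least-squares system and integrates
$(\log\sigma^2, \log\alpha)$ by nested adaptive quadrature; across small
datasets spanning the simulation grid the two agree to better than 0.1
$\log_{10}$ units.

## Comparison tests

* **Levene / Brown-Forsythe** (`levene_family_test()`): the classical
  ANOVA-on-absolute-deviations statistic
  $W = \frac{(n-k)\sum_t n_t(\bar z_t - \bar z)^2}
  {(k-1)\sum_t\sum_s (z_{ts} - \bar z_t)^2}$, with group means (Levene) or
  medians (Brown-Forsythe) as centres, referred to $F(k-1, n-k)$. The
  group-size weights $n_t$ in the numerator are what make the statistic
  F-distributed under the null; the suite cross-checks against
  `car::leveneTest`. These tests need categorical covariates and make no
  monotonicity assumption.
* **Bartlett** (`bartlett_test()`): pooled-variance chi-square test,
  delegated to `stats::bartlett.test`; sensitive to non-normality, included
  for comparison.
* **CLS** (`cls_test()`): Spearman rank correlation between squared OLS
  residuals and the covariate. The p-value uses the $t$ approximation on
  $n-2$ degrees of freedom with average ranks for ties; for $n < 10$ the
  exact permutation distribution is enumerated. As a two-stage procedure it
  carries no uncertainty from the first stage — the motivation for BTH.
* **dglm** (`dglm_test()`): alternating estimation of a Gaussian mean model
  (weighted least squares, weights = reciprocal fitted dispersions) and a
  gamma GLM with log link for the dispersion (response = squared mean-model
  residuals, linear predictor $\lambda_0 + \lambda_1 x$, prior weights
  $\tfrac12$ — the classical adjustment for the degrees of freedom absorbed
  by the mean fit), iterated until the fitted Gaussian log-likelihood
  changes by less than $10^{-8}$ (at most 50 iterations). The test is the
  likelihood ratio $2(\ell_{\lambda_1 \text{ free}} - \ell_{\lambda_1=0})$
  on a $\chi^2_1$ reference. The algorithm is this package's own
  implementation of the standard double-GLM scheme and is validated by its
  calibration properties (null p-value uniformity), not by matching any
  other software's internal step sizes. Non-convergence is reported, not
  hidden; it concentrates at low minor allele frequency.

Degenerate inputs follow fixed conventions so that FDR machinery never
receives missing values: all-tied deviations or residuals give statistic 0
with p-value 1; categorical-only tests *refuse* continuous covariates
rather than rounding them (an explicit `round_dosage()` exists for
idealized simulations).

## Permutation nulls and FDR calibration

`mean_preserving_permutation()` fits $y = \beta_0 + \beta x$ by least
squares, permutes the residuals, and re-adds the fitted values. This keeps
mean effects and destroys variance effects — exactly the null needed for a
test that should ignore mean structure. Each candidate permutation must
pass a two-sided slope t-test of the permuted residuals on $x$ at
$p \geq 0.10$ (at most 100 redraws, then accept with a warning). The
"generalized least squares" fit of the original formulation is ordinary
least squares here: no residual covariance structure is ever specified, so
the two coincide.

`estimate_fdr()` implements
$\widehat{\mathrm{FDR}}(t) = \#\{\text{perm} > t\} / \#\{\text{real} > t\}$
(0 when there are no discoveries); `calibrate_threshold()` scans the
observed scores for the smallest threshold with estimated FDR at or below
the nominal level; `maf_stratified_fdr()` repeats the calibration within
MAF bins (default edges 0.05, 0.1, 0.2, 0.3, 0.5 — a conventional choice,
as no canonical binning exists). Signed Bayes factors are compared by
absolute value; p-value methods enter as $-\log_{10} p$ so that larger
always means more significant. Permutation-based FDR estimates are
conservative by construction; the suite checks that the realized
false-discovery proportion at a calibrated 0.05 threshold stays below 0.10
on a mixed alternative/null suite.

## The simulation families

`sim_config()` / `simulate_dataset()` generate covariates — discrete
genotypes $x_i \sim \mathrm{Bin}(2, \pi_{maf})$, imputed dosages from a
clipped normal mixture ($c_0, c_2 \sim \mathcal{N}(0, 0.5)$,
$c_1 \sim \mathcal{N}(1, 0.5)$, second parameter read as the *variance*),
binary and uniform continuous covariates — and traits from five families:

* **ideal**: the BTH model itself;
* **additive_variance**: $\mathcal{N}(\beta_0 + \beta x_i, \sigma^2 + a
  x_i)$. Its null is $a = 0$, so for this family the `log_alpha`
  configuration field is read directly as $a$ — keeping "`log_alpha = 0`
  $\iff$ no variance effect" uniform across families;
* **log_gaussian**: the exponential of an ideal draw (variance rises with
  the mean, so mean effects masquerade as variance effects);
* **gamma**: $y_i \sim \mathrm{Gamma}(\text{shape} = \mu_i,
  \text{scale} = 1)$ with $\mu_i = 1/(\beta_0 + \beta x_i)$, i.e. mean and
  variance both $\mu_i$ — the continuous analogue of overdispersed Poisson
  counts, as in RNA-seq-like traits. This parameterization (rather than an
  exponential with mean $\mu_i$) is what makes the square root the
  family's variance-stabilizing transformation, which the prescriptive
  transform machinery relies on;
* **bimodal**: a $\lambda$-mixture of $\mathcal{N}(10, 1)$ with an ideal
  component ($\lambda = 0.4$ by default) — the signature of epistatic
  interactions.

Every suite pairs each replicate with one mean-preserving permutation null,
and all randomness flows through counter-derived sub-stream seeds
(`seed_stream()`), so suites are bitwise reproducible regardless of
generation order. The default parameter grid
(`default_parameter_grid()`) spans $n \in \{300, 500, 1000\}$,
$\pi_{maf} \in \{0.05, 0.2, 0.3\}$, $\beta \in \{0, 0.2, 0.5, 1\}$,
$\log\alpha \in \{-0.2, -0.1, 0, 0.1, 0.2\}$, $\beta_0 \in \{0, 1\}$ with
$\sigma^2 = 1$ — sample sizes, frequencies and effects typical of current
eQTL studies.

What the generator does *not* emulate: linkage disequilibrium, multi-locus
genotypes, relatedness structure, missing data and measurement batch
effects. Passing the simulation suites therefore demonstrates correctness
and calibration under independent covariates and clean trait models, not
robustness to every pathology of real cohorts.

## Hypothesis taxonomy and prescriptive transformations

Scenarios are labelled by the four combinations of mean and variance
effects: strong null ($\beta = 0, \log\alpha = 0$), weak null
($\beta \neq 0, \log\alpha = 0$), weak alternative
($\beta = 0, \log\alpha \neq 0$) and strong alternative (both non-zero).
The weak null is the dangerous case: in log-Gaussian and gamma traits the
variance is a function of the mean, so a pure mean effect *looks*
heteroskedastic to every test.

The distribution classifier (`build_training_set()`,
`train_classifier()`, `classify_and_recommend()`) addresses this: a trait
sample is represented by one-sided KS statistics
($D^+ = \sup_t \mathrm{ECDF}_{query} - \mathrm{ECDF}_{ref}$; the one-sided
statistic is deliberately asymmetric, recording where the query puts excess
mass) against 79 reference densities moment-matched to the sample, and a
random forest maps this feature vector to one of seven trait families. The
79 defaults span Gaussian, Student-t, lognormal, gamma, beta, uniform,
Laplace and two-component Gaussian-mixture shapes; the classifier contract
depends on the bank's size and moment matching, not on the identity of the
densities, which is configurable. The "exponential mean" and "exponential
residual" classes are this package's conventions: Gaussian noise around an
exponentiated linear predictor, and centred exponential residuals with the
ideal variance function, respectively. Training uses 50 samples per class
per $(\beta, \log\alpha)$ zero/non-zero cell with five-fold stratified
cross-validation.

Predicted log-Gaussian traits get a log transform; predicted gamma traits
get a mean-centred square root; everything else is left alone. The suite
verifies the point of the exercise: on weak-null log-Gaussian data the
untransformed Bayes factor shows spurious signal (PR-AUC well above 0.5
against permutation nulls), and after the log transform every test drops
back to chance level.

## Benchmarking conventions

`run_benchmark()` scores suites with every method under one orientation
(log10 BF for BTH, $-\log_{10} p$ otherwise) and evaluates
real-versus-permutation discrimination by precision-recall curves with tied
scores grouped at single thresholds; `auc` integrates precision over recall
by trapezoid, `average_precision` accumulates precision at newly recalled
positives. Real (non-permutation) replicates are the positive class; under
a null configuration a calibrated method therefore sits at PR-AUC
$\approx 0.5$, and spurious sensitivity shows up as PR-AUC above 0.5 on
weak-null suites. Non-converged dglm fits score 0 (no evidence) so all
methods face identical label sets, with convergence rates reported
alongside. Bootstrap intervals for AUC differences resample datasets, not
score pairs.

Problem sizes used by the heavyweight suite checks: 500 strong-null
replicates for calibration, 300 replicates per configuration for power
orderings and grid monotonicity, 1000 replicates (the per-configuration
count of the simulation design) for the headline method comparison in
`scripts/acceptance.R`, and 20 small datasets for the quadrature-oracle
comparison.

## Preprocessing for variance-effect testing

Variance testing is more sensitive to distributional artifacts than mean
testing, so `preprocess_expression()` applies, in order: log2; genotype
PCs by SVD (population structure); per-gene least-squares residualization
on known covariates plus genotype PCs with mean-centring; expression PCs
of the residual matrix and a second residualization (latent confounders).
The order — known covariates and genotype PCs first, expression PCs
estimated from the residuals — is a committed convention of this package.
`quantile_normalize()` then maps each gene to standard-normal quantiles
$\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties. All genomic
coordinates in the cis-pairing utilities are 1-based inclusive, with
distances measured to the nearest interval edge and window boundaries
included.

## Known limitations

* The Laplace approximation is accurate for the posteriors arising at the
  grid's sample sizes ($n \geq 30$ in the oracle checks); very small $n$ or
  covariates with almost no variation can degrade it, and constant
  covariates are rejected outright.
* One covariate per test; no joint multi-covariate model, no MCMC.
* `dglm` instability at low MAF is inherited from its iteratively
  reweighted fits; failures are flagged, scored as "no evidence" in
  benchmarks, and excluded from calibration.
* Permutation FDR estimates are conservative; with a single permutation per
  test the FDR curve is itself noisy at very small discovery counts.
* The square root stabilizes the gamma family's variance only to first
  order: exactly, $\mathrm{Var}(\sqrt{y}) = \mu -
  (\Gamma(\mu + \tfrac12)/\Gamma(\mu))^2$, which still drifts with the mean
  at small shapes. On transformed gamma weak-null traits the most sensitive
  tests (BTH, Brown-Forsythe) can therefore retain weak residual signal
  slightly above chance level — a property of the family, not a test
  artifact.
* A covariate with fewer than a handful of minor-allele carriers leaves the
  variance effect essentially unidentified (the likelihood is flat in
  $\log\alpha$, so the posterior inherits the Cauchy prior's tails and the
  Laplace approximation degrades). Such variants should be filtered out by
  the MAF threshold before testing, as is standard.
* The classifier's reference bank is a default, not an identification of
  any canonical density list; its accuracy target is "useful for choosing a
  transformation", not taxonomic certainty.
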