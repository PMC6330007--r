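# hetvar — detecting variance effects on quantitative traits

Most association methods in quantitative genetics look for *mean* effects:
covariates (genotypes, sex, age, BMI, ...) that shift the average value of a
trait. A covariate can instead — or additionally — change the *variance* of
the trait. Such variance QTLs (vQTLs) and variance-controlling covariates
signal epistasis, gene-by-environment interaction and canalization, and they
matter in medical genetics wherever disease risk is a tail probability of a
phenotype. Detecting them is a heteroskedasticity testing problem, and naive
tests produce hundreds of spurious hits on real genomic data.

`hetvar` is an R toolkit for this problem, built for statistical geneticists
and methodologists. It provides:

* **BTH**, a Bayesian test for heteroskedasticity. The trait is modelled as

  ```
  y_i ~ N(beta0 + beta * x_i,  sigma^2 * alpha^(-x_i))
  ```

  with priors `beta ~ N(0, 1/gamma)`, `sigma^2 ~ InvGamma(theta1, theta2)`,
  `log(alpha) ~ Cauchy(x0, nu)` and a flat prior on `beta0`. The test
  reports the base-10 log Bayes factor comparing `alpha != 1` (variance
  effect) against the point null `alpha = 1`:

  ```
  BF(y, x) = Pr(y | x, H_A: alpha != 1) / Pr(y | x, H_0: alpha = 1)
  ```

  The mean effect `beta` is marginalized in closed form by Gaussian
  conjugacy; the remaining parameters `(beta0, log sigma^2, log alpha)` are
  integrated by a Laplace approximation around the posterior mode. Because
  the test integrates over all mean effects, it is robust to large `beta`,
  and it accepts discrete *and* continuous covariates (dosages, age, BMI).

* **Comparison tests** under one result contract: Levene and Brown-Forsythe
  (ANOVA on absolute deviations from group means/medians), Bartlett,
  CLS (Spearman correlation between squared regression residuals and the
  covariate) and an iterative double-GLM (`dglm`) dispersion test.

* **Mean-effect-preserving permutation FDR**: residuals of the trait
  regression are permuted and re-added to the fitted values, destroying
  variance effects while keeping mean effects; the false discovery rate at a
  score threshold `t` is estimated as `#{perm > t} / #{real > t}`, globally
  or stratified by minor allele frequency.

* **A trait simulator** for the ideal heteroskedastic model and four
  non-ideal families (additive variance, log-Gaussian, gamma, bimodal
  mixture), with discrete, imputed-dosage, binary and continuous covariates.

* **A trait-distribution classifier** (random forest over one-sided
  Kolmogorov-Smirnov feature vectors against a bank of 79 moment-matched
  reference densities) that recommends prescriptive transformations — log
  for log-Gaussian traits, mean-centred square root for gamma traits — to
  remove spurious variance signal caused by mean-variance coupling.

* **A precision-recall benchmarking harness** comparing all tests across
  simulation grids, plus expression preprocessing utilities (log2,
  PC-based confounder control, residualization, quantile normalization) and
  cis-pairing / MAF filtering for genome-scale runs.

## Worked example

Simulate one discrete-genotype dataset with a strong variance effect
(`n = 1000`, MAF 0.3, mean effect 0.5, `log alpha = 0.5`) and test it:

```r
library(hetvar)
cfg <- sim_config(n = 1000, pi_maf = 0.3, beta = 0.5, log_alpha = 0.5,
                  covariate_kind = "discrete")
ds <- simulate_dataset(cfg, seed = 42)
run_test("bth", ds$y, ds$x)
#> <het_test:bth> log10 BF = 6.2717 (n = 1000)
run_test("brown_forsythe", ds$y, ds$x)
#> <het_test:brown_forsythe> statistic = 17.4628, p = 3.514e-08 (n = 1000)
run_test("dglm", ds$y, ds$x)
#> <het_test:dglm> statistic = 37.4857, p = 9.209e-10 (n = 1000)
run_test("cls", ds$y, ds$x)
#> <het_test:cls> statistic = -0.1634, p = 2.057e-07 (n = 1000)
```

A log10 Bayes factor of 6.27 is overwhelming evidence for a variance
effect; all classical tests agree here. Benchmark BTH on 100 replicates of
this configuration paired with 100 permutation nulls, and calibrate a
discovery threshold at FDR 0.05:

```r
suite  <- generate_benchmark_suite(cfg, reps = 100, seed = 42)
labels <- !vapply(suite, `[[`, TRUE, "is_permutation_null")
scores <- vapply(suite, function(d) score_dataset(d, "bth")$score, 1)
precision_recall(scores, labels)
#> <pr_curve> AUC = 1.0000, AP = 1.0000 (100+/100-)
calibrate_threshold(scores[labels], scores[!labels], level = 0.05)
#> <calibrated_threshold> level=0.05 d_fdr=-1.15 discoveries=100
```

At this effect size the Bayes factor separates real from permuted suites
perfectly (PR-AUC 1.0), and the permutation-calibrated threshold recovers
all 100 real replicates.

A command-line wrapper with `simulate`, `test`, `fdr`, `classify`,
`benchmark` and `preprocess` subcommands is installed as `exec/hetvar`; see
`?hetvar_cli`.

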