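---
title: "Reference effect measures for cluster variation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference effect measures for cluster variation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remvar)
```

## The model and its assumptions

`remvar` works with two-level designs: subjects $j = 1, \dots, n_i$ nested
in clusters $i = 1, \dots, N$. The headline case is mixed logistic
regression for a binary outcome,

$$Y_{ij} \mid p_{ij} \sim \mathrm{Bin}(1, p_{ij}), \qquad
  \mathrm{logit}(p_{ij}) = L_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_i,
  \qquad u_i \sim N(0, \sigma_u^2),$$

with the covariate vector partitioned into subject-level columns
$\mathbf{x}_{sij}$ and cluster-level columns $\mathbf{x}_{cij}$
(cluster-level columns must be constant within each cluster, which the
data container enforces at load). The random intercept $u_i$ captures
unexplained between-cluster variation — the general contextual effect
(GCE). Poisson (log link) and normal (identity link) outcomes are
supported by swapping the conditional likelihood kernel; results are then
rate ratios or mean differences rather than odds ratios.

Because the odds ratio between two subjects with identical covariates in
different clusters is $\exp(L^* - L)$, covariates subtract out, and a
subject in a cluster at the $100a$ percentile of the random-effect
distribution versus a median cluster has

$$\mathrm{REM}_u(a) = \exp(\sigma_u \Phi^{-1}(a)).$$

This is the reference effect measure. Three consequences the package
relies on throughout: $\mathrm{REM}_u(0.5) = 1$ identically;
$\mathrm{REM}_u(a)\,\mathrm{REM}_u(1-a) = 1$ (log-scale symmetry for
normal effects); and a covariate coefficient $\beta_k$ is equivalent to
being at the $100\,\Phi(\beta_k/\sigma_u)$ percentile cluster. A $95\%$
REM *range* $[\exp(-1.96\sigma_u),\ \exp(1.96\sigma_u)]$ encloses the
middle 95% of the distribution of such odds ratios; it is a description
of heterogeneity, not a confidence interval, and the reporting code keeps
the two visually distinct (ranges in square brackets, CIs in round
brackets).

### Variation from sets of covariates

For a covariate subset $s$, the empirical distribution of the observed
contributions $\{\mathbf{x}_{sij}'\hat{\boldsymbol\beta}_s\}$ plays the
role of the random-effect distribution. Centering at its median (i.e.
comparing with a median-risk subject),

$$\mathrm{REM}_{\{x'\beta\}}(a) =
  \exp\left(F^{-1}(a) - F^{-1}(0.5)\right),$$

where $F^{-1}$ is the empirical quantile function. Wider ranges mean the
set carries more of the outcome variation, on the same scale as the GCE,
so the two can be compared directly.

**Quantile convention.** The empirical quantile estimator is the linear
interpolation between order statistics (`stats::quantile` type 7, R's
default), configurable through the `type` argument of `risk_dist()`. The
choice is immaterial at realistic sample sizes (thousands of subjects)
but visible in tiny examples; the unit tests freeze hand-computed type-7
values, e.g. values $\{0, 0, \log 2, \log 2\}$ give
$F^{-1}(0.975) = \log 2$, $F^{-1}(0.5) = \tfrac12\log 2$, hence
$\mathrm{REM}(0.975) = \sqrt 2$. Note the median-centering matters here:
conventions that skip it (or use an inverse-ECDF median of 0) would
report 2 instead.

**Centering for non-normal random effects.** Every
`ranef_dist` family is median-centered so that `quantile(0.5) = 0` and
$\mathrm{REM}(0.5) = 1$ by construction. For log-Gamma effects
($u = \log G$, $G \sim \Gamma(k, k)$, mean 1 — the parameterization under
which the Poisson marginal is negative binomial) the median of $\log G$
is subtracted; the shape $k$ is configurable. User-supplied quantile
functions are centered automatically.

### Comparison measures

- **MOR** $= \exp(\sqrt 2\,\sigma_u\,\Phi^{-1}(0.75))$: the median odds
  ratio between the higher- and lower-risk member of two randomly drawn
  clusters. The identity $\mathrm{MOR} =
  \mathrm{REM}_u(\Phi(\sqrt 2\,\Phi^{-1}(0.75))) \approx
  \mathrm{REM}_u(0.83)$ is verified to $10^{-12}$ across a grid of
  $\sigma_u$ in the tests.
- **PerSD** $= \exp(\sigma)$, the effect of a one-SD shift, equal to
  $\mathrm{REM}_u(\Phi(1))$; applicable to $\sigma_u$ or to the SD of an
  empirical covariate distribution.
- **Latent-scale ICC** $= \sigma_u^2 / (\sigma_u^2 + \pi^2/3)$, from the
  latent-logistic-error representation. Other ICC definitions for binary
  outcomes (probability-scale variants) exist and can differ markedly;
  only the latent-scale formula is implemented.
- **IOM**: $\mathrm{logit}^{-1}(x'\beta + \sigma_u\Phi^{-1}(a))$, the
  outcome probability for a fixed covariate pattern across the cluster
  distribution. Implemented for the logit link only, since its purpose is
  the probability scale; its range width depends on the covariate
  pattern, which is exactly why REM is preferred for comparisons.
- `sigma_from_rem()` inverts $\mathrm{REM}_u(a)$ for $\sigma_u$, which
  makes reports reproducible when only a REM value at a known percentile
  was published.

**Boundary convention.** When $\hat\sigma_u$ is at the zero boundary
(reported as $< 10^{-6}$ with a `boundary` flag), all random-effect
measures collapse to their null values (REM $=$ MOR $=$ PerSD $= 1$,
ICC $= 0$) with a warning rather than an error; percentile equivalence is
undefined there and errors.

## Estimation

The fitter maximizes the marginal likelihood, integrating each cluster's
likelihood over $u_i$ with *adaptive* Gauss–Hermite quadrature: per
cluster, the integrand's mode $\hat u_i$ and curvature are found by a
vectorized Newton iteration, the quadrature rule is recentred and
rescaled there, and the nodes' contributions are accumulated on the log
scale. Default `n_quad = 15` nodes balance accuracy and cost for binary
outcomes; the tests check both that the log-likelihood is stable in the
node count (15 vs 25 agree to at least 5 significant digits) and that it
matches a dense brute-force trapezoid integration (10,000 points over
$\pm 8\sigma$) to $10^{-4}$ relative error. Nodes and weights come from
the Golub–Welsch eigendecomposition of the Jacobi matrix.

Numerical choices worth knowing:

- $\sigma_u$ is optimized as $\log\sigma_u$ to enforce positivity; the
  reported SE is back-transformed by the delta method. Below
  $\sigma_u = 10^{-6}$ the per-cluster integral is replaced by its exact
  pooled limit, which keeps the objective smooth through the boundary.
- Optimization is quasi-Newton (BFGS) with numerically differenced
  gradients, with one automatic restart if the iteration cap is reached
  (this happens on the flat $\log\sigma_u$ ridge of boundary fits).
  Convergence is declared on the gradient max-norm at the optimum,
  scaled by the log-likelihood magnitude
  ($10^{-5}\max(1, |\ell|)$ — numerically differenced gradients cannot
  resolve below roughly $|\ell|\sqrt{\varepsilon}$), together with
  `optim`'s relative-change criterion (`reltol = 1e-12`). Line-search
  excursions to absurd variances are repelled by a sloped penalty above
  $\log\sigma_u = 12$; the warm-started Newton mode search restarts cold
  if it was left stranded by such an excursion.
- Standard errors come from the inverse observed information (numeric
  Hessian) at the optimum; the joint covariance of
  $(\hat\beta, \hat\sigma_u)$ is exposed for delta-method work
  downstream.
- Starting values: a single-level GLM for $\beta$ and
  $\sigma_u = 0.3$, unless supplied. Singular designs error with the
  names of the collinear columns; a single cluster errors
  ($\sigma_u$ unidentifiable).
- The normal family carries a residual SD parameter and has a
  closed-form marginal likelihood, which the test suite uses as an
  internal cross-check; Poisson supports an offset column.

An independent implementation (`lme4::glmer` with matched `nAGQ`) is used
in the test suite as a cross-check oracle on small fixtures; estimates
agree to $10^{-4}$ and log-likelihoods to $10^{-6}$ there.

## Confidence intervals

**Delta method.** For $\mathrm{REM}_u(a)$ the interval is
$\exp\{(\hat\sigma_u \pm z\,SE(\hat\sigma_u))\,\Phi^{-1}(a)\}$ — the only
parenthesization under which it is a CI for
$\exp(\sigma_u\Phi^{-1}(a))$. The lower $\sigma_u$ bound is truncated at
0 before transforming, and for $a < 0.5$ (where the transform is
decreasing) the endpoints are swapped so `low <= high`. Intervals at $a$
and $1-a$ are exact reciprocal pairs. Wald intervals on variance
components can be poor when the sampling distribution is skewed; the
bootstrap below is the alternative.

**Cluster bootstrap.** Whole clusters are resampled with replacement
(each sampled cluster keeps all its subjects, duplicates get fresh ids),
the model is refitted per replicate — warm-started at the full-data
estimates, with a lighter quadrature (7 nodes by default) since replicate
noise dominates — and a percentile interval is formed. Only the cluster
level is resampled: that is what preserves the two-level dependence; a
clusters-then-subjects scheme would add within-cluster noise the model
treats as binomial anyway. Non-converged replicates are dropped and
counted, with an error above a 20% failure rate. Percentile endpoints use
order statistics (type-1 quantiles) so intervals are exactly equivariant
under monotone transformations of the statistic, a property the tests
assert. The seed is mandatory: identical seeds give identical intervals.
Default `n_boot = 1000`; below 50 a warning is issued.

The CI method for percentile equivalents $\Phi(\beta_k/\sigma_u)$ is the
cluster bootstrap by default, with a delta-method alternative
propagating the joint covariance of $(\hat\beta_k, \hat\sigma_u)$; on
well-behaved fixtures the two agree to within a few percentiles, which
the tests check.

## The synthetic-data generator

`make_dataset()` draws cluster intercepts by inverse-CDF sampling from
the design's (median-centered) random-effect distribution, covariates
per their specs (Bernoulli or normal, at subject or cluster level), and
outcomes from the family's conditional distribution. True $u_i$ are
returned *alongside*, never inside, the analysis table, so the analysis
path only sees what a real study would. Cluster sizes are fixed or
Poisson-distributed (truncated at 2).

`make_af_like_fixture()` is a fixed design echoing a procedure-use study:
60 clusters of Poisson-mean-60 subjects; four subject-level risk factors
(a continuous age-like score and three binary comorbidity-like factors
with coefficients between $-0.36$ and $0.41$) whose combined risk
distribution is wide; two weak cluster-level characteristics (narrow
distribution); and $\sigma_u = 0.5$, comparable to the combined subject
factors. The intercept ($-2.16$) was calibrated once by simulation so
the overall event rate is near 14.6%, and then frozen. What the fixture
does *not* emulate: confounding between covariates and cluster
membership (covariates are drawn independently of $u_i$), informative
cluster size, non-linear covariate effects, and within-cluster covariate
imbalance — so passing tests demonstrate correctness of the estimators
under the model, not robustness to those real-data features.

## Problem sizes used by the test suite

Chosen to make the Monte-Carlo checks informative while keeping the
default run short: parameter recovery uses 100 replicates of 60 clusters
× 50 subjects at $\sigma_u = 0.5$ (thresholds — absolute bias below 0.03,
Wald coverage at least 0.90 — frozen after a single calibration run);
bootstrap coverage uses a reduced nested Monte-Carlo of 25 outer datasets
(25 × 25) with 60 replicates each, asserting coverage of at least 0.80 at
nominal 0.95 (the percentile interval at 60 replicates and $N = 25$
clusters is expected to undercover somewhat); empirical-REM convergence
uses $10^5$ draws. The quadrature oracle runs on a 20-cluster fixture.

## Reporting, pipeline and figures

`rem_report()` has two entry modes. Full-data mode computes everything;
measures-only mode (printed estimates: $\hat\sigma_u$, optionally its SE
and coefficients) computes every closed-form quantity and errors
informatively for anything needing data (empirical REM, bootstrap). The
config-driven `run_pipeline()` takes JSON (chosen over YAML to keep the
dependency surface minimal), writes `report.json` / `report.csv` /
`table1.csv` and the figures, and stamps seed and package version; reruns
with the same seed are byte-identical. A thin command-line wrapper lives
at `inst/cli/remvar.R`.

Figures expose their numeric layer (`forest_plot_data()`,
`variation_plot_data()`) separately from rendering, and the tests assert
on that layer — band edges equal `rem_range()` outputs exactly — rather
than on pixels. The shading ladder defaults to the 97.5, 90, 80, 70, 60
and 50 upper percentiles (mirrored below the median) with an opacity ramp
darkening toward the median; colors are configurable since no convention
fixes them. The x axis is log-scaled with a reference line at 1, so
normal GCE bands are symmetric.

## Known limitations

Single random intercept only (no crossed effects, more levels, or random
slopes); no GEE; no survival/frailty models or median hazard ratios; no
interval odds ratios; no probability-scale ICC variants; no
between/within covariate decomposition; Bayesian estimation and credible
intervals are out of scope. Spline or other basis columns must be
pre-computed by the user. The delta CI for REM inherits the usual
fragility of Wald intervals on variance components near the boundary —
prefer the cluster bootstrap there.
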