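---
title: "Similarity-weighted informative priors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-weighted informative priors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A focal study estimates a multiple regression. A body of K previously
conducted studies addressed the same question, but with different samples,
different predictor distributions, and heterogeneous results. How much of
that background knowledge should flow into the focal analysis? swipr answers
this with a per-coefficient similarity weight $\omega_p \in [0, 1]$ and a
weighted informative prior: the posterior is

$$p(\theta \mid D) \propto p(D \mid \theta)\,\pi(\theta)^{\omega},$$

so $\omega = 1$ uses the background knowledge fully (a direct replication)
and $\omega = 0$ ignores it.

## The similarity measure

$\omega$ multiplies two components that are deliberately
*non-compensatory* — high similarity on one cannot offset dissimilarity on
the other:

$$\omega_p = \frac{L}{1 + \exp\!\big[s\,(\tau^2_p + \delta\tau^2_p - \omega_0)\big]}\;\bar B$$

with defaults $L = 1$, midpoint $\omega_0 = 0.24$, slope $s = 10$. The
midpoint and slope are frozen to discriminate across the range of
between-study heterogeneity typical of psychological research (roughly 0.13
to 0.24 on the Fisher-z scale); `omega_config()` exposes them for
sensitivity analysis only.

**Sample similarity $\bar B$** (module `generalizability_index()`): for each
previous study, a logistic regression of sample membership on the shared
predictors yields sampling propensity scores; $B_k$ is the Bhattacharyya
coefficient $\int \sqrt{f_f(s) f_k(s)}\,ds$ of the two score densities,
estimated by Gaussian-kernel KDE on a fixed 512-point grid over $[0, 1]$,
each density renormalized to unit mass on the grid before trapezoidal
integration. $\bar B$ is the unweighted mean of the $B_k$. The
Bhattacharyya (square-root) form is used because it is the form that equals
1 under perfect similarity; the plain product form
$\int f_f f_k$ does not, and is available only behind
`overlap_coefficient(form = "product")`.

**Outcome heterogeneity $\tau^2$ and moderator-explained heterogeneity
$\delta\tau^2$** (module `heterogeneity_summaries()`): per predictor, the
per-study regressions are converted to Fisher-z partial correlations
($r = t/\sqrt{t^2 + df}$, $z = \operatorname{atanh} r$, sampling variance
$1/(n - q - 3)$ with $q = p - 1$ covariates partialled out) and pooled by a
hierarchical Bayesian random-effects meta-analysis. The mixed-effects model
adds the study-level moderator; $\delta\tau^2 = \max(0, \tau^2 -
\tau^2_{res})$, truncated at zero when the moderator explains nothing.

## The four analysis arms

All arms share the likelihood $y \sim N(\beta_0 + X\beta, \sigma^2)$ with
$\beta_0 \sim N(0, 10)$ (variance) and a half-Cauchy(0, 2.5) prior on the
error scale.

* **SWIP** (`fit_swip()`): $\beta_j \sim N(\mu_j, SE_j^2)^{\omega_j}$,
  implemented exactly as $N(\mu_j, SE_j^2/\omega_j)$ — raising a normal
  density to a power rescales its variance. Below `omega_floor = 1e-3` the
  prior is replaced by a diffuse $N(0, 100)$, which avoids the improper
  $\omega \to 0$ limit while matching the weighted prior's vanishing
  informativeness.
* **Pooled** (`fit_pooled()`): all rows stacked, diffuse $N(0, 100)$
  coefficient priors.
* **MAP** (`fit_map()`): per-coefficient meta-analytic predictive prior
  $N(\mu_j, SE_j^2 + \tau^2_j)$, robustified as a mixture with a diffuse
  component of weight 0.2 (the conventional default of robust-MAP
  implementations; configurable).
* **NPP** (`fit_npp()`): normalized power prior with a random borrowing
  weight $a_0 \sim U(0, 1)$ discretized on a 21-point grid over a diffuse
  normal-inverse-gamma baseline (coefficient variance $100\sigma^2$,
  IG(0.01, 0.01)). Everything is conjugate, so the $a_0$ posterior and the
  final mixture posterior are computed in closed form; convergence
  diagnostics for the regression parameters come from chains of exact
  independent draws. $a_0$ itself is enumerated exactly on the grid — often
  with nearly all mass on a single point — so a chain-based $\hat R$ is
  neither needed nor meaningful for it and is reported as `NA`.

### Scale bridge

The meta-analytic summaries live on the Fisher-z partial-correlation scale;
the prior is placed on raw coefficients. The default bridge back-transforms
the mean with $\tanh$ and the SE with the delta method,
$SE_r = SE_z (1 - r^2)$, and uses the r-scale values directly as
coefficient-scale hyperparameters. This is adequate when predictors are
standardized and the error variance is near 1 — exactly the simulation's
design — but it is an approximation for raw data on other scales; for those,
`effect_sizes(measure = "raw")` plus `swip_prior(scale = "identity")`
meta-analyzes the raw coefficients instead.

## Numerical and sampling choices

* **Sampler.** All sampled models run in JAGS (rjags) with 4 chains of
  2,000 iterations and 1,000 burn-in by default, per-chain seeded RNGs, and
  convergence declared at Gelman–Rubin $\hat R < 1.02$ for every parameter.
  A fit whose $\hat R$ exceeds the bound is rerun once with doubled
  iterations and otherwise returned flagged, never silently.
* **Sufficient-statistic likelihood.** Every arm's likelihood is an
  ordinary normal regression, so it is passed to the sampler through its
  exact factorization $\hat\beta \sim N_q(\beta, \sigma^2 (X'X)^{-1})$
  independent of $RSS \sim \sigma^2 \chi^2_{n-q}$. The posterior is
  identical to the row-wise form (verified against it), and sampling cost
  stops growing with $n$ — pooled fits with thousands of rows cost the same
  as the focal fit.
* **Marginalized meta-analytic models.** The normal-normal hierarchy is
  sampled with the study effects integrated out,
  $z_k \sim N(\mu + b\,m_k, v_k + \tau^2)$: the $(\mu, \tau)$ posterior is
  identical to the centered parameterization but mixes well even as
  $\tau \to 0$, where centered Gibbs updates stall. Hyperpriors (not fixed
  by the method's description, so chosen here): $\mu \sim N(0, 10)$,
  $\tau \sim \text{half-normal}(0.5)$ on the z scale — weakly informative
  and stable down to $K = 3$. Point estimates: posterior mean/SD for $\mu$,
  posterior median for variance components (right-skewed posteriors).
  $\delta\tau^2$ combines the two models' independent posterior medians.
* **Distribution-parameter convention.** Every $N(a, b)$ in the model
  definitions is read as (mean, variance), consistently. The half-Cauchy
  error prior is placed on $\sigma$ (the SD), the standard practice;
  `sigma_scale = "variance"` restores the literal reading on $\sigma^2$.
* **KDE bandwidth.** The Sheather–Jones plug-in selector by default,
  falling back to Silverman's rule when the sample is too small or too
  discrete for it, and to a minimal positive bandwidth for zero-variance
  samples (with a warning). Propensity scores are clipped to
  $[10^{-6}, 1 - 10^{-6}]$.
* **Separation.** Near-perfect separation of the two samples makes the ML
  logistic fit diverge; since extreme dissimilarity is a legitimate,
  informative outcome ($B \to 0$), the model is refit with a small ridge
  penalty instead of failing.
* **Seeds.** Condition seeds derive deterministically from a base seed and
  the grid index; replication seeds from the condition seed; sampler chain
  seeds from the replication seed. Conditions are independent work units —
  results do not depend on execution order.

## The simulation study

`sim_grid()` enumerates the full design: $K \in \{3, 5, 10\}$ previous
studies, sample-size offsets $\Delta_N \in \{-100, +100\}$ around the focal
$N_F = 200$, predictor mean offsets
$\Delta_\mu \in \{0.25, 0.5, 1, 2, 3\}$, and between-study heterogeneity
$\tau^2 \in \{0.025, 0.05, 0.10, 0.15, 0.20, 0.35, 0.5\}$ — 210 conditions;
at 100 replications, 21,000 generated datasets (`sim_manifest()` enumerates
them without materializing anything). The focal study has true coefficients
$(0.5, 0.25, -0.5)$ against meta-analytic means $(0.4, 0, 0.3)$ —
certainty, disagreement, and contradiction — unit error variance, standard
normal predictors. Previous-study sizes are drawn from
$N(N_F + \Delta_N, 25)$ — variance 25, i.e. SD 5, consistent with the
(mean, variance) convention — rounded and floored at $p + 4$; their
predictors from $N(\Delta_\mu, 1)$ in every coordinate.

One study-level moderator explains 10% of the between-study heterogeneity.
It is implemented as *additional* variance on top of $\tau^2$: study
coefficients are $\beta_k = \mu_\beta + \gamma m_k + e_k$ with
$\gamma = \sqrt{0.1\,\tau^2}$, $m_k \sim N(0,1)$ and independent coordinate
noise $e_k \sim N(0, \tau^2)$, so the total coefficient variance is
$1.1\,\tau^2$ and the residual after the moderator is $\tau^2$. This
matches the designed totals $\tau^2 + \delta\tau^2 = 1.1\,\tau^2$
(0.0275, 0.055, 0.110, ...). An alternative reading — total $\tau^2$,
residual $0.9\,\tau^2$ — exists but does not reproduce those totals.
Coefficient coordinates are drawn independently (diagonal covariance), and
all generating intercepts are zero.

Shrinkage is reported as $\hat\beta - \beta_F$: positive when the estimate
is pulled up toward a meta-analytic mean above the focal value (as for
$\beta_3 = -0.5$ against mean $0.3$), negative when pulled down. Averages
over replications use the plain mean for estimates and the root of the mean
squared SE for standard errors.

### What the generator does and does not emulate

The generator reproduces the study conditions exactly: normal predictors and
errors, coefficients scattered around meta-analytic means, a single
moderator, no missing data, a common $p$ across studies. Real data violate
most of these — non-normal predictors, unequal predictor sets, outcome
scales that differ across studies, missingness. Passing tests therefore
demonstrate that the method behaves as designed *under its own generative
assumptions*, not that the bridge from Fisher-z summaries to raw-coefficient
priors is calibrated for arbitrary real data.

### Scaled-down problem sizes

The full 210-condition, 100-replication study is a cluster-scale
computation. The packaged checks use sizes chosen to exercise every code
path with stable statistics: the convergence and behavior checks rerun the
study on the 8 corners of the $(K, \Delta_\mu, \tau^2)$ design cube with
$\Delta_N$ alternating between its extremes, 5 replications each, all four
arms at the full MCMC settings; parameter-recovery checks use $K = 50$ to
$200$ synthetic studies and 100 replicates; KDE-oracle checks use $10^5$
score draws.

## Known limitations

* The r-scale bridge treats a partial correlation as a coefficient-scale
  quantity; outside standardized-predictor, unit-error settings the prior
  location can be biased even when $\omega$ is accurate.
* $\bar B$ needs the previous studies' raw predictor rows; summary-data-only
  workflows are out of scope.
* One meta-analysis per predictor ("multiple univariate"); a joint
  multivariate meta-analysis is not implemented.
* The NPP arm is the conjugate normal-inverse-gamma formulation with a
  discretized uniform $a_0$; non-uniform $a_0$ priors and non-conjugate
  likelihoods are out of scope.
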