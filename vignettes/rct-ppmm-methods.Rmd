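---
title: "Assessing generalizability of trial results under nonignorable selection: methods"
author: "rctppmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing generalizability of trial results under nonignorable selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rctppmm)
```

## The estimation problem

A two-arm randomized trial is run on $n$ participants ($S = 1$) drawn
non-randomly from a target population; the remaining units ($S = 0$,
nonparticipants) contribute only aggregate covariate information: the mean
vector and covariance matrix of baseline covariates $Z$, and optionally
their count $N_0$.  The estimand is the average treatment effect among
nonparticipants, $E[Y_1 - Y_0 \mid S = 0]$ (and, when the trial is a
subset of the population, the marginal effect as the
participation-weighted average).  The obstacle is that participation may
depend on *unmeasured* effect modifiers $U$, making selection
nonignorable: no estimator based on observed covariates alone can remove
that bias, so the honest output is a sensitivity analysis rather than a
single number.

## The pattern-mixture model on outcome and proxy

Within arm $a$, the outcome is regressed on the covariates by OLS using
the trial data and the fitted values $X_a$ are the *proxies* for the
potential outcome $Y_a$.  Two facts make proxies convenient: the in-sample
proxy mean equals the arm outcome mean (intercepted OLS), and the
proxy-outcome sample correlation $\hat\rho_a$ equals $\sqrt{R^2}$ of the
arm regression — it measures how much outcome information the covariates
carry ("proxy strength").  The population proxy mean
$\bar x_a^{(0)}$ is the plug-in of the population covariate means into the
arm regression, so only summary-level data are needed.

$(Y_a, X_a)$ is modelled as bivariate normal with separate parameters for
$S = 1$ and $S = 0$; the nonparticipant parameters are identified only by
an assumption on selection, namely that arm-$a$ participation depends on
$(1 - \phi_a)X_a^* + \phi_a Y_a$ (proxy standardized to the outcome scale)
plus covariates orthogonal to both.  The bounded sensitivity parameter
$\phi_a \in [0,1]$ interpolates between ignorable selection
($\phi_a = 0$, selection only through the covariate-predictable part) and
selection entirely on the potential outcome ($\phi_a = 1$, an extreme but
useful bound).  The adjusted nonparticipant mean has the closed form
implemented in `adjusted_mean()`:

$$\hat\mu_y^{(a)(0)} = \bar y_a + g(\phi_a, \hat\rho_a)
\sqrt{\hat\sigma_{yy}/\hat\sigma_{xx}}\,(\bar x_a^{(0)} - \bar x_a^{(1)}),
\qquad g(\phi, \rho) = \frac{\phi + (1-\phi)\rho}{\phi\rho + 1 - \phi}.$$

$g$ increases from $\rho$ at $\phi = 0$ (the regression estimator — the
same answer as outcome-model-based generalizability methods) to $1/\rho$
at $\phi = 1$; a perfect proxy ($\rho = 1$) makes the analysis insensitive
to $\phi$, and a proxy-mean difference of zero collapses the whole curve
to the trial mean — a diagnostic that the observed data carry no
information about selection.  The treatment effect at a setting
$(\phi_1, \phi_0)$ is the difference of the two adjusted means
(`treatment_effect()`), and the recommended presentation varies one
$\phi$ at a time with the other fixed at 0 (`sensitivity_grid()`),
reporting where the effect and its interval cross zero
(`tipping_points()`).  The equal-$\phi$ variant moves both group means in
the same direction and typically leaves the effect nearly flat — a
"canceling out" that the grid mode `"both"` exposes directly.

### Assumptions that matter

* Internal validity of the trial (randomization, positivity).
* Bivariate normality of outcome and proxy per arm and pattern.  Mean
  adjustment is fairly robust to this, but intervals inflate when it
  fails; transform skewed outcomes first.
* $\hat\rho_a > 0$: guaranteed for in-sample OLS proxies; user-supplied
  external proxies with $\hat\rho \le 0$ are rejected loudly since the
  adjustment factor is undefined there.  A proxy with $\hat\rho < 0.2$
  triggers a warning — the analysis will be wide and weakly informative.

## Bayesian inference

`ppmm_bayes()` produces direct conjugate posterior draws; nothing is
iterative, so 10&nbsp;000 draws (the default) take a fraction of a second.
Per draw and per arm:

1. regression residual variance from its scaled inverse-$\chi^2$ posterior
   ($n_a - p - 1$ df) and coefficients from the conditional normal, i.e.
   Jeffreys priors on the proxy regression — this is what propagates the
   uncertainty of *building* the proxy;
2. proxies and their moments rebuilt from the drawn coefficients, and the
   nonparticipant proxy mean re-derived from the same drawn coefficients
   (optionally with the population covariate mean drawn at
   $\Sigma_z/N_0$ when a count is available — default on in that case,
   off otherwise);
3. the arm's bivariate $(Y, X)$ covariance from its Jeffreys posterior via
   the factorization *proxy marginal variance, then outcome-on-proxy
   regression*, both with $n_a - 1$ degrees of freedom, and the mean
   vector at $\Sigma/n_a$;
4. $\phi_a$ from its prior — a fixed value or Uniform$(l, u)$; the
   default analysis pairs Uniform$(0,1)$ on one arm with 0 on the other,
   and Uniform$(0, 0.5)$ encodes "moderately nonignorable at worst";
5. the closed-form transformation applied to the drawn quantities.

Draws implying $\rho \le 0$ are redrawn up to 100 rounds and then error:
silently truncating them would bias the intervals.  Credible intervals are
equal-tailed percentiles of the effect draws.  The exact draw scheme
(ordering, degrees of freedom, factorization) is a package choice; it is
non-iterative by construction and reproducible given a seed.
`bayes_sensitivity_report()` summarizes several scenarios at once, binning
draws by $\phi$ in bins of width 0.05 with within-bin medians and
percentile bands for curve plots — the bin width is a display choice, not
a model parameter.

## M-estimation standard errors

For fixed $(\phi_1, \phi_0)$, `ppmm_mest()` stacks per-arm estimating
equations for the regression coefficients, the outcome and proxy means,
and the three second moments (moment equations with divisor $n_a$), and
applies the empirical sandwich with a delta-method gradient through the
adjusted-mean transform.  The point estimate is the closed form itself —
the transform depends only on ratios of second moments, which are
invariant to the moment divisor — so only the variance needs the stacked
system.  The bread and the gradient use central finite differences with
step $10^{-6}\cdot\max(1, |\theta_j|)$; the system is small (about 16
parameters for two covariates) so this is cheap and accurate.  When a
population count is supplied, the sampling variance of the plug-in
population proxy means is added analytically.  Whether population
summaries are treated as fixed or noisy is flag-controlled
(`popsum_uncertainty`) in both inference modes, since practice varies with
the data source.

## The simulation framework

The generator (`generate_population()`) emulates a finite population of
$N = 5000$: $Z, U \sim N(0,1)$ independent, $W \sim N(\rho_{UW}U,\,
1-\rho_{UW}^2)$ so $W$ carries partial information about the unobserved
$U$; potential outcomes
$Y_0 \sim N(Z + W + U, \sigma^2)$ and
$Y_1 \sim N(1 + (1{+}\gamma_Z)Z + (1{+}\gamma_W)W + (1{+}\gamma_U)U,
\sigma^2)$.  Defaults encode the core study condition: effect modification
by $U$ only ($\gamma_U = 1$), $\sigma^2 = 4$, $\rho_{UW} = 0$.
$\sigma^2 \in \{1, 4, 13\}$ calibrates arm proxy correlations to roughly
0.7 / 0.55 / 0.4.  Selection is logistic in $(Z, W, U)$ with the intercept
bisection-calibrated (`calibrate_intercept()`, tolerance $10^{-6}$) so the
expected sample size is exactly $n = 200$, and exactly 200 units are drawn
by Brewer's fixed-size unequal-probability procedure (`brewer_sample()`),
which removes sample-size noise relative to Bernoulli sampling.  The
working weight at draw $k$ is
$\pi_i\{n - a - (n-k+1)\pi_i\}/(1-\pi_i)$ with $a$ the
$\pi$-total of units already selected; realized inclusion probabilities
are exact for $n = 2$ and near-exact for larger $n$ (verified against
exhaustive enumeration in the tests).  Arms are a uniformly random
100/100 split — equivalent in distribution to randomizing an arbitrary
ordering of the selected units, since selection order is independent of
potential outcomes given the sampler.  The nonselected units are
immediately reduced to the summary statistics of $(Z, W)$ plus the count;
$U$ and all nonparticipant microdata are discarded, so no analysis path
can touch them.

What the generator does *not* emulate: the data are drawn from an
unconditional normal model rather than from the pattern-mixture model
itself (so conditional-on-$S$ normality holds only approximately), there
are no sporadically missing values, no non-normal or discrete outcomes,
and no measurement error in the population summaries beyond finite-$N_0$
sampling.  Passing coverage here therefore demonstrates robustness of the
method to a realistic *mis*specification, not performance on arbitrary
real data.

`run_replicate()` performs one generate–select–analyse cycle (MLEs at
$\phi \in \{0, 0.5, 1\}$ per one-arm scenario; endpoint-interval coverage,
where the "MLE interval" is the range between the $\phi = 0$ and
$\phi = 1$ point estimates — a plausibility range, not a confidence
interval; Bayesian 95% intervals per prior), and `run_scenario()`
aggregates replicates with binomial Monte-Carlo standard errors, seeding
each replicate from a master seed and recording the per-replicate seeds
for exact replay.

### Problem sizes used in the shipped checks

The packaged tests and `scripts/acceptance.R` run the coverage study at
300–500 replicates per scenario with 2000 posterior draws per Bayesian
analysis, comparing against reference coverage within three binomial
Monte-Carlo standard errors; proxy-strength calibration uses 500
replicates, and sampler margins use 5000 small-population replicates.
These sizes were chosen once as the package's scaled protocol; the full
1000-replicate, 10&nbsp;000-draw protocol is supported by the same
functions.

## Numerical and design choices

* Sample variances use divisor $n - 1$ and Pearson correlations
  throughout the closed-form layer; the M-estimation layer uses divisor
  $n$ internally, which cannot change the point estimate (ratio
  invariance) and is the natural moment-equation convention.
* Default $\phi$ grid: 0 to 1 in steps of 0.05; tipping points are
  linearly interpolated between grid points and reported to 2 decimals.
* Covariates are not standardized before proxy construction: the adjusted
  mean is invariant to proxy rescaling, so standardization is cosmetic.
* $\sigma_{xx} = 0$ (no covariate signal) yields a flat, zero-width
  sensitivity band plus a warning rather than an error — flatness *is*
  the informative diagnostic; an inconsistent input (zero proxy variance
  with a nonzero proxy-mean difference) errors.
* Intercept calibration brackets adaptively and bisects to $10^{-6}$;
  monotonicity of the expected size in $\beta_0$ makes this globally
  convergent.
* All drivers take explicit integer seeds; per-replicate seeds are spawned
  from the master seed by a single `sample.int()` call and stored in the
  output.

## Known limitations

* Continuous, roughly normal outcomes only; binary/ordinal/count outcomes
  would need a different pattern-mixture layer.
* The sensitivity parameterization acts on each potential outcome, not
  directly on the individual treatment effect $Y_1 - Y_0$; selection on
  the effect itself is only captured indirectly.
* When selection depends on nothing observable, the proxy means coincide
  and the analysis is honestly uninformative (flat curves, zero-width
  bands) — by design it cannot conjure information the data lack.
* The M-estimation variance treats the fitted one-arm scenario as given;
  it does not average over selection scenarios.
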