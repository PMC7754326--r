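---
title: "Testing small-study effects across partially overlapping outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing small-study effects across partially overlapping outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallstudy)
```

## The problem

A *small-study effect* is a systematic association between a study's effect
estimate $Y_i$ and its standard error $s_i$: small (imprecise) studies report
different effects than large ones, classically because of publication bias,
and classically probed by Egger's regression of $Y$ on $s$. When a
meta-analysis reports several outcomes per study — say mortality and quality
of life, each with its own effect estimate and standard error, and not every
study reporting every outcome — the per-outcome tests are correlated (the
standard errors of different outcomes in one study are usually highly
correlated, since they share the study's sample size) and a joint test is
both more powerful and more honest than reading off $J$ separate p-values.

This package fits, per outcome, a meta-regression of the effect on its
standard error; estimates the cross-outcome covariance of those regression
estimates from the studies reporting both outcomes; combines the slopes into
one global $\chi^2$ test; and, when that global test is significant, runs a
sequentially rejective multiple-testing step on the per-outcome p-values.

## The univariate model

Three mean/variance structures for a single outcome are implemented in
`fit_small_study()`:

* **Egger**: $Y_i \sim N(\alpha + \beta s_i,\; s_i^2)$. Weighted least
  squares with *known* variances. Rigid: no allowance for between-study
  heterogeneity, which is why it over-rejects under heterogeneity.
* **Lin–Chu** (`fit_lin_chu()`): $Y_i \sim N(\alpha + \beta\sqrt{\tau^2 +
  s_i^2},\; \tau^2 + s_i^2)$, joint ML over $(\alpha, \beta, \tau^2)$. Here
  $\tau^2$ modifies both the mean and the variance, which couples the two in
  an awkward way and rules out simple GEE-style extensions. (The slope
  multiplies the *total* standard deviation; this is the reading of the
  model we adopt and document, as its published renderings vary.)
* **Flexible hybrid** (the default): Egger's mean structure with a
  heterogeneity-inflated, scale-free variance,
  $$Y_i \sim N\big(\alpha + \beta s_i,\; \sigma^2(\hat\tau^2 + s_i^2)\big).$$

The flexible hybrid is fitted in two steps. First $\hat\tau^2$ comes from the
*marginal* intercept-only random-effects model $Y_i \sim N(\alpha, \tau^2 +
s_i^2)$ (`estimate_tau2()`); then the transformation
$$Y_i^* = \frac{Y_i}{\sqrt{\hat\tau^2 + s_i^2}},\qquad
  x_{0i} = \frac{1}{\sqrt{\hat\tau^2 + s_i^2}},\qquad
  x_{1i} = \frac{s_i}{\sqrt{\hat\tau^2 + s_i^2}}$$
turns the fit into ordinary least squares of $Y^*$ on $(x_0, x_1)$ with no
further intercept: $Y_i^* \sim N(x_i\theta, \sigma^2)$, $\theta = (\alpha,
\beta)^\top$. The transformation is computational convenience only — the OLS
solution is identical to direct generalised least squares of $Y$ on $(1, s)$
with covariance $\sigma^2\,\mathrm{diag}(\hat\tau^2 + s_i^2)$, and the test
suite asserts that equivalence to $10^{-8}$. The free scale $\sigma$ makes
the variance model robust to misestimation of $\tau^2$: the point estimates
do not depend on $\sigma$ at all, and the Wald statistic
$(\hat\beta/se(\hat\beta))^2$ is invariant to rescaling the data. With
$\hat\tau^2 = 0$ and $\sigma$ fixed at 1 the fit *is* the Egger regression,
exactly.

Each fit reports both $P$ (with $\hat\sigma^2 = RSS/(n-2)$) and $p^*$ (the
same test with $\sigma$ fixed at 1).

## Tunable parameters

* `tau2_method` (`"DL"`, default, or `"REML"`): the heterogeneity estimator
  of step 1. DL is the closed-form moment estimator — reproducible with no
  optimisation — and is the conventional default in meta-analysis software;
  REML maximises the restricted likelihood on $[0, \infty)$ (L-BFGS-B,
  iteration cap 200, tolerance $10^{-10}$, started at the DL value). Both
  are truncated at zero and the truncation is flagged. On moderate datasets
  the choice moves $\hat\tau^2$ by far less than its sampling error.
* `tau2`, `fix_sigma`: overrides that pin $\tau^2$ and/or $\sigma$, mainly
  for reductions (Egger) and sensitivity checks.
* `alpha` (default 0.10 in `mv_small_study()`): the level used both to gate
  and to run the multiple-testing step. 0.10 is the customary level for
  asymmetry tests, whose power is notoriously low.
* `gate_mtp` (default `TRUE`): the sequential step is only interpretable as
  an improvement over Bonferroni–Holm *conditional* on a significant global
  test; ungated use is provided for exploration (`gate_mtp = FALSE`) but
  the gated form is the default.

## The multivariate test

With per-outcome estimates $\hat\theta_j$ and model-based covariances $C_j =
\hat\sigma_j^2 (X_j^\top X_j)^{-1}$, the missing piece is the
cross-covariance $C_{jk} = \mathrm{cov}(\hat\theta_j, \hat\theta_k)$. As in
GEE with a working-independence model, it is estimated by a sandwich over
the overlap set $A$ (studies reporting both outcomes):
$$C_{jk} = (X_j^\top X_j)^{-1}
  \Big[\textstyle\sum_{i \in A} x_{ji}^\top r_{ji} r_{ki} x_{ki}\Big]
  (X_k^\top X_k)^{-1},$$
with $r$ the transformed-scale residuals of the *full* per-outcome fits.
Three deliberate readings, each of which was genuinely open:

* the bread matrices run over **all** studies with the respective outcome,
  while the meat sum is restricted to $A$ — the bread is the actual inverse
  design of each fit, and only the overlapping studies carry information
  about the covariance;
* residuals come from the full fits, not refits on $A$, because the
  covariance wanted is that of the full-sample estimators;
* an empty overlap returns the zero matrix, so the global statistic then
  collapses to the sum of the univariate $\chi^2$'s — exactly (a tested
  invariant).

The slope covariance $C_\beta$ is extracted from the assembled $2J \times
2J$ matrix, symmetrised, and the global test is $\chi^2_J =
\hat\beta^\top C_\beta^{-1} \hat\beta$. For $J > 2$ the assembled $C_\beta$
can fail to be nonnegative definite (the off-diagonal blocks are not
constrained); we then clip negative eigenvalues at zero, use the
Moore–Penrose pseudo-inverse, reduce the degrees of freedom to the retained
rank, and flag the repair loudly (`psd_ok`, `repaired`, and a note in the
report). An overlap below 3 studies triggers a warning that the
cross-covariance is very unstable; the computation proceeds.

## Multiple testing

After a significant global test at level $\alpha$, at most $J - 1$ of the
individual nulls can still be true. The sequential rule orders the
per-outcome p-values and rejects while $p_{(j)} \le \alpha / t_j$ with
$t = (J-1, J-1, J-2, \dots, 1)$ — Holm's procedure with every divisor
shifted down by one, hence never fewer rejections than Holm (a tested
property). For $J = 2$, $t = (1, 1)$: both hypotheses are tested at the full
level. Ties share a sorted position; since thresholds are nondecreasing the
decision is invariant to how ties are ordered.

## The synthetic-data generator

`simulate_dataset()` draws from
$$Y_{ij} = \alpha_j + \beta_j s_{ij} + b_{ij} + e_{ij},\qquad
  b_i \sim MVN(0, T),\qquad e_{ij} \sim N(0, s_{ij}^2),$$
with $\mathrm{cor}(e_{ij}, e_{ik}) = \rho_w$ for co-observed outcomes and
log-normal standard errors coupled across outcomes by an equicorrelated
Gaussian copula on the log scale (correlation $\rho_{se}$) — a proxy for the
common sample size that makes real multi-outcome SEs move together. The
first `overlap` studies observe every outcome; the rest observe outcome 1
only.

Default conditions, fixed once: $\tau^2 = 0.2$ per outcome with
between-study correlation 0.5 (moderate heterogeneity, of the order seen in
the case studies, whose reported $\hat\tau^2$ range from 0 to 0.72);
$\rho_w = 0.5$ (distinct but related clinical outcomes measured on the same
patients); SEs log-normal with mean 0.5 and SD 0.25 (a typical spread for
log hazard/odds ratios from studies of tens to hundreds of patients);
$\rho_{se} = 0.9$ (the case studies show 0.87 and 0.97). The presets
`config_case1_like()` (34 studies, 12 overlapping, induced SE correlation
$\approx 0.87$) and `config_case2_like()` (50/10, $\approx 0.97$) take their
study counts and SE moments from the published summary tables.

What the generator deliberately does **not** emulate: a selection
(publication-bias) mechanism. It implements the associational model — the
mean is linear in $s$ — because that is the model being tested; data arising
from selective publication would show a nonlinear association, so
calibration and power under this generator do not certify behaviour under
real censoring. It also assumes normal sampling errors, exactly known
$s_{ij}$, and a monotone missingness pattern (outcome 1 always observed),
none of which real meta-analytic data guarantee.

The type-I/power harness (`rejection_rate_experiment()`) derives one seed
per replicate from the root seed, so experiments are reproducible and
splittable. Replicate-level fit failures (e.g. an outcome dropping below 3
studies) are counted and reported rather than aborting the experiment.

## Numerical choices

* $\hat\sigma^2 = RSS/(n-2)$ — two mean parameters. A fit needs $n \ge 3$
  per outcome (Egger: $n \ge 2$, since nothing is estimated beyond the mean).
* All Wald p-values use the $\chi^2$ reference, not $t$/$F$. This matches
  the method's large-sample derivation; exact small-sample inference is out
  of scope.
* Identical standard errors make $x_1 \propto x_0$: a collinearity error
  naming the cause, not a silent pseudo-inverse.
* Zero residuals ($Y$ exactly linear in $s$): $\hat\sigma = 0$ is reported
  with a degeneracy flag, $P$ is withheld and only $p^*$ (at $\sigma = 1$)
  is reported.
* PSD checks use a relative tolerance of $10^{-10}$ times the largest
  eigenvalue; the GLS/OLS equivalence holds to $10^{-8}$.

## Worked example

```{r}
d <- simulate_dataset(config_case1_like(seed = 20))
summary_stats(d)
mv_small_study(d, alpha = 0.10)
```

## Known limitations

* **Small-sample anti-conservatism.** Referring Wald statistics with an
  estimated $\sigma$ to $\chi^2$ instead of $t^2$/$F$ inflates the level
  when outcomes have few studies. In the packaged harness (50 studies, 25
  overlapping, 2000 replicates) the global test rejects at about 0.07 at
  nominal 0.05; the gap is the usual $t^2$-versus-$\chi^2$ difference, so it
  closes as the per-outcome study counts grow. (Harness problem sizes are
  kept at tens to hundreds of studies so the full suite runs in minutes.)
  Users with 10–30 studies per outcome should read borderline global
  p-values accordingly.
* The sandwich cross-covariance rests on the overlap set; with fewer than
  about 8–10 overlapping studies it is noisy enough that the global test
  mostly reflects the univariate statistics (a warning fires below 3).
* No selection model: a significant slope says the effects are associated
  with the standard errors, not why.
* The Lin–Chu observed-information covariance is evaluated just inside the
  boundary when $\hat\tau^2 = 0$ and is then approximate.
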