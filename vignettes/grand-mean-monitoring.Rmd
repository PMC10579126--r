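---
title: "Comparing centers with the Grand Mean: models, inference and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing centers with the Grand Mean: models, inference and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmcenter)
```

## The monitoring problem

Central statistical monitoring asks whether any center of a multicenter
trial or registry deviates from the others in a recorded variable — a mean
age, an adverse-event rate, a severity-score distribution, a missingness
rate. Rather than comparing every pair of centers, `gmcenter` compares each
center with the sample-size-weighted average of all centers, the Grand
Mean

$$m_. = \sum_{i=1}^{I} \frac{n_i}{N} m_i, \qquad N = \sum_i n_i,$$

where $m_i$ is the model parameter of center $i$ (a mean, a logit, or a
rank-scale relative effect). The deviations $d_k = m_k - m_.$ are linear
contrasts $d_k = c_k' m$ with

$$c_k = \left(-\tfrac{n_1}{N}, \ldots, 1 - \tfrac{n_k}{N}, \ldots,
       -\tfrac{n_I}{N}\right),$$

one contrast per center ($K = I$). Stacking the $c_k$ gives the contrast
matrix $C$; a fitted model supplies $\hat m$ and $\widehat V$, and

$$\hat d = C \hat m, \qquad \widehat U = C \widehat V C',\qquad
  t_k = \hat d_k / \widehat{se}(\hat d_k).$$

Because the $K$ statistics are correlated (each center appears in every
contrast), single-step multiplicity adjustment uses the equicoordinate
quantile $q_{1-\alpha}$ of the central multivariate $t$ (or normal)
distribution with the estimated correlation matrix $\widehat R$. Adjusted
p-values are $p_k = 1 - P(\max_j |T_j| \le |t_k|)$ and simultaneous
confidence intervals are $\hat d_k \pm q_{1-\alpha}\,\widehat{se}(\hat
d_k)$, so the test decision, the adjusted p-value and the interval always
agree. When equivalence margins $[-\delta, \delta]$ are supplied, a center
whose interval lies inside them is declared consistent with the average;
an interval excluding zero flags a significant deviation; anything else is
inconclusive.

## Estimation backends

* **`lm`** (continuous): the one-way cell-means layout
  $Y_{ij} = m_i + \varepsilon_{ij}$, $\varepsilon_{ij}\sim N(0,\sigma^2)$.
  Estimates are center means, $\widehat V = s^2\,\mathrm{diag}(1/n_i)$ with
  the pooled variance $s^2$, and the multivariate $t$ uses the residual
  $df = N - I$. Under normality the procedure is exact, which the
  simulation engine confirms empirically.
* **`glm`** (binary): the saturated logit model,
  $\hat m_i = \log(y_i/(n_i-y_i))$,
  $\widehat V = \mathrm{diag}(1/y_i + 1/(n_i-y_i))$, asymptotic normal
  reference. Centers with $y_i \in \{0, n_i\}$ make the logit and its
  standard error infinite; the fit refuses such data and names the
  offending centers, because rare events (a center with zero adverse
  events, or zero missing values) are exactly the interesting case in
  monitoring.
* **`brglm`** (binary): Firth's bias-reduced logistic fit — IRLS with the
  hat-value score adjustment
  $U^*(\beta) = X'(y - n\mu + h(\tfrac12 - \mu))$ — which always yields
  finite logits. In the saturated one-way layout it coincides with adding
  $1/2$ to successes and failures, a closed form the tests exploit as an
  oracle. Convergence: score norm below 1e-8, at most 100 iterations.
* **`bayesglm`** (binary): posterior mode under weakly informative Cauchy
  priors, following the standard recommendation of scale 10 for the
  intercept (the baseline logit can range widely) and scale 2.5 for
  center effects. The intercept + treatment-coded effects model is fitted
  by penalized IRLS with the Cauchy prior handled as a scale mixture of
  normals: each EM step sets the prior precision of coefficient $j$ to
  $(\nu+1)/(\nu s_j^2 + \beta_j^2)$, $\nu = 1$. Coefficients and the
  penalized-information covariance are mapped linearly to center logits.
  Convergence: max coefficient change below 1e-8, at most 200 iterations.
  The prior scales are arguments; shrinkage is monotone in the scale,
  which the tests check.
* **`nparcomp`** (continuous or ordinal): nonparametric relative effects.
  The effect of center $i$ is $p_i = P(X_G \le X_i)$ against the
  *unweighted* average distribution $G = \tfrac1I \sum_r F_r$; estimates
  use mid-distribution functions (pseudo-ranks), so heavily tied ordinal
  scores are handled, and the unweighted mean of $\hat p$ is exactly 1/2.
  The covariance of $\hat p$ is estimated from the empirical influence
  functions: the contribution of an observation in center $r$ to
  $\hat p_i$ is $(w_{ir} - F_i(x))/I$ for $i \ne r$ (with
  $w_{ir} = \int F_i\,dF_r$) and minus the sum of those terms for its own
  effect; summing per-center influence covariances scaled by $1/n_r$
  gives $\widehat V$. Monte Carlo checks show this estimator is close to
  unbiased down to $n_i = 3$. Inference is on the untransformed effect
  scale (no range-preserving logit transform); the Grand-Mean contrast
  matrix keeps its $n_i/N$ weights even though $G$ is unweighted, so the
  reported deviations are the weighted contrasts of rank-scale effects.

### Degrees of freedom for the rank backend

The multivariate-$t$ approximation needs a degrees-of-freedom parameter
that the asymptotic theory does not supply. Two Satterthwaite-type
variants are implemented (`df_method`):

* `"contrast_min"` (default): a Satterthwaite df is computed for every
  Grand-Mean contrast from its per-center variance components
  $a_{kr} = c_k' S_r c_k / n_r$,
  $\nu_k = (\sum_r a_{kr})^2 / \sum_r a_{kr}^2/(n_r - 1)$, and the
  smallest $\nu_k$ is used. Each contrast's variance is dominated by its
  own center's component, estimated with only $n_k - 1$ df, and the
  minimum acknowledges that the joint quantile must protect the worst
  coordinate.
* `"total"`: one global df from the pooled components. This choice makes
  the small-sample test far too liberal (familywise error near 50% for
  ten centers of three subjects in our pilot runs) and is retained only
  for comparison.

The df is floored at 2. The quasi-Monte-Carlo integrator for the joint
probabilities accepts integer df only, so the fractional df is rounded to
the nearest integer there, while univariate marginal computations keep the
fractional value; at the df sizes involved the effect on the quantile is
well below the quantile tolerance.

## Numerical choices

Joint probabilities of the multivariate $t$/normal are evaluated by
quasi-Monte-Carlo integration (Genz–Bretz) with absolute tolerance 1e-4
(`gm_settings(prob_tolerance = )`) under a fixed integration seed, so
reported p-values and quantiles are reproducible run to run. The
equicoordinate quantile is found by root search bracketed between the
unadjusted and Bonferroni quantiles, to tolerance 1e-3. Correlation
matrices failing positive semidefiniteness by more than numerical noise
get one ridge-repair attempt (1e-10, logged) before an error. Contrasts
with variance below 1e-12 are reported as `NA` statistics rather than
infinities; a zero variance combined with a nonzero deviation raises a
degenerate-variance error. Adjusted p-values exactly at $\alpha$ are
flagged non-significant (strict inequality).

## The simulation engine and its study conditions

`gm_scenario()` + `run_gm_study()` reproduce the Monte Carlo design used
to characterize the procedures:

* Continuous data are $N(m_i, 1)$; ordinal data are the same draws
  rounded to 0 digits (round-half-even by default, switchable to
  half-away-from-zero), giving about seven effective categories at the
  baseline $N(0,1)$; binomial data are per-center counts
  $\mathrm{Binomial}(n_i, \pi_i)$.
* Grids: $I \in \{5, 10\}$ centers; balanced per-center sizes from
  $\{2, 3, 4, 5, 6, 10, 20, \ldots\}$; unbalanced null profiles alternate
  $n$ and $n/2$; unbalanced power profiles give the single deviating
  center half the observations of the others.
* Effects are calibrated, per sample size, so a two-sided two-sample
  $t$-test (noncentral-$t$ inversion, `calibrate_delta_ttest()`) or
  pooled-approximation proportion test (`calibrate_prop_test()`) at that
  $n$ has 80% power.
* Rejection means at least one adjusted p-value below $\alpha$. With 1000
  replicates the standard error of an estimated type I error at the
  nominal 0.05 is about 0.007 and 95% of estimates from an exact method
  fall in [0.036, 0.063] (`mc_interval()`).
* Replicates whose fit fails — plain-GLM separation, or rank-degenerate
  data where a deviation has zero estimated variance — are counted and
  treated as non-rejections by default (`failed_fits = "drop"` removes
  them from the denominator instead). The choice is reported because it
  materially affects tiny-$n$ ordinal scenarios, where complete
  separation of a shifted center is common.
* Per-scenario RNG substreams derive deterministically from one master
  seed; identical seeds give identical tables.

The bundled checks run the null grids at $n_i \in \{2,\ldots,6\}$ and the
unbalanced power grids at $n \in \{4,5,6\}$ (the smallest sizes for which
the rank backend's variance estimator is defined in the halved deviating
center), with 300–1000 replicates; the acceptance script uses 1000. These
sizes keep full runs in minutes while leaving Monte Carlo error (about
1–2 percentage points) small relative to the effects asserted.

What the generator emulates — and what it does not: independent subjects,
homoscedastic normal or rounded-normal outcomes, a single deviating
center, and binomial counts without overdispersion. Real registry data
bring correlated visits, heteroscedastic and skewed outcomes, and
center-level heterogeneity that is *expected* rather than anomalous;
passing these simulations therefore demonstrates the procedures' operating
characteristics under the stated conditions, not robustness to every
real-data pathology. For repeated visits the package only offers explicit
per-patient reduction rules (`reduce_visits()`: latest, first, any-event),
defaulting to the latest visit.

## Design choices that were genuinely open

* **Reference distribution $G$**: unweighted average of the center
  distributions, following the convention of the rank-based multiple
  contrast literature; the $n_i/N$ weighting enters through $C$. An
  $n$-weighted $G$ would entangle the effect definition with the center
  sizes and change under recruitment imbalance alone.
* **Df variant for the rank backend**: `contrast_min`, for the reasons
  above; the global variant is demonstrably too liberal for tiny centers.
* **BayesGLM parameterization**: intercept + effects coding honors the
  two different prior widths; the uniform cell-means coding used by the
  other backends would force one common prior scale on absolute logits.
  A consequence is that the fit is not exactly permutation-equivariant in
  the baseline center, which is documented rather than hidden.
* **Ties between calibration conventions**: the proportion-test
  calibration uses the pooled-variance normal approximation (the same
  formula as `stats::power.prop.test`), inverted to the upper root.
* **Failed-fit accounting**: non-rejection by default, since a monitoring
  procedure that cannot be computed has, operationally, not flagged
  anyone.

## Known limitations

* The binomial backends are asymptotic; for low expected counts they are
  conservative rather than liberal, and the plain GLM is unusable under
  separation by design.
* The rank backend remains liberal for centers with fewer than about 10
  subjects — familywise error around 10% for continuous and up to ~19%
  for few-category ordinal data in the bundled small-$n$ studies — so its
  flags on very small centers should be read as screening signals, not
  confirmatory evidence.
* Covariate adjustment, cumulative-link ordinal models, survival
  endpoints, overdispersed binomial models and stratified Grand Means are
  out of scope.
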