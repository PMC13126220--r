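---
title: "Meta-analytic CFA with mean structures: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic CFA with mean structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Meta-analytic structural equation modeling (MASEM) fits a structural
equation model to effect sizes synthesized across independent studies.
When the effect sizes are *correlations*, only the factor structure can be
studied. `metacfa` analyzes **covariance matrices and mean vectors**, which
makes measurement properties and latent means comparable across studies:
are the indicators functioning the same way in clinical and non-clinical
samples, and do the groups differ on the underlying construct? Answering
the second question requires the first — latent means are only comparable
under (sufficient) strong factorial invariance — so the package is built
around an invariance-testing workflow.

All the package needs from each primary study is `n`, the sample
covariance matrix `S` (denominator `n - 1`), the sample means, and
study-level moderator values. Raw participant data are never required.
This only makes sense when the studies administered the same instrument on
equivalent scales; harmonization questions are out of scope. Likert-type
items are ingested as continuous, which is the common practice for the
5-point scales these datasets typically contain.

## The model

For study $i$, stack the non-redundant sample covariances and the sample
means into the effect-size vector
$y_i = [\mathrm{vech}(S_i);\ \bar y_i]$ of length $p(p+1)/2 + p$. The
multivariate random-effects meta-analysis decomposes

$$ y_i = \mu_y + u_i + e_i, \qquad u_i \sim N(0, T^2), \quad
   e_i \sim N(0, V_i), $$

where $T^2$ is the between-studies covariance of the study-specific
population effect sizes and $V_i$ the study's sampling covariance,
treated as known. One-stage MASEM with means restricts the average
effect sizes to the model-implied moments of a confirmatory factor model:

$$ \mu_y(\theta, x_i) = \begin{bmatrix}
   \mathrm{vech}\!\left(\Lambda \Phi \Lambda' + \Psi\right) \\
   \tau + \Lambda \kappa \end{bmatrix}, $$

with loadings $\Lambda$, factor covariances $\Phi$, diagonal residual
variances $\Psi$, intercepts $\tau$, and factor means $\kappa$. Every
parameter may be *moderated*: a moderated parameter equals
$\beta_0 + \sum_m \beta_{1m} x_{im}$ in study $i$ (the regression
approach). With a 0/1 dummy this reproduces a two-group model; with a
continuous moderator it describes how a parameter drifts with, say, mean
sample age. Multiple moderators compose additively. Slopes on variances
can drive a moderated variance negative at extreme moderator values; the
package reports such values as a diagnostic rather than clipping them,
because the likelihood only involves the implied moments, not their
admissibility.

Identification follows the usual convention: in the reference
configuration each factor's variance is fixed at 1 and its mean at 0, so
the factor is standard normal; a fixed-marker alternative (fixed loading
and intercept) is accepted by the spec constructor but is not the
default. Single-indicator factors are accommodated by fixing the
indicator's residual variance at 0.

### Invariance levels

`build_invariance_model()` turns a reference specification into one of
three moderated models with respect to a grouping dummy:

* **configural** — every free CFA parameter gets a slope; factor variances
  stay fixed at 1 and factor means at 0 in both groups;
* **weak** — loading slopes are removed; factor variances keep a fixed
  baseline of 1 and gain a free slope (the non-reference group's variance
  is estimated);
* **strong** — intercept slopes are removed as well; factor means keep a
  fixed baseline of 0 and gain a free slope, so each factor-mean slope *is*
  the latent mean difference between the groups.

`partial_free` exempts individual loadings (weak) or loadings/intercepts
(strong) from the constraint. The package codifies the usual search for a
partial model: free one candidate parameter at a time, compare each
candidate against the less restrictive reference by the chi-square
difference test, and prefer the candidate with the best fit, breaking ties
by lower AIC.

### Degrees of freedom

`count_df()` counts residual dfs against the saturated
means-and-covariances model with the same moderation status:
$df = m\,(p(p+1)/2 + p) - n_{\text{free}}$, with $m$ one plus the number
of distinct moderators. Heterogeneity parameters are shared with the
saturated baseline and never enter the count. For the one-factor,
five-indicator, two-group design this gives the 10/14/18 ladder for the
configural/weak/strong models.

## Estimation

The marginal likelihood multiplies, over studies, the multivariate normal
density of $y_i$ (restricted to the entries the study reports, via a
selection of rows of $\mu_y$, $T^2$, and $V_i$) with covariance
$T^2 + V_i$. Missing variables are handled by this selection, never by
imputation.

* **Heterogeneity structure.** Estimating all of $T^2$ is hopeless at
  realistic study counts, so the covariance-block of $T^2$ is diagonal
  (one log-SD parameter per covariance element) while the mean-block is a
  full symmetric matrix parameterized by its Cholesky factor — positive
  semidefiniteness holds by construction, no constrained optimization
  needed. The cross-block between covariance and mean random effects is
  fixed at zero; freeing it would add $p \cdot p(p+1)/2$ parameters that
  no dataset of this kind can support. Log-SD parameters are box-bounded
  at $[-8, 5]$ (variances $\approx 10^{-7}$ to $e^{10}$); a solution at
  the lower bound is reported as a boundary estimate.
* **Optimizer.** `stats::nlminb` with analytic gradients (the moment
  Jacobian is assembled in compiled code alongside the likelihood),
  relative function tolerance `1e-10`, and one jittered restart on
  non-convergence. Non-convergence is always reported, never masked;
  rich moderated models on few studies genuinely fail to converge and the
  ladder tooling simply skips the comparisons that would need them.
* **Starting values.** Loadings start at .5, residual variances at half
  the pooled observed variances, intercepts at the pooled means, slopes at
  0. Heterogeneity starts are moment-based: the between-study variance of
  each effect size in excess of the average sampling variance (floored at
  5% of the spread), and for the mean block the moment estimate of the
  full matrix, eigenvalue-floored to positive definiteness. The
  moment-based start replaces a fixed-constant start because it makes
  cold starts converge reliably across the simulation's thousands of
  fits. Ladder fits warm-start from the previous model on the ladder.
* **Standard errors** come from the inverse observed information,
  obtained by central differences of the analytic gradient at the
  optimum. They are skipped (`se = FALSE`) in bulk simulation, where only
  point estimates and likelihoods are consumed.
* **Saturated baseline.** For fixed heterogeneity parameters the
  saturated mean structure is linear in its parameters, so it is profiled
  out by GLS in closed form and only the heterogeneity parameters are
  searched; the profiled gradient is the partial gradient at the GLS
  solution. An unmoderated saturated fit is exactly the multivariate
  random-effects meta-analysis of the covariances and means.

### The sampling covariance plug-in

Under normality, $V_i$ has mean-block $\Sigma/n$, covariance-block
$\mathrm{Cov}(s_{ij}, s_{kl}) = (\sigma_{ik}\sigma_{jl} +
\sigma_{il}\sigma_{jk})/(n-1)$ (exact for the unbiased $S$), and a zero
cross-block (third central moments of the normal vanish). Some $\Sigma$
must be plugged in. Plugging in each study's *own* $S_i$ looks natural
but makes the weights $(T^2 + V_i)^{-1}$ anticorrelated with the observed
effect sizes — studies whose covariances are randomly small claim too
much precision — and at moderate within-study $n$ this visibly shrinks
the pooled covariances and inflates latent mean differences. In the
package's own calibration at $n = 100$ (one factor, loadings .70,
residual variances .51), the own-$S$ plug-in recovered mean loadings of
.659 and a factor-mean difference of .551 instead of .70/.50; the
artifact shrinks roughly like $1/n$ (.691 at $n = 500$). The default is
therefore `v_plugin = "pooled"`: the precision-weighted pooled sample
covariance enters the $V_i$ formula for every study (with the study's own
$n$), which removes the correlation between weights and outcomes while
keeping $V_i$ "known". With it the same calibration recovers .698/.512
and a factor-mean bias under .01. `v_plugin = "study"` remains available
for comparison with software that uses the per-study plug-in.

## Model comparison

The chi-square of a factor model is the difference in $-2\log L$ against
the saturated model with *matching* moderation status (unmoderated CFA
vs unmoderated saturated; the invariance ladder vs the moderated
saturated model). Nested fits are compared by `masem_lrt()` (or
`anova()`), with significance at the conventional 5% level.
`information_criteria()` uses $AIC = -2\log L + 2m$ and
$BIC = -2\log L + m \log N$, where $m$ counts *all* estimated parameters
(heterogeneity included) and $N$ is the summed within-study sample size.
Neither convention is universal; both matter only through differences
between fits on the same data, which are invariant to the likelihood
constant. RMSEA uses $\sqrt{\max(\chi^2 - df, 0) / (df\,(N - 1))}$ with
the same $N$; other MASEM conventions exist, which is why the convention
is stated here and in `?rmsea`. A latent mean difference is standardized
(`smd()`) by the unweighted pooled factor SD,
$\sqrt{(\phi_{\text{ref}} + \phi_{\text{other}})/2}$.

## The Monte-Carlo harness

`sim_condition()` / `run_condition()` regenerate the package's evaluation
study. The generating model is a one-factor CFA on five indicators in two
groups of studies: loadings .70, residual variances .51, intercepts .50,
factor mean 0 in group 1 and .50 in group 2. Under the violated-invariance
("weak") truth the first indicator's intercept is 1.00 instead of .50 in
group 2. Between-study heterogeneity: independent $N(0, .01)$ random
effects on every covariance element (redrawn until the study population
covariance is positive definite, capped at 1000 attempts) and a
multivariate normal on the means with variance .20 and pairwise
covariance .10 (a positive-definite compound-symmetric matrix). Study
counts per group are 15, 20, or 24. Each replication samples raw
within-study data from the study's population and summarizes them, so
sampling error enters exactly as it would in a real meta-analysis.

Choices the design leaves open, fixed here once:

* **Within-study sample size** is not part of the published grid; the
  default is `n_within = 100`, a typical primary-study size for this
  literature. Rejection rates and power depend on this choice; bias
  results do not (with the pooled $V_i$ plug-in — see above). The knob is
  exposed, and sensitivity runs at `n_within` of 50/100/200 are part of
  the acceptance tooling's remit rather than hard-gated assertions.
* **Replications.** Test and acceptance runs use 200 replications per
  condition for the four-model ladder (the bias targets pool extra
  strong-model-only replications on top, 600 per condition under the
  strong truth and 400 under the weak truth), which keeps the full suite
  in the tens of minutes on one core while leaving Monte-Carlo standard
  errors around .01 on the bias summaries; assertions on stochastic
  quantities use tolerances derived from those standard errors.
* **Random-number protocol.** One master seed per condition;
  per-replication sub-seeds are drawn once up front, so any single
  replication can be reproduced in isolation and an interrupted run
  re-produces the head of a longer one.

Each replication fits the moderated saturated model and the
configural/weak/strong ladder, records the strong model's factor-mean
slope, the overall chi-square p-value of the strong model, both
chi-square-difference p-values, and the AIC/BIC winners among the four
models (ties broken by the first minimum, which never occurs in
practice at these sample sizes). Non-converged fits are recorded,
excluded from the summaries they would enter, and surfaced as a
convergence rate.

The fitted models in the harness pair the diagonal covariance-effect
block with an **exchangeable** (compound-symmetric) mean block:
`het_spec("diagonal", "exchangeable")`. The structure of $T^2_m$ turns
out to drive the operating characteristics at these study counts, and
the package's own calibration runs at $k = 30$ make the trade-off
concrete. Estimating the full symmetric $5 \times 5$ mean block (15
parameters) makes the 4-df strong-vs-weak chi-square difference badly
anticonservative — rejection around .13–.15 at the 5% level under the
strong truth, mean statistic 5.4 instead of 4 — because the weights
$(T^2 + V_i)^{-1}$ are themselves noisy; the distortion disappears by
$k = 150$ but that is not the regime of interest, and holding the
baseline's heterogeneity fixed across the ladder does not repair it.
Ignoring the correlation among mean effects (diagonal $T^2_m$) makes
the same test conservative (.02–.03) and sacrifices roughly half the
power of the mean-structure comparisons, because difference contrasts
among correlated means are much more precise than independence implies.
The exchangeable structure — one variance, one common correlation,
mapped onto the interval that keeps compound symmetry positive definite
— captures that correlation with two parameters: the tests sit at
.04–.09, power is restored, and the bias of the factor-mean difference
under violated invariance lands on the analytic projection value. The
full symmetric structure remains the package default for *data
analysis*, where the mean block is the model of record rather than a
nuisance shared across a simulation ladder.

What the generator deliberately does **not** emulate: non-normal raw
data, unequal within-study sample sizes, missing indicators, more than
two groups, moderated heterogeneity, and model misspecification beyond
the single shifted intercept. Passing results therefore speak to the
estimator's behavior under a clean two-group design, not to robustness
against those complications.

## Known limitations

* Correlation-matrix-based MASEM is intentionally unsupported — variances
  and means are the point of this package.
* $T^2$ is assumed equal across moderator values; moderating the
  heterogeneity itself is out of scope (and rarely estimable).
* REML, robust/sandwich standard errors, and Bayesian estimation are not
  provided; ML with observed-information SEs matches the Wald-type
  inference the workflow uses.
* With many indicators relative to the number of studies (e.g. 12
  indicators in ~50 studies), richly moderated models often fail to
  converge. This is a property of the data regime; the package reports
  it and the less moderated models remain interpretable.
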