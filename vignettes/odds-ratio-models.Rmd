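---
title: "Seven random-effects models for the summary odds ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seven random-effects models for the summary odds ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ormeta)
```

## The problem

A meta-analysis of comparative trials with a binary outcome starts from a
series of 2-by-2 tables: for study $i$, the treated arm has $n_{i1}$
patients with $e_{i1}$ events and the control arm $n_{i0}$ patients with
$e_{i0}$ events.  The quantity of interest is the summary odds ratio
$\exp(\theta)$, together with the between-study variance $\tau^2$ of the
study-specific true log odds ratios $\theta_i \sim N(\theta, \tau^2)$.
`ormeta` implements seven random-effects models for this problem, from the
likelihood level up, plus a simulation engine for studying their bias,
precision and confidence-interval coverage.

## The models

**Model 1 (`"1-DL"`, `"1-REML"`, `"1-ML"`)** is the conventional two-stage
approach.  Stage one computes per-study empirical log odds ratios
$y_i = \log\{(A_i/B_i)/(C_i/D_i)\}$ with variances
$s_i^2 = 1/A_i + 1/B_i + 1/C_i + 1/D_i$, adding 0.5 to *all four* cells of
any table containing a zero cell (other tables are untouched; this is the
standard effect-size calculator default, and it applies to Peto effects
too — see below).  Stage two assumes $y_i \sim N(\theta, s_i^2 + \tau^2)$,
estimates $\tau^2$ by the DerSimonian–Laird moment estimator (truncated at
0), REML, or ML, and pools with inverse-variance weights
$1/(s_i^2 + \hat\tau^2)$, treating $\hat\tau^2$ as known.  Wald intervals
use the normal quantile (no small-sample adjustment), matching the most
conventional practice.  A Q-profile interval for $\tau^2$ inverts the
generalised Cochran statistic $Q(\tau^2) = \sum w_i(y_i - \hat\theta)^2$,
$w_i = 1/(s_i^2+\tau^2)$, against $\chi^2_{k-1}$ quantiles; $Q$ is
strictly decreasing in $\tau^2$ so bisection is reliable.

**Models 2–6** describe the binomial counts directly,
$e_{ij} \sim \mathrm{Bin}(n_{ij}, \pi_{ij})$, with logistic linear
predictors:

| model | baselines $\gamma_i$ | random slope coding | covariance |
|-------|----------------------|---------------------|------------|
| 2 | fixed (one per study) | $j\,\epsilon_i$ | $\tau^2$ |
| 3 | random $N(\gamma,\sigma^2)$ | $j\,\epsilon_i$ | $\sigma^2$, $\tau^2$ independent |
| 4 | fixed | $(j-\tfrac12)\epsilon_i$ | $\tau^2$ |
| 5 | random | $(j-\tfrac12)\epsilon_i$ | $\sigma^2$, $\tau^2$ independent |
| 6 | random, bivariate | — | unstructured $2\times 2$ $\Sigma$ |

In every case $\mathrm{E}[\theta_i] = \theta$ and
$\mathrm{Var}[\theta_i] = \tau^2$; for model 6 the arm logits are jointly
normal with mean $(\gamma, \gamma + \theta)$ and
$\tau^2 = \sigma_0^2 + \sigma_1^2 - 2\rho\sigma_0\sigma_1$.  Models 3 and
5 are constrained special cases of model 6 (their maximised
log-likelihoods can never exceed model 6's, a property the test suite
asserts).  The choice between the $j$ and $j - 1/2$ slope codings is *not*
a reparameterisation — it changes the implied covariance of the two arm
logits — whereas the same switch applied to the fixed term $j\theta$ is
pure reparameterisation ($\gamma_i^* = \gamma_i - \theta/2$), which
`reparam_check()` verifies numerically.

**Model 7 (`"7"`)** conditions each table on its total events
$t_i = e_{i0} + e_{i1}$, after which $e_{i1}$ follows the noncentral
hypergeometric distribution with weight $\exp(\theta_i e_{i1})$.  The pmf
is evaluated entirely in log space (log-binomial weights plus log-sum-exp
over the full support, no truncation), which keeps it stable for table
entries into the millions.  The marginal likelihood integrates the pmf
against $N(\theta, \tau^2)$ in the standardised variable
$z = (\theta_i - \theta)/\tau$, so nothing divides by a small $\tau$.
Studies with $t_i = 0$ or $t_i = n_{i0}+n_{i1}$ have a degenerate (point
mass) conditional distribution and contribute nothing to the likelihood,
which is why model 7 is exactly invariant to double-zero studies.  Two
approximations are provided: `"7-AL"`, a rare-event binomial
approximation, $e_{i1} \mid \theta_i \sim \mathrm{Bin}(t_i,
\mathrm{expit}(\log(n_{i1}/n_{i0}) + \theta_i))$, fitted as a
random-intercept logistic model with an offset; and `"7-Peto"`, the
conventional model 1 applied to per-study Peto log odds ratios
$(O_i - E_i)/V_i$ with ML heterogeneity estimation, which is numerically
robust and serves as a sanity check on the fragile exact fit.  The Peto
one-step common-effect estimator $\sum(O_i-E_i)/\sum V_i$ is exposed as
`peto_one_step()`.

## Numerical methods

Random effects are integrated out with *adaptive Gauss–Hermite
quadrature*: nodes (computed once by the Golub–Welsch eigenvalue method)
are recentred at the per-study mode of the log-integrand and rescaled by
its curvature at every objective evaluation; one node per axis is the
Laplace approximation.  The defaults are 7 nodes for models with one
random effect per study (2, 4, 7, 7-AL) and 1 node (Laplace) for models
with two (3, 5, 6) — the same convention as the reference software
defaults for these model families, and cheap enough for large simulation
grids.  On the packaged datasets, moving from 7 to 15 nodes changes the
model-2/4 estimates by less than $10^{-3}$.

Variance components are optimised on unconstrained scales: $\log\tau$ and
$\log\sigma$ for scalar components, and the log-Cholesky factorisation for
model 6's $\Sigma$, which enforces $\rho \in [-1, 1]$ while permitting
boundary solutions (the otitis media example genuinely has $\hat\rho = 1$;
the factor's second diagonal element simply goes to its floor).  $\tau = 0$
is handled by an explicit boundary comparison: the conditional model
profiles $\theta$ at $\tau = 0$ and compares likelihoods, and the
two-stage likelihood estimators compare the interior optimum against the
$\tau^2 = 0$ value before truncating.

For the fixed-baseline models 2 and 4 the optimiser uses a fused
objective/gradient evaluation: the gradient of the marginal log-likelihood
is the posterior expectation of the complete-data score, available from
the same quadrature weights as the objective at essentially no extra cost,
with per-study modes warm-started across evaluations.  Because that
score-form gradient differs from the exact gradient of the *adapted*
quadrature objective by a term of the order of the quadrature error, the
quasi-Newton solution is polished by a short derivative-free pass over the
objective itself; the polish moves estimates by under 0.01 on the most
heterogeneous packaged dataset and much less elsewhere.  Standard errors
come from the numerically differentiated observed information (central
differences, relative step $10^{-5}$), taking the $(\theta,\theta)$ block
of the inverse; this is invariant to the reparameterisation of the
nuisance coordinates.  Failed optimisations restart from up to three
perturbed starts; model 7 falls back to Nelder–Mead with 20000 iterations
at relative tolerance $10^{-4}$.

Mixed-model standard errors can be artificially small in hard problems.
Every GLMM standard error is therefore compared against the robust
`"7-Peto"` standard error; a value below half of it triggers one refit
with a tenfold evaluation budget, and the fit is flagged
(`se_reliable = FALSE`) if the problem persists.  For batch use of model
7, the repair policy substitutes the Peto-approximation standard error
when the exact one is missing, below 50% of the Peto value, or more than
10 times it (values between 2 and 10 times are retained; the 10x cut-off
for "grossly large" is this package's own codification of a qualitative
judgement).

## Zero cells and double-zero studies

Tables with a zero cell get 0.5 added to all four cells for both the
Wald and the Peto effect computations — including double-zero tables,
which therefore still yield a (nearly null) Peto effect.  This matches the
reference effect-size calculator exactly, and reproducing the published
Peto-approximation results for the otitis media outcome requires it; the
raw-count behaviour, in which double-zero studies have undefined Peto
effects, is available via `zero_rule = "none"`.  For model fitting,
`drop00 = "auto"` keeps double-zero studies where they provably cannot
change the fit (models 1, 2, 4, 7) and removes them for the
random-baseline models 3, 5 and 6, where they *do* move the estimates by
recovery of intertrial information — the otitis media dataset shows the
model-6 heterogeneity estimate collapsing from 0.197 to 0.004 when its
double-zero study is excluded.  Both behaviours are selectable.

## The simulation engine

`sim_setting()` encodes 15 generative settings.  The defaults are: $k=10$
studies; treated-arm sizes uniform on $\{50,\dots,500\}$ with equal
control arms; control-group log odds $N(\mathrm{logit}(0.2), 0.3^2)$;
$\tau^2 = 0.024$; and treatment-arm log odds
$LO_c + \theta + \tau Z$, $Z \sim N(0,1)$.  The other settings vary one
ingredient at a time: $\tau^2 \in \{0, 0.168, 2\}$, $k \in \{3,5,20\}$,
small studies, rare ($p_c = 0.05$) and very rare ($p_c = 0.01$) events,
three unequal-allocation rules (all control arms halved; half of them by
simulation order; half of them by rank of the true control risk, which
deliberately correlates allocation with risk), a uniform baseline that
misspecifies the normal-baseline models, and a centred parameterisation
in which half the effect is added to and subtracted from an average log
odds (data generated under models 4/5 rather than 2/3).  Halved sizes are
rounded half-up.  The generator returns the true arm logits as an
attribute, so its moments are unit-tested directly.

`run_study()` fits any model subset to the *same* simulated datasets per
cell, with one RNG stream per (setting, $\theta$) cell derived from the
master seed so that single cells re-run identically in isolation.  A
replicate on which a model fails is discarded for that model only and
logged.  Reported metrics per (setting, model): mean estimates of
$\theta$ and $\tau^2$, empirical SDs, the Monte-Carlo standard error of
the mean (empirical SD$/\sqrt{n}$), 95% Wald coverage, the average
model-based standard error as a percentage of the empirical one, and
failure/repair counts.

What the generator emulates is the randomised-trials ideal: binomial
sampling within arms, normally distributed baselines and effects, and no
selective reporting, publication bias, confounding or outcome
misclassification.  Passing simulation checks therefore demonstrates
correct estimation under the stated models, not robustness to the ways
real review data violate them.

## Problem sizes used in the checks

The package's own verification uses deliberately modest problem sizes
chosen to give informative Monte-Carlo precision: 1000 replicates for the
headline coverage and bias metrics (matching the reference design for the
default setting), 200 replicates for ordering/coverage properties where
the effect being tested is many Monte-Carlo standard errors wide, and 500
replicates of $k=50$ meta-analyses for parameter recovery.  The full
15-setting grid across all eight fits is supported through
`run_study()`/`run_config()` but is not exercised by the tests; the exact
conditional model dominates its cost.

One check deserves a note: in the recovery experiment the mean ML
estimate of $\tau^2$ is compared against the first-order expectation
$\tau^2 - (\tau^2 + \bar v)/k$ rather than $\tau^2$ itself.  ML variance
components carry that downward bias ($\approx 0.0024$ here) by standard
theory; at 500 replicates the Monte-Carlo standard error is smaller than
the bias, so an unadjusted equality check would reject a *correct*
implementation.  The summary effect $\theta$ is unbiased and is checked
against its true value directly.

## Known limitations

* Only the odds ratio scale is supported; no relative risk, risk
  difference, or Mantel–Haenszel pooling.
* No small-sample (Hartung–Knapp-type) interval adjustments; inference is
  Wald-type throughout, as in the models being studied.
* Model 7's exact fit remains numerically delicate in extreme data (very
  rare events with large heterogeneity); the Peto approximation is the
  intended cross-check, and `se_reliable`/repair flags should be heeded.
* The asymptotics behind models 2 and 4 are non-standard (the number of
  fixed baselines grows with $k$); model 2 in particular severely
  underestimates $\tau^2$ — reproduced in the test suite — and is kept
  mainly so that sensitivity analyses can demonstrate the fact.

## A worked example

```{r example}
fit <- meta_or(measles_data(1), model = "1-DL")
fit
or_sensitivity(measles_data(1), models = c("1-DL", "1-REML", "4"))
```
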