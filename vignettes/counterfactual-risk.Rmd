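---
title: "Counterfactual model performance from trial and observational data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual model performance from trial and observational data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrisk)
```

## Setting and estimands

We observe a single table with outcome $Y$, binary treatment $A$, binary
source indicator $S$ ($S=1$ randomized trial, $S=0$ observational study),
and covariates $X$, of which a subset $X^*$ feeds a prediction model
$g(X^*)$. The design is *non-nested*: the two samples are drawn separately
from their super-populations with unknown sampling fractions, so only
odds-type participation weights are identified. The target population is the
one underlying the observational study, where the model would be deployed.
With $Y^a$ the potential outcome under treatment $a$, the two estimands are
the tailored model $\mu_a(x^*) = E[Y^a \mid X^*=x^*, S=0]$ and the
counterfactual risk $\psi(a) = E[L(Y^a, g(X^*)) \mid S=0]$ for a loss $L$
(squared error, Brier for binary outcomes, absolute).

Neither quantity is a function of the observed data without assumptions.
Three analyses identify them:

* **Observational** — consistency, conditional exchangeability of treatment
  groups in the observational source ($Y^a \perp A \mid X, S=0$, i.e. no
  unmeasured confounding), and treatment positivity there. Then
  $\psi(a) = E[\,E[L \mid X, S=0, A=a] \mid S=0\,]$.
* **Transportability** — consistency in both sources, randomization-backed
  exchangeability and positivity in the trial, conditional exchangeability
  of the *populations* ($Y^a \perp S \mid X$), and positivity of trial
  participation. Then $\psi(a) = E[\,E[L \mid X, S=1, A=a] \mid S=0\,]$.
  Notably this expression never touches outcome or treatment data of the
  target rows — a property the test suite enforces literally, by replacing
  target-row $Y$ and $A$ with sentinels and requiring bit-identical output.
* **Joint** — all assumptions at once, under which the conditional losses
  agree across sources and may be pooled:
  $\psi(a) = E[\,E[L \mid X, A=a] \mid S=0\,]$. The pooled regression uses
  the most data, so when its extra assumptions hold it is the most
  efficient; an optional diagnostic refit adds $S$ as a predictor to probe
  the pooling equality.

The exchangeability assumptions are untestable; the positivity assumptions
can at least be inspected, which `positivity_diagnostics()` does by
reporting propensity ranges per source and flagging target rows whose
estimated $\Pr(S=1\mid X)$ falls below a threshold (default 0.01).
Diagnostics warn and never abort: assumption checking is advisory.

## Estimators

Per-row losses $L_i = L(Y_i, g(X^*_i))$ are the regression targets
throughout (not $Y$ itself), matching the risk estimand. Writing
$\hat h_{a,s}(X)$ for the fitted conditional loss in cell $(S=s, A=a)$,
$\hat h_a(X)$ for the pooled fit, $\hat e_a(X, s)$ for treatment
propensities, and $\hat w(X) = \widehat{\Pr}(S=0\mid X)/\widehat{\Pr}(S=1\mid X)$
for the participation odds:

* **Outcome model**: $\hat\psi = n_0^{-1}\sum_{S_i=0} \hat h(X_i)$ with
  $\hat h$ chosen by analysis.
* **IPW**: weighted means of observed losses with weights
  $I(S=0, A=a)/\hat e_a$ (observational),
  $I(S=1, A=a)\,\hat w/\hat e_a$ (transportability), and
  $I(A=a)\,[I(S=0) + I(S=1)\hat w]/\hat e_a(X, S)$ (joint).
* **Doubly robust**: outcome-model term plus the same weights applied to
  residuals $L_i - \hat h(X_i)$; consistent when either the loss regression
  or the weight models are correct.

Two normalizations are offered. The displayed estimators use $1/n_0$
scaling (`"ht"`). The default is Hajek (`"hajek"`): weighted sums are
divided by the sum of the weights (and the doubly robust correction is the
Hajek mean of the weighted residuals). We made Hajek the default because it
recovers a constant loss *exactly* under every analysis, keeps estimates
inside the range of the losses, and absorbs the unknown multiplicative
constant in the non-nested participation odds. The toy example in the test
suite shows why the choice matters: with $n_0$ target rows but trial weights
summing elsewhere, `ht` and `hajek` can differ by a factor of two on the
same data. For the joint doubly robust estimator the residual correction
uses both sources by default (`joint_residuals = "both"`); a trial-only
variant is available.

Nuisance learners default to main-effects linear regression for conditional
losses and main-effects logistic regression for propensities and
participation — the standard parametric implementation — with saturated
(cell-mean), polynomial-degree, random-forest, and user-supplied learners
available. Probabilities are clipped to $[0.001, 0.999]$ (configurable) to
stabilize weights; an estimate with more than 10% of its weighted rows at a
clip bound triggers a warning. Cross-fitting (K seeded folds, off by
default) is available for flexible learners; the parametric defaults do not
need it. If the trial randomization probability is known it can be supplied
and is used verbatim for the trial propensity.

Tailored models use the two-step procedure: regress $Y$ on the full $X$ in
the analysis cell, predict for *all* target rows regardless of their actual
treatment, then regress those predictions on $X^*$ among target rows.
Squared-error regression is used for step 2 throughout, including for
binary step-1 predictions; the nonparametric alternative for low-dimensional
discrete $X^*$ is covered by the saturated learner rather than a second code
path. When $X^* = X$ and step 2 can represent step 1's surface, step 2
reproduces step-1 predictions exactly (tested on discrete data).

## Inference and benchmarking

Standard errors come from the nonparametric bootstrap, stratified by source:
every replicate redraws $n_0$ target and $n_1$ trial rows with replacement,
because the non-nested design fixes the per-source sample sizes;
unstratified resampling is deliberately not offered. All nuisance models are
refit inside each replicate so the intervals reflect nuisance estimation.
Defaults are $B = 500$ and Wald intervals from the bootstrap SE, with
percentile intervals for skewed losses. Replicates that lose a required cell
are retried with a fresh resample (up to 10 times), then counted; more than
5% failures warns. The seed, $B$, and the data fully determine every output.

Benchmarking reports $\hat\Delta = \hat\psi_{obs} - \hat\psi_{tr}$ with a
bootstrap CI of the *paired* difference — both analyses see the same
resampled rows within a replicate — and a concordance flag (CI contains
zero) plus the absolute difference. Concordance supports the assumptions
but cannot prove them: both analyses could be biased the same way. The
package reports; the user judges, ideally with subject-matter knowledge.

## The synthetic-data generator

The generator emulates the structure of a comprehensive cohort study: a
trial and an observational study with shifted covariate distributions,
confounded treatment only in the observational source, and an unmeasured
covariate $U$ driving selective violations. Per row of source $s$:
$X \sim N(0.5\,I(s=0), 1)$, $U \sim N(0,1)$ independent of $X$;
$A \sim \text{Bern}(0.5)$ in the trial and
$\text{Bern}(\text{expit}(\alpha_0 + \alpha_X X + \beta_{AU} U))$ otherwise;
$Y^1 = 1 + X + \mu_{YU} U + e_1$ and $Y^0 = X + \mu_{YU} U + e_0$ with
$e_0 \sim N(0, \sigma_\varepsilon)$,
$e_1 \sim N(0, \sqrt{\sigma_\varepsilon^2 + \sigma_{YU}^2 U^2\, I(s=0)})$;
and $Y = A Y^1 + (1-A) Y^0$, so consistency holds by construction. The
oracle columns $(U, Y^0, Y^1)$ live outside the observed container and are
unreachable by estimator code.

The three knobs isolate the two exchangeability assumptions:
$\beta_{AU} = 0$ makes $A \perp U$ given $X$ (treatment exchangeability
holds); $\sigma_{YU} = 0$ makes the conditional distribution of the $Y^1$
residual identical across sources (population exchangeability holds for the
squared-error functional). The noise enters as
$\sqrt{\sigma_\varepsilon^2 + \sigma_{YU}^2 U^2}$ — and only for $Y^1$,
only in the target source — because that form yields a clean closed-form
truth: for squared error, $a=1$, and $g$ equal to the true conditional mean,
$\psi(1) = \mu_{YU}^2 + \sigma_\varepsilon^2 + \sigma_{YU}^2$ (since
$\operatorname{Var}(U) = E[U^2] = 1$), and it guarantees the transport
estimator's limiting relative bias is
$-\sigma_{YU}^2/(\sigma_\varepsilon^2+\sigma_{YU}^2)$ when only
$\sigma_{YU}$ is on. The default covariate shift $\mu_{X0}=0.5$ keeps the
transport weighting non-trivial; setting it to 0 gives the
identical-populations sanity case.

What the generator does *not* emulate: missingness, censoring,
non-adherence, multi-dimensional or non-Gaussian $U$, and real-data quirks
such as measurement error. Passing tests therefore demonstrate estimator
correctness under the stated mechanism, not robustness to everything real
data can do.

### The four canonical cases

`canonical_cases()` fixes one configuration per violation pattern:

| case | $\beta_{AU}$ | $\mu_{YU}$ | $\sigma_{YU}$ | biased analysis |
|---|---|---|---|---|
| 1 | 0 | 0 | 0 | none |
| 2 | 0 | 0 | 1 | transportability ($-50\%$ relative) |
| 3 | 2 | 2 | 0 | observational ($\approx +28\%$ relative) |
| 4 | 2 | 2 | 1 | both |

All four share $\alpha_0 = -1.5$ in the confounded treatment model
(treatment taken up by roughly 31% of the observational source, selectively
in $U$). The asymmetric intercept is a deliberate design choice: with a
symmetric intercept, logistic selection on $U$ barely moves the second
moment $E[U^2 \mid A=1]$, and the squared-error risk of a correctly
specified $g$ is almost unaffected even by strong confounding — the
confounding shifts the mean of $U$ among the treated but compensates by
shrinking its variance. Making treatment uncommon and selective breaks that
cancellation and produces a confounding bias large enough to study
benchmarking power. The sign of the case-3/4 observational bias (upward
here) is a property of this mechanism; other mechanisms can produce the
opposite sign.

## Study sizes and numerical choices

The simulation studies in the test suite and `scripts/acceptance.R` use
sizes chosen to keep Monte-Carlo error well below the effects under study:
bias grid 500 datasets per case at $n_0=n_1=2000$; closed-form recovery of
all nine estimators, 500 datasets; efficiency study 500 datasets per
$(n_0, n_1)$ cell, where the joint estimator's variance runs at roughly half
of either single-source variance; double robustness 200 datasets at
$n=4000$ (misspecified-component bias $\approx 12\%$ relative versus $<2\%$
for the doubly robust estimator); bootstrap coverage 400 outer datasets
$\times$ $B=200$ at $n_0=n_1=1000$ (coverage $\approx 0.94$); benchmarking
300 no-violation and 100 confounded datasets with $B=200$. The
demonstration pipeline dichotomizes the outcome at 1 (near the overall
median under the default coefficients), trains a 500-tree random forest on
a 50% split of the target rows, and evaluates the full 18-cell grid with a
shared set of stratified bootstrap resamples.

Other numerical choices: one-hot encoding uses lexicographic level order
with the reference level dropped, so designs are full-rank and loading is
byte-deterministic; saturated learners fall back to the global cell mean for
unseen covariate patterns; rank-deficient least-squares coefficients are
zeroed rather than propagated as `NA`; all randomness flows from explicit
integer seeds through isolated RNG scopes, leaving the caller's RNG state
untouched.

## Limitations

Per-analysis covariate sets are not supported — one shared $X$ serves all
three analyses, although in practice the observational source may record
more covariates than the trial. Nested sampling designs, general or
stochastic treatment regimes, censoring and missing data, uniform
confidence bands over $X^*$, sandwich variances, and AUC/calibration
transportability are out of scope. The doubly robust forms are the standard
augmented ones; their efficiency is demonstrated by simulation against
oracle truths rather than derived here.
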