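---
title: "Methods: item response theory based pharmacometric modeling of cognitive assessment data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: item response theory based pharmacometric modeling of cognitive assessment data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogirt)
```

## The problem

Composite cognitive scales such as the ADAS-cog aggregate a dozen
heterogeneous components — pass/fail tasks, word-list tests, a timed
number-cancellation test and rater-judged severity categories — into a
single total score. Analyzing only the total discards the component-level
structure: items differ sharply in where on the disease continuum they
are informative, studies administer different variants of the scale, and
the bounded total behaves poorly near its floor and ceiling. `cogirt`
implements an item response theory (IRT) treatment of such data combined
with a pharmacometric (nonlinear mixed-effects) model of disease
progression, so that item-level responses, longitudinal trajectories,
dropout and treatment effects are described in one likelihood.

## Latent scale and item models

All item models condition on a scalar latent *cognitive disability*
$D_i$ for subject $i$. At baseline $D_i \sim N(0, 1)$; this fixes the
location and scale of the latent metric (a Z-score relative to the
calibration population). Larger $D$ means worse cognition: failure
probabilities and error counts increase with $D$, cancellation points
decrease.

Five response families cover the component types:

* **Binary tasks** (3PL): the failure probability is
  $p_j(D) = c_j + (1 - c_j)\,\mathrm{logit}^{-1}\!\big(a_j (D - b_j)\big)$
  with discrimination $a_j > 0$, difficulty $b_j$, and a lower asymptote
  $c_j$, the failure probability of a cognitively intact subject
  (non-zero for reasons unrelated to cognition, e.g. restricted shoulder
  motion for a "tap shoulder" command).
* **Word-list tests**: the number of missed words out of $n$ is binomial
  with per-word failure probability from the 3PL curve. The three recall
  trials and delayed recall are separate items with their own parameters
  (learning across repetitions shows up as shifted difficulties).
  Study variants that store a truncated count renormalize the binomial
  over the stored support.
* **Word recognition** adds an upper asymptote $d_j \le 1$: even
  severely impaired subjects classify some words correctly by chance, so
  $p_j(D) = c_j + (d_j - c_j)\,\mathrm{logit}^{-1}(a_j (D - b_j))$.
* **Number cancellation**: points 0–40 follow a generalized Poisson
  distribution with mean curve $p_j(D) = d_j\,(1 -
  \mathrm{logit}^{-1}(a_j(D - b_j)))$ and dispersion $\delta$.
  The distribution is renormalized over the attainable score range
  0–40, which keeps every predicted score within the test's support;
  $\delta$ is constrained so that every term of the pmf stays positive
  over the whole support ($p(D) + \delta k > 0$ for $k \le 40$), and
  draws violating the constraint are rejected at fit time.
* **Rater items**: five ordered severity categories via a
  proportional-odds model, $P(Y \ge k) =
  \mathrm{logit}^{-1}(a_j(D - b_{j,k}))$ with non-decreasing thresholds
  $b_{j,k}$; category probabilities are cumulative differences.

`item_spec()` / `item_bank()` carry these parameters together with
per-study variant masks (which items a study administered) and the score
map used to roll item outcomes back up to the familiar total.

## Estimation

### Baseline (cross-sectional)

Item parameters are estimated by marginal maximum likelihood: the latent
disability is integrated out of each subject's response-pattern
likelihood against the $N(0,1)$ prior. The default integration is a
fixed 61-node Gauss–Hermite rule. Because the prior is a standard normal
and baseline posteriors concentrate well inside $\pm 4$, a fixed rule of
this order is as accurate as adaptive quadrature here, and it admits a
response-table formulation whose exact analytic gradient (posterior-
weight accumulation over the nodes) makes the joint optimization of all
item parameters fast and reliable. Adaptive Gauss–Hermite (mode- and
curvature-rescaled nodes) and the Laplace approximation are available as
methods both for `fit_baseline()` and for per-subject marginals
(`marginal_loglik()`), and the test suite pins all three against dense
grid integration.

Bounded parameters are transformed ($\log a$, logit for probabilities,
$d = c + (1-c)\,\mathrm{logit}^{-1}(z)$ to keep $c < d$, thresholds as a
first threshold plus log-increments). Default starting values are
neutral: $a = 1$, $b = 0$, $c = 0.05$, recognition $d = 0.95$, count
mean 30, $\delta = 0.02$ (just inside the boundary, since the dispersion
is estimated on a logit scale), thresholds equally spaced on $[-1, 2]$.
Items answered by too few subjects, or with degenerate (all-pass /
all-fail) responses, are held at their starting values under a named
warning. Standard errors, when requested, come from the numerically
differentiated observed information and are skipped with a warning if
the Hessian is not positive definite.

Multi-study pooling is by design trivial in the IRT formulation: one
shared parameter set, and items a study did not administer are simply
absent from its subjects' likelihoods (missing completely at random by
design).

Empirical Bayes disability estimates (`estimate_ebe()`) are posterior
modes with curvature-based uncertainties; subjects without records fall
back to the prior ($\hat d = 0$, sd 1) with a warning.

### Longitudinal

Disease progression acts on the latent scale:
$$D_i(t) = D_i^0 + a_i\,t, \qquad
  D_i^0 = \theta_1 + \eta_{i1}, \qquad
  a_i = (1 - \beta\,x_i)\,(\theta_2 + \eta_{i2}),$$
with correlated bivariate normal random effects
$(\eta_{i1}, \eta_{i2})$ (SDs $\omega_1, \omega_2$, correlation $\rho$),
treatment indicator $x_i$ and a fractional drug effect $\beta$ on the
subject-specific slope — a disease-modifying effect that multiplies the
whole random slope, not just its typical value. Slopes are per year;
the interface carries months (the conventional clinical unit) and
converts internally. A linear shape is deliberate: over an 18–20 month
trial the total latent change is small relative to the scale of the
item curves, so curvature is not identifiable and the linear model is
the parsimonious choice.

Item parameters are fixed to their baseline calibration; the joint
subject likelihood integrates the product of item likelihoods along the
trajectory (and the dropout likelihood, below) over the two random
effects. The default integration is the per-subject Laplace
approximation (Newton mode search with analytic first and second
derivatives of every item family's log-likelihood); adaptive 2-D tensor
Gauss–Hermite (default $7 \times 7$) is available via `method = "agh"`.
Both are verified against dense 2-D grid integration in the tests.

Dropout is interval censored: a subject last seen at visit $t_k$ and
absent thereafter contributes $\log\{S(t_k) - S(t_{k+1})\}$, a completer
$\log S(T)$ at the last scheduled visit, where
$S(t) = \exp(-\int_0^t h)$. Four log-linear hazards are supported:
constant, current-disability dependent ($\log h = \theta_3 + \theta_4
D_i(t)$), progression-rate dependent ($\theta_4 a_i$) and
baseline-disability dependent ($\theta_4 D_i^0$). All four cumulative
hazards are closed form — the current-disability hazard is exponential-
linear in time, $H(t) = e^{\theta_3 + \theta_4 D_i^0}\,
(e^{\theta_4 a_i t} - 1) / (\theta_4 a_i)$ with the obvious limit as
$\theta_4 a_i \to 0$ — and a numeric quadrature route is kept as an
independent cross-check rather than as the implementation.
`select_hazard()` compares each covariate hazard against the constant
one by a 1-df likelihood-ratio test at the 5% level, warm-starting every
covariate fit from the constant-hazard optimum so the nested-likelihood
ordering is guaranteed.

### Numerical acceleration

Because the longitudinal fit holds item parameters fixed, every item's
outcome log-likelihood is a fixed smooth function of $D$. These
functions (values, first and second derivatives) are tabulated once per
bank on a latent grid ($[-12, 14]$, step 0.02) and interpolated during
optimization — cubic Hermite in the value/gradient, linear in the stored
second derivative. Interpolation error is far below the Monte-Carlo
noise of any simulation experiment (estimates agree with the exact
objective to about four decimals); the reported log-likelihood is always
re-evaluated exactly at the optimum, and `use_tables = FALSE` restores
the exact objective throughout, which is what `joint_loglik()` (the
oracle-grade entry point) always uses. Optimization is quasi-Newton
(`nlminb`) on transformed parameters ($\log \omega$, $\tanh^{-1}\rho$)
with two-stage starting values: per-visit empirical Bayes disability
scores regressed on time within subject.

## Fisher information and component ranking

The Fisher information of an item for the latent disability is the
negative expected curvature of its log-likelihood in $D$ — closed form
for the binary ($p'^2 / p(1-p)$), binomial ($n$ times the per-word
information) and ordered ($\sum_k P_k'^2 / P_k$) families, and a
numeric expectation over the truncated support (via the squared-score
identity) for the generalized Poisson and truncated-binomial variants,
with the finite-difference expectation kept as the independent oracle.
Because $D$ is the only random quantity, information is additive over
items; `average_information()` integrates an item's curve against a
normal population distribution (Gauss–Hermite), and `rank_components()`
sums item averages within components and ranks them with a
percent-of-total column (ties broken alphabetically). The population
means and SDs are explicit inputs: rankings in different disease stages
(e.g. MCI vs mild AD) differ because component information curves peak
at different disabilities.

## Trial simulation

`simulate_trial()` draws the correlated random effects, applies the
arm-specific slope, samples every administered item at each attended
visit, and samples dropout by inverse-transform of the subject-specific
survival function (root-free, since all cumulative hazards are closed
form and monotone). Attendance is monotone: a subject attends all visits
strictly before the dropout time, the dropout interval being (last
attended, first missed]. `simulate_baseline_studies()` generates pooled
cross-sectional data across study variants that differ in administered
components, including truncated recognition storage and a three-trial
recognition variant.

The committed banks — `default_item_bank()` (13 components, 44 core
items plus variant items) and `reduced_item_bank()` (20 items spanning
every family) — are hand-authored, calibrated to be plausible for a
mild-to-moderate AD population: binary difficulties spread over the
populated latent range with small floors, word-list items most
discriminating (as memory components are in practice), delayed recall
informative at low disability, rater items weakly informative with a
dominant lowest category. They are synthetic and are not estimates from
any clinical database; analyses that need published item estimates can
load them through `check_external_estimates()`.

What the generator emulates: conditional independence of items given the
latent state, between-subject heterogeneity in level and progression
rate, arm effects on the slope, monotone interval-censored dropout, and
variant heterogeneity across studies. What it does not emulate: rater
effects and longitudinal rater drift, practice/learning effects beyond
the static repetition difficulties, intermittent missed visits,
item-level local dependence, and non-normal latent distributions.
Passing simulation tests therefore demonstrates self-consistency of the
machinery under the stated assumptions, not robustness of the models to
their violation in field data.

The default total-score map is configuration, not code: failures summed
for task components, mean errors over the recall trials (rounded half
up), recognition errors, rater categories, and cancellation points
binned into 0–5 (fewer points, higher score). Partially observed
components are prorated by default (configurable to `NA`).

## Analysis methods compared

Three analyses of a simulated trial are implemented:

* `irt_analysis()` — the longitudinal IRT model above with $\beta$ free;
  the decision is the Wald test of $\beta$ at 5% (95% CI excluding 0),
  with the standard error from the observed information.
* `fit_total_score_model()` — a pharmacometric linear mixed model for
  the total score: $Y_{ij} = (B + \eta_{Bi}) + (1 - \beta x_i)(S +
  \eta_{Si})\,t_{ij} + \varepsilon_{ij}$ with correlated random
  intercept/slope and additive residual, fitted by exact Gaussian
  maximum likelihood. This is a reconstruction of the standard linear
  disease-progression total-score analysis (the minimal model of that
  family); scores are analyzed untransformed, mirroring common practice
  with bounded totals.
* `ls_means_analysis()` — change from baseline with treatment, visit
  (categorical), treatment-by-visit interaction and baseline as
  covariate, subjects as grouping factor, fitted by `nlme::gls` with
  compound-symmetric within-subject covariance (the stable small-sample
  default; unstructured covariance is an option). The decision contrast
  is the treatment difference at the last scheduled visit. With no
  dropout this analysis is the MMRM.

`estimate_power()` / `estimate_type1()` run seeded replicate trials and
analyze each replicate with every requested method (common random
numbers, which sharpens between-method comparisons), reporting rejection
fractions with Wilson intervals; failed fits count as non-significant
(conservative). `subjects_for_power()` interpolates a power curve after
isotonic smoothing, resolving flat tie groups to their largest sample
size.

## Diagnostics

`icc_vs_smoother()` compares a model item curve with a penalized
cubic-regression-spline smoother (`mgcv::gam`, GCV-selected smoothness;
logit link for binary outcomes) of observed outcomes against empirical
Bayes disability estimates, with pointwise 95% bands and optional
per-study stratification. Note that empirical curves built on shrunken
EBE scores are mildly attenuated relative to the true ICC; the
comparison is a qualitative misfit detector, not an unbiased estimate of
the curve. `vpc()` is a simulation-based predictive check at three
levels — total-score percentiles per visit, per-item outcome fractions
per visit, and the retention curve — with percentile bands across seeded
replicates (no band smoothing).

## Problem sizes and test-suite settings

The simulation experiments shipped with the package run at desk scale,
chosen so the whole suite completes comfortably on a single core:
longitudinal recovery at 322 subjects and 8 visits averaged over 10
replicates; drug-effect recovery at 400 subjects over 20–50 replicates;
type-I calibration over 300 null trials of 200 subjects; the
three-method power comparison over 200 shared replicates at 200 and 400
subjects; baseline item recovery at 2,000 subjects with the 20-item
bank. Recovery tolerances in the tests reflect the statistical
information actually available at those sizes; in particular the binary
items' lower asymptote (and with it the slope/difficulty of easy items)
is weakly identified at n = 2,000, so the binary-family tolerances are
wider than those of the word-list, count and rater families. Reported
Monte-Carlo quantities always carry their replicate counts and seeds.

## Known limitations

* One latent dimension; no covariates on the latent trait at baseline;
  no item-parameter drift over time.
* Linear latent progression only (by design, for trial-length horizons).
* The dropout inverse-CDF and interval likelihood assume monotone
  missingness at scheduled visits.
* Laplace marginal likelihoods for very sparse subjects (few items per
  visit) are less accurate than adaptive quadrature; the `method`
  argument exposes the trade-off.
* The EBE-based smoother diagnostic inherits shrinkage attenuation, as
  noted above.
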