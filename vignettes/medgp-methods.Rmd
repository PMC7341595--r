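---
title: "Methods: sparse multi-output GPs for clinical time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse multi-output GPs for clinical time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(medgp)
```

This vignette is the package's own account of the model it implements, the
choices made where the design was genuinely open, and what the synthetic
experiments do and do not establish.

## Model and assumptions

A patient's D covariates (vital signs, laboratory values) are modelled as
noisy observations of a zero-mean multi-output Gaussian process over time.
Time is measured in hours since admission. The joint kernel is a linear
model of coregionalization over Q spectral-mixture basis kernels,

$$\kappa\big((d,t),(d',t')\big) \;=\; \sum_{q=1}^{Q} b_{q,(d,d')}
  \, e^{-2\pi^2 \rho^2 v_q}\cos(2\pi\rho\mu_q), \qquad \rho = |t-t'|,$$

with $\kappa_q(0)=1$ so that all amplitude information lives in the weight
matrices $B_q = A_qA_q^\top + \mathrm{diag}(\lambda_q)$ — PSD by
construction, strictly PD when all $\lambda$ are positive. The model
assumes stationarity within the modelled window (appropriate for stable or
recovery-phase inpatient episodes, not for acute decompensation), Gaussian
residuals with covariate-specific variances, and no mean structure: each
covariate is standardized to its history mean and standard deviation before
fitting, and predictions are mapped back.

Key interpretation aids: the characteristic period of kernel $q$ is
$1/\mu_q$ and its length scale $1/(2\pi\sqrt{v_q})$; a kernel with
$\mu_q = 0$ is a squared exponential. These two conversions
(`period_to_mu()`, `lengthscale_to_v()`) are the single source of truth
used by initialization and reporting.

## The shrinkage prior

Each $A_q$ entry carries a four-level hierarchical gamma chain (shapes
$\alpha=\beta=\gamma=\xi=0.5$, recapitulating two layers of the horseshoe):
every gamma is shape/rate, and each level's value is the *rate* of the level
below, so a large global $\tau_{q,(r)}$ shrinks its whole column. The
$\lambda$ entries are non-negative with a Laplace prior on their magnitude,
i.e. an exponential with scale $\beta_\lambda = 0.01$ on the half-line.
Frequencies and spectral variances get flat priors; their initialization
ranges (periods 24–72 h, length scales 6–72 h) act as soft box constraints —
hard clamping inside the optimization loop would break the monotone-trace
property of the inner optimizer, so bounds are enforced at initialization
only.

The latent scales are updated in closed form as the modes of their full
conditionals — derived here because only the chaining convention, not the
update equations, is public:

* $\psi \mid a, \delta$: generalized inverse Gaussian with order
  $\alpha - 1/2$; its mode is always positive when $a \ne 0$;
* $\delta \mid \psi,\phi \sim \mathrm{Ga}(\alpha+\beta,\ \psi+\phi)$;
* $\phi \mid \delta,\tau \sim \mathrm{Ga}(D\beta+\gamma,\ \sum_d\delta+\tau)$;
* $\tau \mid \phi \sim \mathrm{Ga}(\gamma+\xi,\ \phi+\eta)$.

When a conditional's shape is $\le 1$ its mode sits at the boundary, and the
conditional *mean* is used instead. At the default shapes this applies to
$\delta$ and $\tau$ (shape exactly 1). A consequence worth stating plainly:
with the mean fallback, iterated scale sweeps converge to a fixed point but
are not exact coordinate ascent, so the outer objective can dip slightly
between iterations early in a sparse-prior fit. Monotonicity is guaranteed
(and tested) for the gradient stage and for fits without the prior; the
$|\Delta Q| < 0.005$ stopping rule is unaffected because the sweeps
contract geometrically. Every update is verified against a 1-D numerical
optimizer in the test suite.

Two numerical floors matter. The local variance $\psi$ is floored at
$10^{-6}$: a pruned entry then equilibrates near $10^{-5}$ — far below the
$10^{-3}$ "near-zero" reporting threshold — while keeping the $1/\psi$
curvature small enough that the optimizer's global trust region is not
destroyed by dead coordinates. The global shrinkage rate $\eta$ defaults to
0.1 (the midpoint of the 0.01/0.1/1.0 grid one would cross-validate over);
*larger* $\eta$ produces *smaller* global $\tau$, hence larger local
variances and looser shrinkage.

## Fitting

`fit_patient()` alternates (1) the closed-form scale updates with (2)
maximization of the log posterior over kernel parameters by Møller's scaled
conjugate gradient, implemented in the package (no line-search function
evaluations; steps are accepted only if they improve the objective, making
the stage monotone by construction). Positives are optimized as logs; $A$
entries are raw. The optimizer treats trial points with overflowed
parameters or unfactorable Gram matrices as $-\infty$ and rejects them.
Gram factorizations add escalating relative jitter
($10^{-8}\,\overline{\mathrm{diag}} \times 10$ per retry, ceiling
$10^{-2}$) before raising an error. Initialization draws `n_init` (default
1000) candidate kernels uniformly over the stated ranges, with $A$ entries
uniform in $(-1.5, 1.5)$, scores each by the exact marginal likelihood and
keeps the best (first index wins ties). Because the posterior is
multimodal in the frequencies — at sparse sampling a kernel can lock onto a
period *alias* with locally maximal likelihood — `fit_config(n_starts = m)`
enables triaged multi-start: the top-m initialization candidates each run
`triage_iters` outer cycles and only the best objective continues to
`max_iters`. The heavy numerics — block Gram
assembly, marginal likelihood, analytic gradients for all five parameter
classes — live in compiled RcppArmadillo code; the pure-R `gram()`, a dense
multivariate-normal oracle and finite differences serve as independent
cross-checks in the tests.

## Population prior and online updating

Fitted basis kernels whose $B_q$ is entirely near zero (all entries
$\le 10^{-3}$) are dropped; the rest are represented by their kernel values
at hourly lags 1–72 h (lag 0 is identically 1 and carries no information;
a switch restores it) and clustered with a Gaussian mixture selected by BIC
over $1 \le Q' \le Q$. Two clustering choices are the package's own. First,
each component has its own *diagonal* covariance: with 72-dimensional
features, unconstrained covariances put ~2,700 parameters per component
into the BIC penalty, which at realistic numbers of fitted kernels (tens to
a few hundred) always selects a single cluster regardless of separation.
Second, component variances are floored at 0.01 per dimension (0.1 in
kernel-correlation units): kernel features lie on a two-parameter manifold,
so without a resolution scale BIC splits tight families into arbitrarily
many micro-clusters. The floor declares kernel shapes closer than ~0.1 to
be the same cluster; the KDE aggregation absorbs variation at that scale.

Within a cluster, every $B$ entry is aggregated by a Gaussian-KDE
density-weighted mean with Silverman's bandwidth (outliers are
down-weighted; a single member passes through unchanged). The kernel-shape
parameters $\mu$ and $v$ instead use the KDE density *argmax*: kernel shape
is strongly non-linear in $(\mu, v)$, and member frequencies form lumps of
period aliases (a cluster can contain kernels with periods of 25 h and
700 h that behave identically at daily lags); the weighted mean of such
lumps is a kernel unlike any member, while the argmax picks the dominant
lump. Density-weighted means for shape parameters are exactly the
instability the grid-based fallback (below) exists for. If one patient
contributed several kernels to a cluster their
$B$ matrices are summed first — the kernel is additive. The aggregated $B$
is symmetrized, eigenvalue-floored at zero, and refactored as
$A = U_R\,\mathrm{diag}(\sqrt{s_R})$ with
$\lambda_d = \max(B_{dd} - (AA^\top)_{dd},\ 0)$, preserving the diagonal
and guaranteeing PSD. Noise variances and standardization statistics are
averaged arithmetically across patients. Clusters are reported in order of
descending length scale. For univariate baselines, density-weighted means
are replaced by the argmax of each hyperparameter's KDE on a 32-point
log-spaced grid over the observed range (density-weighted means are
unstable with one covariate's worth of members).

`run_online()` processes a new patient's observations in time order. The
conditioning set for an observation at time $t$ is everything strictly
earlier plus same-time observations of *other* covariates; same-covariate
simultaneous observations are excluded from each other. Predictive
variances include observation noise, so 95% intervals are intervals for
observations. After each prediction, one momentum step (momentum 0.9,
learning rate $10^{-5}$) is taken on all non-frozen hyperparameters using
the gradient of the log marginal likelihood restricted to observations in
the trailing 72-h window $(t-72, t]$ — prediction uses the full history,
only the update gradient is windowed. $A$ entries whose magnitude in the
prior is $\le 10^{-3}$ are pinned to exactly zero, preserving the empirical
sparsity structure. Standardization statistics come from the population
prior, never from the patient's own future data. A numerically failed
update is skipped with a warning; prediction continues.

## Evaluation

MAE and 95% coverage are computed per covariate from online traces. The
naive one-lag baseline carries the previous value forward and has no
predictive distribution (coverage is not applicable, not zero). Univariate
GP baselines run the identical online protocol at D = 1, with the SE
variant the SM kernel with frequency fixed at zero. `compare()` aligns
prediction events by (patient, covariate, time), computes the percent MAE
improvement (positive = method better), and applies a two-sided paired
t-test on per-event absolute errors with a Bonferroni threshold
$\alpha / D$. The default $\alpha = 0.01$ reproduces both reference
thresholds ($4.17\times10^{-4}$ at 24 covariates, $0.005$ at 2). Per-event
errors are pooled across patients within a covariate.
`crossvalidate()` partitions patients into seeded folds, fits each patient
once (fitting is fold-independent), builds one population prior per fold
from the training patients and evaluates online prediction on the held-out
patients.

## The synthetic generator

`simulate_cohort()` draws, per patient, a uniform length of stay, a
jittered-gap renewal process per covariate (gap $\times U(0.5, 1.5)$;
vitals every 4 h, labs daily by default — the sampling densities of general
inpatient wards), exact joint latent values via one Cholesky of the full
truth Gram matrix, and covariate-specific Gaussian noise. Three scenarios
ship as study conditions: `two_correlated` (a PT/INR-like pair sharing a
rank-1 long-term kernel plus a weaker circadian kernel), `vitals_labs`
(two vitals carrying a 24-h circadian kernel and an Hct/Hgb/RBC-like
correlated triple on a >3-day smooth kernel, block-structured so neither
kernel loads across blocks), and `independent` (diagonal weights; negative
control). The generator reproduces the *assumption class of the model* —
which is exactly what parameter-recovery and calibration tests require —
and deliberately omits features of real EHR data: informative missingness,
artifacts, non-stationary disease phases, alignment to clinical events,
and non-Gaussian residuals. Passing tests therefore demonstrate correctness
of the machinery, not clinical performance.

## Problem sizes used by the experiments

The shipped experiments are scaled for a single CPU. Parameter recovery
fits 20 single patients of the `two_correlated` scenario with 3-h sampling
over ~10-day stays (T ≈ 160); the recovery criterion is the median relative
error of the circadian period below 10%. Sparsity recovery uses a pure
shared-latent pair (rank-1 truth, $\lambda = 0$) and checks the dominant
kernel's second column norm falls below $10^{-3}$. Calibration runs the
true `vitals_labs` model as a frozen prior over ~2,400 online events and
expects 93–97% empirical coverage. Online adaptation plants a 30-h patient
rhythm under a 24-h prior and compares final-quartile MAE with and without
updating over 10 seeds. The cross-validated comparison simulates 30
patients with 240–400-h stays (10–17 days; at shorter stays daily labs
yield under ~8 observations per covariate and per-patient kernel estimates
alias in period, which is a property of daily sampling, not of the
implementation) and uses 3 folds. Fitting budgets in the experiments
(100–120 restarts, 10–15 outer iterations, 40–60 inner iterations) are
reduced from the package defaults (1000 restarts, 30 outer iterations);
the defaults remain the reference protocol.

## Known limitations

* Exact inference is $O(T^3)$ per patient; patients beyond a few thousand
  observations need an approximation this package deliberately does not
  include (no inducing points, no variational inference).
* The mean-fallback scale updates make the outer objective non-monotone in
  sparse-prior fits (see above); in practice dips vanish as the sweeps
  converge.
* Period estimation from sparsely sampled covariates is alias-prone; the
  population-level clustering and density-weighted aggregation are the
  mitigation, and they need enough observations per patient to work with.
* Online updating with the reference learning rate ($10^{-5}$) adapts
  slowly by design; it corrects moderate prior mismatch within a stay but
  will not overturn a badly wrong prior.
* The coverage statistic treats the 95% interval per event; it does not
  account for dependence between events of the same patient.
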