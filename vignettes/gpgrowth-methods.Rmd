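---
title: "Modeling, clustering and forecasting childhood BMI trajectories with gpgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling, clustering and forecasting childhood BMI trajectories with gpgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pediatric growth surveillance mostly asks a retrospective question — how has
this child grown relative to peers — while the clinically valuable question is
prospective: given the BMI measurements collected so far, what will this
child's BMI trajectory look like, and how likely is it to cross an
overweight/obesity cutoff years from now? `gpgrowth` implements a unified
probabilistic answer: a multi-task Gaussian-process mixture in the style of
the Magma/MagmaClust family (Leroy et al., *Machine Learning* 2022, 2023)
that simultaneously

* models each child's BMI curve as a smooth function observed with noise,
* clusters children into a small number of trajectory patterns,
* and produces full predictive distributions at any age, from which
  threshold-crossing probabilities follow directly.

Two classical reference methods are included for comparison — per-child cubic
smoothing splines and the hierarchical Jenss–Bayley nonlinear mixed-effects
growth model — together with the evaluation harness (missing-data
reconstruction and prospective forecasting, scored by pooled MSE and weighted
95% credible-interval coverage) and a risk calculator for sex-specific
overweight cutoffs at a target age.

## The model

For child $i$ with latent cluster $Z_i = k$, observed BMI at ages $t_i$ is

$$ y_i = \mu_k(t_i) + f_i(t_i) + \varepsilon_i, $$

where

* $\mu_k \sim \mathrm{GP}(m_0, K_{\gamma})$ is a *mean process* shared by all
  children of cluster $k$ — the cluster's trajectory pattern;
* $f_i \sim \mathrm{GP}(0, K_{\theta})$ is the child's smooth individual
  deviation, with one kernel $\theta$ common to all children;
* $\varepsilon_i \sim N(0, \sigma^2 I)$ is i.i.d. measurement noise;
* $P(Z_i = k) = \pi_k$.

All kernels are squared-exponential, parameterized by a variance
((kg/m²)², the function's scale) and a lengthscale (years, how far
correlation reaches); both are optimized on the log scale.

### Variational EM

Exact posteriors are intractable because the mean processes and memberships
couple all children. `gpm_fit()` uses a structured variational family
$q(\mu)q(Z)$ and alternates:

* **E-μ** — each mean process gets a Gaussian hyper-posterior
  $(\hat m_k, \hat C_k)$ on the pooled grid of observed ages, in closed form:
  $\hat C_k = (C_\gamma^{-1} + \sum_i \tau_{ik} A_i^\top \Psi_i^{-1} A_i)^{-1}$,
  $\hat m_k = \hat C_k (C_\gamma^{-1} m_0 + \sum_i \tau_{ik} A_i^\top \Psi_i^{-1} y_i)$,
  with $\Psi_i = K_\theta(t_i, t_i) + \sigma^2 I$ and $A_i$ the incidence of
  child $i$'s ages in the grid.
* **E-Z** — memberships
  $\log \tau_{ik} \propto \log \pi_k + \log N(y_i; A_i \hat m_k, \Psi_i)
  - \tfrac12 \mathrm{tr}(\Psi_i^{-1} A_i \hat C_k A_i^\top)$, normalized per
  child.
* **M** — $\pi_k = \bar\tau_k$; $(\gamma, \theta, \sigma^2)$ by Nelder–Mead
  on the log scale, each update guarded so it never decreases its objective.

The evidence lower bound (ELBO) is computed once per cycle and is
non-decreasing by construction; training stops when its change falls below
`tol` (default $10^{-3}$ nats) or after `max_iter` cycles (default 100).

### Design choices that were genuinely open

* **Shared mean-process kernel.** The mean-process kernel hyper-parameters
  are shared across clusters by default (`common_mean_kernel = TRUE`), a
  sub-case the Magma/MagmaClust family itself offers. With per-cluster
  kernels, a component that captures two or three outlying children can
  inflate its own kernel variance (we observed values above 150) and survive
  as a spurious micro-cluster when the model is deliberately over-provisioned
  (large K); sharing lets the well-populated clusters set the scale and
  regularizes the rest. Per-cluster kernels remain available.
* **Shared individual kernel and noise.** One $(\theta, \sigma^2)$ serves
  all children. With at most 20 visits per child, child-specific kernels are
  weakly identified; sharing pools roughly $n \times 16$ residual degrees of
  freedom.
* **Prior mean constant at the grand mean.** A zero prior mean would drag
  extrapolations toward BMI 0; the training grand mean is the neutral
  choice.
* **Initialization.** Memberships start from seeded k-means on per-child
  features — BMI linearly interpolated at anchor ages (0.25, 0.75, 1.5, 3,
  5, 7, 10 y) — which captures both infancy peak intensity and later level.
  Plain (mean, slope) features proved too coarse: they misassign around half
  the children and the VEM can then converge to merged clusters.
* **Restarts.** Mixture ELBOs are multimodal. With `n_init > 1` the fit
  runs that many seeded restarts for `init_iter` burn-in cycles, continues
  the best `n_keep` to convergence, and returns the best final ELBO. The
  cluster-number analysis in `analysis/02_cluster_bmi_trajectories.R` uses
  `n_init = 6, init_iter = 40, n_keep = 2`.
* **Empty clusters are frozen, not deleted.** A cluster whose total
  responsibility drops below $10^{-8}$ stops updating its hyper-parameters
  and is flagged; it keeps its slot so that K never silently changes
  mid-run.
* **Ties in argmax membership** break toward the lower cluster index.

### Prediction

For a new (or partially observed) child, `predict()` recomputes each
hyper-posterior on the union of the training grid, the child's ages and the
target ages — exact, because the training contribution lives only on
training-grid coordinates, whose sufficient statistics are cached in the
model — then conditions the child-level prior
$N(\hat m_k, \hat C_k + K_\theta + \sigma^2 I)$ on the child's observations.
Membership weights come from the E-Z formula applied to the observations;
with none, the learned $\pi$ is returned, giving a population-level
prediction. Returned per-cluster laws are predictive laws of *observations*
(noise variance included on the diagonal), so interval-coverage metrics can
be read off directly. `sample_trajectories()` draws cluster indices from the
weights and multivariate-normal paths from the chosen cluster's law.

## The synthetic cohort

The real cohort the method family targets is access-restricted, so the
package generates its own study conditions (`sim_config()`,
`generate_cohort()`), emulating the structure such data exhibits:

* **5 cluster mean curves** from the family
  $f(t) = a + bt - e^{c - dt} + h\,e^{-(t - t_p)^2 / 2w^2}$ — a
  Jenss–Bayley-shaped backbone plus a Gaussian bump. Every curve has an
  infant BMI peak near 9 months (peak ages 0.68–1.1 y across the preset) and
  the curves diverge afterwards, the upper pattern reaching ≈26.5 kg/m² at
  age 10 and the lowest ≈13.6. Peak intensity varies strongly across
  clusters (bump heights 4.2 down to 0.5 kg/m²), peak timing only slightly —
  all "around 9 months". The preset was designed once, by computing the
  between-cluster Mahalanobis separation under the deviation-plus-noise
  covariance (adjacent separations 3.5–5.1, i.e. 2–5% pairwise Bayes error):
  clearly separated patterns with a realistic continuum of children in
  between.
* **Per-child deviations** from an SE kernel with variance 1 (kg/m²)² and
  lengthscale 2 y; **noise** SD 0.4 kg/m²; **schedule** of 20 visits from
  birth to 10 y, 8 of them before age 2; **20% of visits missing** at
  random; mixture weights (0.12, 0.18, 0.25, 0.25, 0.20); even sex ratio;
  default n = 300 children.
* An optional mode emits **consistent weight/height pairs** (height from a
  fixed monotone Jenss–Bayley template with small child-level random
  effects; weight back-computed so BMI = weight/(height/100)² holds exactly)
  so the Jenss–Bayley weight/height pathway is testable end-to-end.

What the generator deliberately does **not** emulate: secular trends,
sex-specific mean curves, instrument changes mid-follow-up (the length-to-
height switch at age 2), informative missingness, or heavy-tailed
measurement errors. Passing tests therefore demonstrate correct inference
under the model's own assumptions plus mild misspecification (the generating
means are parametric curves, not GP draws) — not robustness to everything
real cohorts do.

## Baselines

* **Cubic smoothing splines** (`fit_cubic_spline()`): `stats::smooth.spline`
  per child, smoothing chosen by generalized cross-validation (the exact
  smoothing policy of the comparison literature is unstated; GCV is the
  conventional default). At least 4 distinct ages are required — fewer is a
  counted runtime error in the harness. Natural-spline extrapolation beyond
  the data is linear, which is exactly why splines fail at long-horizon
  forecasting.
* **Jenss–Bayley mixed model** (`fit_jb_mixed()`):
  $y = a_i + b_i t - e^{c_i - d t}$ fitted by Lindstrom–Bates iterative
  linearization (`nlme::nlme`), random effects on $(a, b, c)$, $d$ fixed at
  the population level (weakly identified per child), general
  positive-definite random-effect covariance with a diagonal fallback.
  Weight and height are fitted separately and composed into BMI. For test
  children, empirical-Bayes parameters are computed by penalized
  Gauss–Newton under the fitted population — the correct out-of-sample
  analogue of the training-time random effects, and cheap enough to refit
  per experimental condition.

## Evaluation designs and metrics

* **Reconstruction**: per child, `round(fraction × n)` points (round half
  up) are held out uniformly at random; at least one point is always kept so
  every method receives an input. **Forecast**: history is every point
  strictly before the age threshold.
* **MSE is pooled over points** (not averaged per child first); the
  convention is stated on every report row.
* **WCIC95** re-specifies the weighted coverage metric as
  $100 \cdot \frac1n \sum_{\text{points}} \sum_k \tau_k\,
  \mathbf 1\{y \in [m_k \pm 1.96 s_k]\}$ — per-cluster central-interval
  coverage weighted by membership. Only the mixture model carries a
  calibrated predictive law, so baselines report no coverage.
* Children a method cannot handle are counted as runtime errors for that
  method, never silently dropped.

## Risk tool

`run_risk_pipeline()` evaluates, per child and history threshold (2, 4, 6,
8 y): predict at the target age (10 y), convert the mixture law into a
crossing probability — by counting among 100,000 sampled trajectories
(default) or by the closed-form mixture tail
$\sum_k \tau_k (1 - \Phi((c - m_k)/s_k))$, which also serves as the test
oracle — classify against a 5% probability cutoff (boundary counts as
positive), and score against observed status (measured BMI at the target
age, matched within ±0.25 y, against the sex-specific cutoff: 22.0 girls /
22.8 boys). Crossing is evaluated pointwise at the target age, not path-wise
over a window. Children without a measurement near the target age are
excluded and counted.

## Numerical choices

* Cholesky with escalating jitter: start at $10^{-10} \max(\mathrm{diag})$,
  escalate tenfold to $10^{-4} \max(\mathrm{diag})$, then fail loudly. SE
  kernels on near-duplicate ages are genuinely ill-conditioned (the
  infancy-dense schedule gives reciprocal condition numbers near
  $10^{-13}$).
* Hyper-parameters live on the log scale; every M-step update is rejected if
  it would worsen its own objective, which keeps the ELBO monotone even when
  Nelder–Mead misbehaves.
* Membership normalization uses the log-sum-exp construction; mixture
  weights are floored at $10^{-300}$ inside logs.

## Problem sizes used by the tests and analysis scripts

Fits in the test suite use cohorts of 100–220 children (training sets of
150–200) and the cluster-number experiment fits K = 10 to 200 children —
sizes chosen so the full suite completes on one CPU in well under half an
hour while keeping every statistical check comfortably powered. The analysis
scripts use the default 300-child cohort split 200/100. Hyper-parameter
recovery is asserted for the identifiable parameters — the individual-kernel
variance and lengthscale and the noise variance, all informed by hundreds of
children — not for the mean-process kernel, which at K clusters is informed
by only K smooth curves and is not consistently estimable from one cohort.

## Known limitations

* Cluster count must be explored by over-provisioning K and counting
  populated components; there is no automatic model-selection criterion
  beyond the ELBO.
* The mixture's predictive variance mixes within- and between-cluster
  spread: for a minority of children, early (infancy-only) histories yield
  overconfident memberships, and additional mid-childhood data can
  temporarily *widen* the predictive law before narrowing it again — visible
  in the nested-information test, which therefore asserts strict narrowing
  only for long histories and median narrowing at 6 y.
* Under the synthetic preset the high-risk trajectory pattern is already
  visible in the infant BMI peak, so risk sensitivity is high even from
  2-year histories and longer histories mainly buy specificity and PPV;
  cohorts whose patterns diverge later would instead show the
  sensitivity-grows-with-history pattern. For the same reason the mean
  absolute gap between predicted probability and observed status need not
  shrink monotonically with history length here: extra data sharpens
  probabilities toward 0 or 1, which helps most children and hurts the
  occasional misclassified one.
* Sex enters only through the overweight thresholds, not the trajectory
  model; post-pubertal ages, covariate-dependent mean processes and non-SE
  kernels are out of scope.
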