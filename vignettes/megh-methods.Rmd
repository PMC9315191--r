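---
title: "Mixed-effects general hazard models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effects general hazard models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meghaz)
```

## The model

Clustered time-to-event data — patients treated in different centres,
residents of different districts — exhibit between-cluster heterogeneity that
a fixed-effects hazard regression cannot absorb. `meghaz` models the hazard of
subject $j$ in cluster $i$ with a *general hazard* (GH) structure carrying
cluster-level random effects on both of the scales a covariate can act on:

$$
h(t_{ij} \mid x_{ij}, u_i, \tilde u_i)
 = h_0\!\left(t_{ij}\, e^{\tilde x_{ij}^\top \alpha + \tilde u_i}\right)
   e^{x_{ij}^\top \beta + u_i},
$$

where $h_0(\cdot \mid \theta)$ is a parametric baseline hazard, $x_{ij}$ are
hazard-scale covariates (coefficients $\beta$), $\tilde x_{ij}$ time-scale
covariates (coefficients $\alpha$, typically a subset of $x_{ij}$), and
$(u_i, \tilde u_i)$ are zero-mean cluster effects with distribution $G$. The
cumulative hazard is closed-form:

$$
H(t \mid x, u, \tilde u)
 = H_0\!\left(t\, e^{\tilde x^\top \alpha + \tilde u}\right)
   e^{x^\top \beta - \tilde x^\top \alpha + u - \tilde u}.
$$

Without random effects the structure reduces to the GH model, which nests
proportional hazards ($\alpha = 0$), accelerated failure time
($\alpha = \beta$) and accelerated hazards ($\beta = 0$). Two tractable mixed
subclasses are implemented, each with a single random effect per cluster:

* **MEGH-I** (`structure = "megh1"`): $\tilde u_i = 0$ — the effect acts on
  the hazard scale only; contains the mixed-effects PH model at $\alpha = 0$.
* **MEGH-II** (`structure = "megh2"`): $\tilde u_i = u_i$ — the same effect
  acts on both scales; generalises the mixed-effects AFT structure
  ($\alpha = \beta$).

The fully general version with two distinct, possibly correlated effects
requires a two-dimensional integral per cluster and is out of scope here.

## Baseline hazards

The baseline family determines the hazard shapes the model can express.
Available families (`baseline_hazard()`): Power Generalised Weibull
(increasing, decreasing, unimodal and bathtub shapes), log-logistic,
log-normal and gamma, each with closed-form or quantile-based inverse
cumulative hazard so the same object drives both likelihood and simulation.
We parameterise the PGW through scale $\eta > 0$, power $\nu > 0$ and tilt
$\delta > 0$ with $H_0(t) = [1 + (t/\eta)^\nu]^{1/\delta} - 1$; at
$\delta = 1$ this degenerates to the Weibull cumulative hazard $(t/\eta)^\nu$,
which the test-suite uses as a numerical cross-check. A standalone Weibull
baseline is refused: under it the GH time-scale and hazard-scale effects are
not separately identifiable, and the constructor says so rather than letting
a user fit an unidentifiable model.

All positive parameters are optimised on the log scale; reported standard
errors are mapped back by the delta method. Log-hazards are evaluated
directly on the log scale (never as `log(hazard)`), since time-scale linear
predictors of the order $e^{4}$ routinely push the rescaled time argument
into regions where the hazard itself underflows.

## Random-effects distributions

`re_dist()` provides three zero-mean laws with support on the real line and
finite variance (the conditions the marginal-likelihood asymptotics need):
normal, scaled Student-$t$, and two-piece normal. Choices the literature
leaves open, settled here once:

* **Student-$t$ degrees of freedom are fixed** (default 4, must exceed 2),
  not estimated, and the scale is $\sigma\sqrt{(df-2)/df}$ so that the
  variance is exactly $\sigma^2$. This keeps the variance parameter
  one-dimensional, which in turn keeps the boundary test for
  $\sigma_u^2 = 0$ in the single-variance chi-bar-square case.
* **Two-piece normal**: two-scale form with left scale $\sigma_1$, right
  scale $\sigma_2$ and mode $m$; zero mean is enforced by
  $m = -\sqrt{2/\pi}\,(\sigma_2 - \sigma_1)$. The symmetric case collapses
  exactly to the normal.

## Marginal likelihood and estimation

The cluster-conditional log-likelihood is
$\ell_i(\eta, u) = \sum_j d_{ij} \log h(t_{ij}\mid\cdot) - \sum_j
H(t_{ij}\mid\cdot)$ and the cluster marginal likelihood integrates it over
$G$. The integrand spans hundreds of log-units across clusters, so it is
scaled by its supremum $\log K_i = \max_u \ell_i(\eta, u)$: the scaled
integrand lies in $(0, 1]$ and equals 1 at the maximiser, and
$\log m_i = \log K_i + \log \int \exp\{\ell_i(\eta,u) - \log K_i\}\, dG(u)$.
The estimator is the maximiser of $\sum_i \log m_i$ (the marginal maximum
likelihood estimator).

Numerical choices that matter:

* **Inner maximiser.** For MEGH-I, $\ell_i(u) = C_i + D_i u - B_i e^u$ with
  $D_i$ the cluster's event count, so $u^*_i = \log(D_i/B_i)$ in closed form;
  a fully censored cluster has its supremum in the limit $u \to -\infty$
  (value 0) and is retained — its marginal term is still well defined. For
  MEGH-II the maximiser is found on a vectorised 25-point grid over
  $\pm\max(8\hat\sigma_u, 6)$ followed by Brent refinement of the bracketing
  cell.
* **Quadrature.** `stats::integrate` on $(-\infty, \infty)$, with the
  integration variable centred at the integrand mode and scaled by
  $1/\sqrt{1/\mathrm{Var}(G) + \max(\text{curvature of } \ell_i, 0)}$. The
  centring is moved from the conditional maximiser to the mode of
  $\ell_i(u) + \log g(u)$ whenever the former sits deep in the tails of $G$
  — this is what keeps the $\sigma_u \to 0$ limit (which must reproduce the
  fixed-effects likelihood) numerically exact instead of underflowing. A
  finite-interval retry and an explicit $-\infty$ report (with a warning)
  back the adaptive rule up.
* **MEGH-II kernel.** Evaluating $\ell_i(u)$ under MEGH-II re-evaluates the
  baseline at rescaled times for every quadrature node; this hot loop is
  implemented in C++ (the only compiled code in the package). The test-suite
  pins the kernel against the plain-R conditional log-likelihood to
  $10^{-10}$.
* **Outer optimiser.** `nlminb` on the unconstrained scale (relative
  tolerance $10^{-8}$), with two default starts: the fixed-effects GH
  estimates plus $\sigma_u = 0.2$, and a null start (zero coefficients,
  data-driven baseline, $\sigma_u = 0.5$). When `nlminb` reports false
  convergence on a flat surface a Nelder–Mead polish decides whether the
  point is a genuine optimum. Standard errors come from the inverse
  numerical Hessian of the negative log marginal likelihood; a singular
  Hessian yields `NA` standard errors with a warning, not an error.
* **Ties** in event times need no handling: the likelihood is fully
  parametric.

## Diagnosing the random effects

**Gradient function.** For an assumed $G$, the directional derivative of the
marginal log-likelihood towards an alternative law $W$ is non-positive for
every $W$ exactly when
$\Delta(G, u) = \tfrac1r \sum_i \exp\{\ell_i(\hat\eta, u)\}/m_i(\hat\eta)
\le 1$ for all $u$, so plotting $\Delta$ against $u$ screens the
distributional assumption without ever specifying $W$. Since the derivative
of the marginal log-likelihood at $G$ towards $G$ itself is zero, the
integral identity $\int \Delta(G,u)\, dG(u) = 1$ holds; the implementation
evaluates it by quadrature on every curve as a self-check (tolerance
$10^{-3}$), and treats the pointwise statement "$\Delta = 1$ on the support"
as the plotting heuristic it is — the derivation pins down the integral, not
the pointwise value. Confidence bands (`gradient_bands()`) use a
cluster-level nonparametric bootstrap — resample clusters with replacement,
refit, recompute $\Delta$ — because resampling whole clusters is the
resampling scheme that respects within-cluster dependence under censoring;
a no-refit variant (`refit = FALSE`) is offered where the refitting cost is
not warranted. The default 95% bands include the point estimate among the
resampled curves.

**Boundary test.** Excluding the random effect means testing
$H_0: \sigma_u^2 = 0$, a parameter on the boundary of its space, so the
likelihood ratio statistic is not asymptotically $\chi^2_1$. For the
implemented one-effect structures the null distribution is the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; for two separate variances it would be
$\tfrac14\chi^2_0 + \tfrac12\chi^2_1 + \tfrac14\chi^2_2$, and
`mixture_pvalue()` implements both (the two-variance case as pure
distributional arithmetic, since fitting two correlated effects is out of
scope). The observed statistic is clipped at zero — optimisers legitimately
return tiny negative differences for nested fits — and $p = 1$ at zero.

## The simulator

`simulate_dataset()` inverts the closed-form cumulative hazard: with
$E \sim \mathrm{Exp}(1)$,

$$
T = H_0^{-1}\!\left(E\, e^{-(x^\top\beta - \tilde x^\top\alpha + u - \tilde u)}\right)
    e^{-(\tilde x^\top\alpha + \tilde u)},
$$

so $H(T \mid x, u, \tilde u) = E$ holds to machine precision record by
record — the test-suite asserts this identity and the unit-exponentiality of
$H(T)$ by Kolmogorov–Smirnov.

The default design *is* the reference study condition set: 24 clusters,
$n = 1043$ split as evenly as possible (eleven clusters of 44, thirteen of
43), PGW truth $\theta = (0.20, 1.50, 3.00)$, $\alpha = 0.96$ on age,
$\beta = (1.00, 0.08, 0.22, 0.10)$ on age, sex, wbc and tpi, normal random
effects with $\sigma_u = 1$ (0.5 is the other scale of interest), and a 25%
censoring target. Two pieces the reference analyses leave unspecified are
fixed here once:

* **Covariate generator**: age, wbc, tpi $\sim N(0,1)$ and sex
  $\sim \mathrm{Bernoulli}(1/2)$, independent — the standardised-covariate
  analogue of a leukaemia-registry covariate set. Absolute AIC levels depend
  on this choice, so the replication harness checks AIC *orderings* between
  structures, never printed AIC values.
* **Censoring**: independent exponential, with the rate calibrated by
  root-finding on a $10^5$-draw pilot so the expected censored proportion
  hits the target. The per-dataset proportion still varies by a few
  percentage points because 24 cluster effects shift the time scale
  cluster-wide; the calibration target is the expectation across replicates.

What passing the simulation-based tests does *not* show: the generator draws
independent, homogeneous covariates and administrative-free exponential
censoring, so agreement under it says nothing about covariate-dependent
censoring, informative cluster sizes, or the heavier-tailed covariate
distributions of real registries.

## Replication harness and problem sizes

`run_study()` simulates replicates, fits any subset of
{MEGH-I, MEGH-II, GH}, and accumulates per-parameter bias, average AIC and
the rejection rate of the boundary test. The packaged checks run 20
replicates of the full-size design (the reference analyses use 250): with 20
replicates the power of the boundary test under $\sigma_u = 1$ and the AIC
and bias orderings between correct, misspecified and no-random-effect fits
are already stable, while each replicate costs one GH, one MEGH-I and one
MEGH-II fit. The type-I-error check of the boundary test uses 200 smaller
replicates (24 clusters of 6, log-logistic baseline) and a three-standard-
error binomial band around the nominal 0.05.

## Limitations

* Only one random effect per cluster (shared or hazard-scale-only); the
  two-effect MEGH with correlated $(u, \tilde u)$, multilevel clustering,
  left/interval censoring and time-varying covariates are not implemented.
* Baselines are parametric; no spline/semiparametric option.
* The gradient-function diagnostic is evaluated at the plug-in estimates
  $\hat\eta$; its bands reflect resampling uncertainty, not a formal test.
* AIC values across packages are comparable only up to the usual constants;
  within-package comparisons are what `model_selection_report()` ranks.
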