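---
title: "Methods: coupled growth mapping and multilayer epistatic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled growth mapping and multilayer epistatic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crinet)
```

crinet maps the pleiotropic genetic control of two coupled growth traits —
stem height and stem diameter in a full-sib tree population — and
reconstructs directional epistatic networks from genome-wide marker effect
curves. This vignette documents the models, the estimation choices, and the
limits of what the bundled simulations demonstrate.

## The coupled regulatory interaction (CRI) growth system

Growth of the two traits is modelled by a Lotka–Volterra-type system,

$$
\frac{dH}{dt} = \alpha_H\Big(1 - \frac{H}{K_H}\Big)H
  + \alpha_H\,\beta_{H\leftarrow D}\,H D, \qquad
\frac{dD}{dt} = \alpha_D\Big(1 - \frac{D}{K_D}\Big)D
  + \alpha_D\,\beta_{D\leftarrow H}\,D H,
$$

which splits each trait's rate of change into a self-regulated logistic part
(rate $\alpha$, asymptote $K$) and an interactive part driven by the
co-existing trait. The signs of the coupling coefficients classify the
interaction strategy: both (numerically) zero is *neutral*, at least one
positive and none negative is *cooperative*, any negative is *antagonistic*
(`classify_strategy()`, with a $10^{-8}$ absolute zero tolerance because
exact zeros never arise in floating-point estimates).

The system has no closed form, so all mean curves come from classic
fixed-step fourth-order Runge–Kutta (`integrate_cri()`). The default
internal step is 0.01 year; inside the likelihood scans we use 0.05 year,
where the RK4 solution error (order $h^4$) is below $10^{-6}$ of the trait
scale and far below phenotypic noise. `decompose_growth()` evaluates the two
derivative components along the *coupled* trajectory; the "independent
growth" curve of a genotype is the running integral of the self-regulated
component along that trajectory, not a re-solved uncoupled logistic (the
uncoupled alternative can be obtained by integrating with the couplings
zeroed; we prefer the along-trajectory component because it sums exactly
with the interactive component to the observed growth rate).

`fit_cri()` estimates the six parameters by least squares on the RK4
solution with Nelder–Mead restarts from a perturbed method-of-moments grid
(asymptote $\approx 1.05\times$ the observed maximum, rate from the early
log-slope, couplings seeded at $0$ and $\pm$ small values). The initial
state is fixed at the first observation so the model keeps six free
parameters per genotype. Coupled-ODE least squares is multimodal; ten
restarts have been sufficient in all bundled tests. Classical single-trait
fits (Gompertz, Korf, Richards, logistic; `fit_classical()`) are provided
for accuracy/complexity comparison; the Richards curve uses the
four-parameter form $y = a(1 - b e^{-ct})^{1/(1-m)}$.

## The mapping likelihood

Phenotypes are bivariate longitudinal vectors of length $2T$ (height at all
times, then diameter). Residuals follow a bivariate first-order structured
antedependence process, SAD(1): each trait's residual is $\phi$ times its
previous value plus an innovation with trait-specific scale $\nu$ and
contemporaneous cross-correlation $\rho$. The implied covariance has a
closed form (`sad1_covariance()`), is guaranteed positive definite for
$|\rho|<1$, and captures the variance growth over a growth period with five
parameters.

The null model fits one CRI parameter set $\Theta$ and one SAD(1) set
$\psi$ to all individuals by profile alternation: Nelder–Mead over
$\Theta$ (log scale for rates and asymptotes) with $\psi$ fixed, then
Nelder–Mead over $\psi$ with residuals fixed, three rounds by default. The
alternative model at a marker gives each genotype class its own
$\Theta_j$ while sharing the null $\hat\psi$ (a config flag re-estimates
$\psi$ per marker). Because genotypes are observed, the per-class
likelihood factorises and each class is fitted independently — an exact
reformulation, not an approximation. The scan statistic is
$\mathrm{LRT} = 2(\ell_1 - \ell_0)$, referred to $\chi^2$ with $6(J-1)$
degrees of freedom (testcross markers have $J=2$ classes segregating 1:1,
intercross markers $J=3$ at 1:2:1); a genotype-permutation null of the
genome-wide maximum LRT is available by config since the chi-square
reference is an approximation. Significance is declared at the
Bonferroni-corrected genome-wide level (default $\alpha=0.05$) and BH-FDR
is always reported. Significant markers get two nested sub-tests:
equality of the independent-growth parameters across classes
($4(J-1)$ df) and equality of the coupling coefficients ($2(J-1)$ df),
each against the unconstrained per-genotype fit (re-polished first so the
nesting inequality holds numerically).

Per-marker genetic effect curves are weighted standard deviations of the
class mean trajectories,
$g(t) = \sqrt{\sum_j w_j(\mu_j(t)-\bar\mu(t))^2}$, with observed class
frequencies by default (Mendelian expectations by flag), plus
independent-effect variants computed from the cumulative independent growth
components and a dynamic genetic correlation across classes.

## Functional clustering into modules

Genome-wide effect curves are clustered with an $L$-component Gaussian
mixture (`em_fit()`): component means are Legendre orthogonal polynomial
(LOP) expansions of order 4 per trait (14 annual time points support order
6 comfortably; 4 is the default to keep $2(r+1)=10$ mean parameters per
module), and a single shared SAD(1) covariance describes within-module
dispersion. The EM update is exact for the weights (posterior column means)
and the mean coefficients (generalized least squares against the weighted
mean curve); the covariance parameters are updated by a short Nelder–Mead
ascent started at the current value, so the observed-data log-likelihood is
monotone — the suite fails if it ever decreases by more than $10^{-8}$.
Initialization is seeded k-means on the stacked curves with restarts;
modules that lose essentially all weight ($\omega_l < 1/(10p)$) are
re-seeded from the worst-fit curve so the requested $L$ is honoured during
model selection. The number of modules is chosen by BIC (AIC by option)
over a grid, with the penalty $\log(p)$ on the
$(L-1) + 2(r+1)L + 5$ free parameters. Hard assignments are MAP with ties
to the lowest index. `subcluster()` recurses on a module's members,
producing the nested module → submodule → marker naming scheme
(`SM<i>/M<l>`).

## Network reconstruction

Each network layer treats node effect curves (module means, submodule
means, or single-marker curves) as the state variables of an ODE system:
node $l$'s rate of change is an independent term plus one dependent term
per regulator. Curves are smoothed by least-squares LOP fits
(`smooth_and_interpolate()`, default order 7 for network work) and
interpolated on a 100-point dense grid, which also handles layers with more
nodes than time points.

Two estimation choices depart from the most obvious formulation, and both
were forced by identifiability:

* **Dependent terms are linear in the regulator's curve**
  ($G_{l\leftarrow l'}(t) = \theta_{l\leftarrow l'}\, g_{l'}(t)$), the same
  form in which the CRI system couples its two traits. Fully flexible
  polynomial dependent terms — in time or in the regulator's state — are
  exactly or nearly collinear with the independent term (any smooth
  function of time is a function of a monotone state), which makes the
  independent/dependent split arbitrary. With linear coupling the
  least-squares split is unique whenever a regulator's curve carries shape
  beyond the independent trend.
* **Regulator selection is a noise-calibrated test at the observed
  resolution.** A dense interpolated grid pseudo-replicates the $T$
  observations, so cross-validating a penalty on it overselects badly.
  Instead, the smoothed derivative is regressed at the observed time points
  on candidate curves alongside an unpenalized low-order time trend
  (Legendre order 3) that absorbs the node's own baseline dynamics. Because
  the derivative estimate is a known linear functional of the data, its
  noise covariance is available in closed form
  ($\sigma^2 D (B'B)^{-1} D'$, with $\sigma^2$ estimated from the
  smoothing residual), and each candidate's fit gain has an exact z-score
  under the no-edge null. Forward selection admits candidates with
  $z \ge 4$ (ranked by fit gain), a backward pass removes any that fall
  below the threshold given the others, and the in-degree is capped
  (default 8). Large candidate sets are screened to the top marginal
  scores first; LASSO-path selection with cross-validated or BIC-chosen
  penalty remains available as `selector = "cv"` / `"bic"`.

The independent component is defined as the smoothed derivative minus the
fitted dependent terms, so the decomposition conserves the derivative
exactly at every grid point, and the node curve is reconstructed by RK4
over the decomposed derivative from its first value. An edge $l'\to l$
carries weight equal to the time-averaged absolute dependent derivative and
the sign of its time average (activation/inhibition). Out/in-degree tables
and per-node deconstruction reports (net, independent, and per-regulator
dependent effect curves) support the module-, submodule- and marker-level
analyses; `variant = "independent"` builds the same networks from
independent-effect curves, re-running selection by default (a flag reuses
the overall support).

## The simulator and what it does (not) show

`simulate_genotypes()` draws unlinked testcross (1:1) and intercross
(1:2:1) markers; `simulate_phenotypes()` gives every individual the RK4
mean curve of its causal-marker genotype class plus SAD(1) noise. The
causal classes shift both asymptotes by $\pm 10\%$ by default; heritability
is imposed by rescaling the innovation scales so that the genetic variance
fraction, averaged over time points and traits, equals the target — the
achieved value is within $\pm 0.01$ at $n = 10^4$ in the test suite.
Baseline parameters ($\alpha_H=0.55$, $K_H=25$ m,
$\beta_{H\leftarrow D}=-0.010$, $\alpha_D=0.40$, $K_D=30$ cm,
$\beta_{D\leftarrow H}=0.006$; $\phi=0.9$, $\rho=0.5$) give sigmoid
trajectories reaching ~19 m and ~28 cm at year 14 with the antagonistic
strategy (diameter inhibits height growth, height promotes diameter
growth) — a realistic hybrid-poplar-like regime.

`run_power_study()` wraps simulate → scan over a grid of $(n, H^2)$:
power is the fraction of replicates whose causal marker clears the
genome-wide threshold, the FPR pools null-marker rejections, and ROC/AUC
sweeps the LRT threshold over its observed range with trapezoid
integration. The desk-scale defaults are 100 markers and 50 replicates per
condition (20 under the null), sized so the full study runs in minutes on
one core; the marker count and replicates scale up by config.

What passing these simulations does **not** show: the generator draws
unlinked markers (no linkage disequilibrium, so no inflation from correlated
tests), a single causal locus, balanced designs with no missing phenotypes,
and Gaussian SAD(1) residuals. Real mapping populations violate all four;
the chi-square reference and the Bonferroni threshold should be checked
against the permutation option before trusting borderline hits. Likewise,
`simulate_planted_network()` produces systems inside the fitted model class
with identifiable regulator shapes; on real effect curves the
independent/dependent attribution is a modelling convention, and edges
should be read as directed associations between effect trajectories, not as
validated causal links.

## Numerical choices, degenerate inputs, limitations

* RK4 steps land exactly on requested times (the last sub-step of each
  interval is shortened); non-finite states raise an integration error
  naming the time.
* All likelihood code goes through one Cholesky factorization per
  covariance; a non-positive-definite SAD(1) matrix names the offending
  parameters.
* Genotype classes with fewer than 2 individuals are dropped with a
  warning; monomorphic markers raise a degenerate-marker error; failed
  markers are flagged in the scan, never fatal.
* Constant trajectories make classical fits return a degenerate flag
  (asymptote = the constant, rate 0).
* LRT values are clamped at 0 (the alternative nests the null; tiny
  negatives are optimizer noise).
* Balanced time grids are required; unbalanced designs are rejected at
  read time rather than imputed.
* Only two traits are supported, and network topology is static over time.
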