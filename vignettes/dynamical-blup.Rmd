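---
title: "Dynamical BLUP for reaction-norm evolution: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical BLUP for reaction-norm evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynblup)
```

## The problem

A linear reaction norm maps an environmental cue to the phenotype a
genotype expresses: for trait $j$ of individual $i$ at generation $t$,

$$y_{j,i,t} = \bar a_{j,t} + a'_{j,i,t} + v_{j,i,t}
  + \sum_{k=1}^{q} \left(\bar b_{jk,t} + b'_{jk,i,t} + \eta_{jk,i,t}\right) u_{k,t},$$

where $\bar a$, $\bar b$ are the population mean intercepts and plasticity
slopes, $a'$, $b'$ are individual *additive-genetic* deviations with joint
covariance $G$, and $v$, $\eta$ are iid nonadditive deviations with
variances $\sigma^2_{\upsilon j}$, $\sigma^2_{\eta jk}$. Cues are measured
as deviations from a reference environment, so the reference is zero. As
the environment changes — here, noisy ramps in the cues with
correspondingly moving fitness peaks $\theta_t$ — the population evolves:
the means $\bar a_{j,t}$, $\bar b_{jk,t}$ shift under selection, and the
interesting scientific question is how to estimate and predict that shift
when only phenotypes, fitness, environments, and relatedness are
observable (as in field data), rather than the individual reaction-norm
parameters themselves (which only a simulator knows).

`dynblup` implements both sides of that question:

* a **population simulator** (the `make_cohort()` / `run_generation_loop()`
  family) that draws cohorts from known $G$, $P$ and assigns integer
  fitness under Gaussian stabilising selection; and
* a **dynamical BLUP estimator** (`blup_fit()` / `blup_solve()`): a linear
  mixed model whose incidence matrix $Z_t = [\,I_p \mid U_t'\,]$ and
  residual covariance $R_t$ are functions of the current cues — hence
  *dynamical* — solved by Henderson's mixed-model equations, with the mean
  traits as fixed effects and the per-individual additive deviations as
  random effects.

Between generations the means are updated by Robertson's secondary theorem
of natural selection applied to the estimated random effects:

$$\Delta \bar z_t = \mathrm{cov}(w_{i,t},\, \hat z'_{i,t}),$$

with $w$ the relative fitness. Two comparator rules are provided: the
selection-gradient form (GRAD), $\Delta = G Z_t' P_{yy,t}^{-1}
\mathrm{cov}(w, y)$, and the multivariate breeder's equation applied to
the *true* individual parameters (simulation-only, since those are not
identifiable from data). For an unrelated population ($A = I$) the
Robertson/BLUP update, its closed form
$G (Z_t'R_t^{-1}Z_t G + I)^{-1} Z_t'R_t^{-1}\mathrm{cov}(w,y)$, and GRAD
are algebraically identical for every $n \ge 2$; the package's property
tests verify this to $10^{-8}$. With genetic relatedness ($A \ne I$,
entering through $\tilde G_t = G \otimes A_t$) BLUP and GRAD genuinely
differ, which is the practical argument for the BLUP route.

## Why BLUP shrinkage is a feature

BLUP systematically underestimates the variance of the random effects: in
the diagonal, no-plasticity case
$\mathrm{var}(\hat a'_{j}) = G_{jj}^2 / (G_{jj} + \sigma^2_{\upsilon j})
< G_{jj}$ (`shrinkage_variance()`). Substituted into the Robertson
covariance this shrinkage is exactly the factor that converts the
phenotypic selection differential into the additive-genetic response — in
the univariate case $\hat a'_i = h^2 (y_i - \bar y)$ and
$\mathrm{cov}(w, \hat a') = h^2 S$, the classic breeder's equation. The
package tests this both algebraically (all update rules coincide when
$q = 0$, $A = I$) and empirically (the realised variance of $\hat a'$ at
$n = 10^5$ matches the shrinkage formula within Monte-Carlo error).

## Tunable parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `Gaa`, `Gab`, `Gbb` | additive covariance blocks of intercepts/slopes | see below | trait², trait·slope, slope² |
| `sigma_v2`, `sigma_eta2` | nonadditive variances | 0.2 / 0.05 per active slope | trait², slope² |
| `omega2` | width of the Gaussian fitness function | 10 | trait² |
| `W_max` | fitness at the optimum | 4 | descendants |
| `n` | population size (constant) | 100 | individuals |
| `ft` | fraction of new offspring per generation | 1 | — |
| `ramp_start` | generation the environmental ramps begin | 10 | generations |
| `cue_ramp_slopes` | drift of the mean cues after the ramp start | 0.05, 0.015 | cue units/generation |
| `noise_cov` | white-noise covariance of `(u, theta)` | see `default_noise_cov()` | mixed |

The built-in example is a two-trait, two-cue system in which each trait
responds to its own cue:
$G_{aa} = \begin{pmatrix}0.2 & 0.1\\0.1 & 0.2\end{pmatrix}$, $G_{ab} = 0$,
slope variances 0.05 with cross-trait slope covariance 0.025,
$P_{aa} = G_{aa} + 0.2 I$, and slope nonadditive variances 0.05, so the
residual variance for trait 1 is $r_{1,t} = 0.2 + 0.05\,u_{1,t}^2$. The
stationary noise covariance couples each cue to its trait's fitness peak
with $\mathrm{cov}(u_k, \theta_j)/\mathrm{var}(u_k) = -0.5$, which is also
the stationary-optimal mean slope (`optimal_slope()`), used as the initial
condition so the population starts fully adapted. The ramp slopes are not
uniquely pinned down by theory; the defaults were chosen once so the first
cue's mean rises by about 2.5 units (and the second's by about 0.75) over
the 50 post-onset generations, a plausibly strong multi-decadal climate
trend on these scales, and are ordinary configuration parameters.

## What the generator emulates — and what it does not

Each generation is drawn fresh: additive deviations from $N(0, G)$
(transformed by $A_M$, the symmetric matrix square root of $A$, when the
population is related, and then mean-centred), nonadditive deviations iid
(never centred, never relatedness-transformed). Inheritance is carried
*only* by the mean parameters; there is no individual-level pedigree
transmission, no mutation, no linkage, and the mid-parent abstraction
stands in for sexual reproduction. Population size is constant by
construction — fitness affects only the selection covariances, meaning not
all descendants survive to reproduce. Consequently, passing tests show
that the estimator and update rules behave correctly *under the model's
own assumptions* (multivariate normal effects, known constant $G$ and $P$,
correct reference environment); they do not show robustness to non-normal
data, unknown variance components, or pedigree dynamics in real
populations. Parameter identification from data (e.g. by a prediction
error method) and REML — which is indeterminate here because each residual
variance confounds several nonadditive components — are out of scope.

## Numerical choices

* **Effect ordering** is trait-major everywhere:
  $(a'_1 \ldots a'_p, b'_{11} \ldots b'_{1q}, \ldots, b'_{pq})$;
  observations stack trait-major to match
  $X = \mathrm{blockdiag}(\mathbf 1_n, \ldots)$. Other orderings would
  require permuting $G$, $U_t$, $Z_t$ consistently; the package fixes this
  one.
* **Singular $G$.** In the built-in example the cross slopes $b'_{12}$,
  $b'_{21}$ have zero variance, so $G$ is singular in the full ordering.
  The Henderson solver needs $\tilde G^{-1}$ and therefore excludes
  zero-variance effects from the system, reporting exact zeros for them —
  the zero-variance limit of the equations. The closed-form update rules
  need no $G$ inverse and work on the full ordering.
* **Two solver paths.** For $A = I$ the mixed model factorises across
  individuals: the GLS fixed effects are the per-trait sample means and
  $\hat x_i = G Z_t' V_1^{-1} (y_i - \hat{\bar y})$ with
  $V_1 = Z_t G Z_t' + R_t$ only $p \times p$. This is an exact algebraic
  identity, not an approximation; it is what makes $10^5$-individual
  checks and the 100-replicate drift experiment fast. The dense Henderson
  system (with $(G \otimes A)^{-1} = G^{-1} \otimes A^{-1}$, falling back
  to a pseudo-inverse with a warning if $A$ is singular) is the primary
  path whenever $A \ne I$, and both paths are verified against an
  independent GLS/conditional-expectation oracle on small instances.
* **Covariance convention.** All selection covariances use the population
  ($1/n$) normalisation of the Price equation, through the single
  implementation `selection_cov()`; the inter-rule identities hold under
  any consistent convention.
* **$P_{yy,t}$ cross term.** For $p, q \ge 2$ with $G_{ab} \ne 0$ the
  GRAD phenotypic covariance is assembled symmetrically as
  $P_{aa} + G_{ab}U_t + (G_{ab}U_t)' + U_t' P_{bb} U_t$; the numerical
  identity with the closed-form BLUP update over random instances with
  dense $G_{ab}$ is the test that this assembly is right (the built-in
  example has $G_{ab} = 0$ and is insensitive to it).
* **Rounding.** Fitness uses round-half-away-from-zero, the convention of
  the numerical environments these models are usually prototyped in; base
  R's banker's rounding would differ on exact halves.
* **$A_M$** is the symmetric PSD square root by eigendecomposition with
  negative eigenvalues clipped at zero (a Cholesky factor would not
  satisfy $A_M A_M = A$ symmetrically).
* **Degenerate inputs.** Residual variances $r_{j,t} \le 0$ are an error
  (the model is unidentifiable); a cohort whose every member draws zero
  descendants is extinct and aborts the run — `drift_experiment()`
  excludes such replicates (possible only at very small $n$) and reports
  their count. Symmetry/PSD checks use a relative tolerance of $10^{-8}$.

## The experiments

`run_generation_loop()` runs all requested update rules on *shared* cohort
draws each generation, so method differences are due to the rules alone
(`method_gap()` quantifies them). `overlap_experiment()` compares
offspring fractions $f_t$ under a shared seed: scaling each increment by
$f_t$ slows the tracking of the moving peak and lowers the time-averaged
mean fitness over the ramp. `drift_experiment()` measures the spread of
the total change in $\bar a_1$ over 60 stationary generations across 100
replicates, re-randomising cue and peak noise jointly in each replicate;
the companion `env_drift_diagnostic()` shows that most of that drift is
inherited from the stochastic environment itself, via the endpoint change
of a least-squares line through the cue series, whose analytic spread is
$(T-1)\sqrt{\sigma^2_U / \sum_t (t - \bar t)^2} \approx 0.31$ at $T = 60$,
$\sigma^2_U = 0.5$. "Spread" is the SD across replicates, not the standard
error of the mean — that is the reading under which the analytic value
above matches the diagnostic.

Problem sizes used throughout the test suite and the reproduction script —
$n = 100$ for 60 generations, 100 replicates for the drift statistics, 200
replicate draws for the relatedness variance ratio, $n = 10^5$ single
draws for distributional checks — are the study conditions of the built-in
example itself.

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
traj <- run_generation_loop(cfg)
autoplot(traj)                    # mean parameters per update rule
method_gap(traj, "robertson", "grad")   # ~1e-16 with A = I
```

## Known limitations

$G$, $P$ and the reference environment are assumed known and constant;
there is no REML or prediction-error identification, no nonlinear
(power-series) reaction norms, no autocorrelated environmental noise, no
pedigree-built $A$ from parent-offspring records, and no demographic
feedback (population size is fixed, so extinction can only occur through
the all-zero-fitness edge case at very small $n$). The banded relatedness
structure is deliberately stylised — useful for demonstrating that BLUP
and GRAD separate under relatedness, not a model of any real pedigree.
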