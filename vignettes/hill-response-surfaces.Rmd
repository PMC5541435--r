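---
title: "Hill response surfaces as null-interaction references for mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hill response surfaces as null-interaction references for mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillsurf)
```

## The problem

Whether a drug or pesticide combination is synergistic, antagonistic or
merely additive depends entirely on the reference — the effect the mixture
*should* produce if its components do not interact. Two classical
references dominate practice and disagree with each other: Loewe
concentration addition (CA), built on the idea that isoeffective doses
substitute for one another, and Bliss independence (Colby's formula in
agrochemistry), built on probabilistic independence of the single-agent
effects. `hillsurf` implements a third construction that takes the
*functional form* of the single-agent curves as its starting point: if each
agent follows a Hill (four-parameter logistic) dose–response curve, the
mixture is required to follow an n-dimensional logistic surface.

## The model

Each agent is a Hill curve on the linear dose scale,

$$ a_i(d) = e_{0,i} + e_{\max,i}\,\frac{m_i^{\gamma_i}}{1 + m_i^{\gamma_i}},
   \qquad m_i = d_i / d_{50,i}, $$

with maximum effect $e_{\max,i}$, median-effect dose $d_{50,i}$ and Hill
slope $\gamma_i$. In log-dose coordinates $x_i = \ln d_i$ the single-agent
curve solves the logistic ODE; for a mixture the package's central object
is the solution of the corresponding semilinear logistic PDE

$$ \sum_i \frac{\partial u}{\partial x_i}
   = \gamma(\vec m)\, u \left(1 - \frac{u}{u_{\max}(\vec m)}\right), $$

subject to two structural requirements:

* **Boundary conditions** — when all doses but one vanish, the surface must
  reduce to that agent's own Hill curve.
* **Sham compliance** — splitting one agent's dose across artificial copies
  of itself ($\sum_i w_i = 1$) must not change the prediction.

Both are satisfied by the closed form implemented in
`hill_surface_effect()`:

$$ u(\vec m) = u_{\max}(\vec m)\,
   \frac{S^{\gamma(\vec m)}}{1 + S^{\gamma(\vec m)}},
   \qquad S = \sum_i m_i, $$

with the dose-weighted mixing functions

$$ \gamma(\vec m) = \frac{\sum_i \gamma_i m_i}{S}, \qquad
   u_{\max}(\vec m) = \frac{\sum_i e_{\max,i} m_i}{S}. $$

No restriction on the components' maxima or slopes is needed — this is the
practical advantage over the classical references, which require equal
slopes (Loewe closed forms), unit slopes (GCA) or shared maxima
(Chou, Greco).

The package does not take the closed form on faith: `pde_residual()`
substitutes any implemented surface into the PDE with a second-order
central-difference stencil, `sham_deviation()` and `boundary_deviation()`
check the two structural requirements on arbitrary parameter draws, and
`pde_convergence_order()` verifies that the residual of the Hill surface
shrinks at the stencil's order ($\approx h^2$) while a non-solution such as
Bliss plateaus at a finite residual.

## Reference models and their relations

| method      | definition | relation to the Hill surface |
|-------------|------------|------------------------------|
| `hill`      | closed form above | — |
| `bliss`     | $1 - \prod_i (1 - a_i(d_i))$ | incompatible: not sham-compliant |
| `loewe`     | implicit CA equation, root-found | equal maxima + equal slopes case |
| `gca`       | $\frac{\sum e_{\max,i} m_i}{1+\sum e_{\max,i} m_i}$ | slope-1 case when all $e_{\max,i}=1$ |
| `chou_ex`   | $u_{\max}\frac{S^\gamma}{1+S^\gamma}$ | shared $(e_{\max},\gamma)$ case |
| `chou_nex`  | $S \to m_a+m_b+m_am_b$ | $\gamma=1,u_{\max}=1$: equals Bliss |
| `greco`     | $S \to m_a+m_b+\alpha\,m_am_b$ | $\alpha=0$: `chou_ex`; $\alpha=1$: `chou_nex` |

Two printed-formula caveats are worth knowing and are asserted in the test
suite rather than papered over:

* **GCA as printed** carries the maxima inside the denominator sum. For
  partial agonists ($e_{\max}<1$) its pure-agent limit is
  $e_{\max}m/(1+e_{\max}m)$, *not* the agent's own Hill curve
  $e_{\max}m/(1+m)$, and it is not the slope-1 Hill surface. The formula is
  implemented verbatim; its equivalences are exact only for full agonists,
  and the tests check exactly that.
* **Bliss vs Hill at slope 1**: for two identical full agonists with
  $\gamma = 1$ the difference has the closed form
  $u_{Hill}-u_{Bliss} = -\,m_am_b/\big((1+m_a)(1+m_b)(1+S)\big) \le 0$
  everywhere. The often-quoted sign structure — Hill above Bliss below the
  median-effect doses, below it above them — emerges for steeper curves
  ($\gamma \gtrsim 2$) and grows with the slope; $\gamma = 1$ is the
  boundary case where the "positive below $d_{50}$" region degenerates.

## Numerical choices

* **Log-space logistic.** $S^\gamma/(1+S^\gamma)$ is always evaluated as
  `plogis(gamma * log(S))`. Printed slopes reach 106 (cypermethrin), where
  the naive power overflows. Slopes are validated into $(0, 200]$.
* **All-zero doses.** $\gamma(\vec m)$ and $u_{\max}(\vec m)$ are $0/0$ at
  the origin; the surface value is defined as 0 by continuity
  ($S \to 0$ forces the logistic factor to 0).
* **Baselines.** The mixture formulas carry no baseline term, so surfaces
  are defined for $e_0 = 0$. Curves with $e_0 > 0$ are rebased by
  subtracting $e_0$ (maxima unchanged — no rescaling by $1-e_0$), with a
  warning.
* **Implicit models.** The CA and Greco equations have left sides strictly
  decreasing in $u$, so Brent root finding on
  $(\varepsilon,\ \min_i e_{\max,i} - \varepsilon)$ with
  $\varepsilon = 10^{-14}\min_i e_{\max,i}$, relative tolerance $10^{-10}$
  and 200 iterations is guaranteed to bracket a root *where one exists*.
  For unequal maxima and doses dominated by the stronger partner the
  classical CA equation has no solution below the weakest maximum (and is
  undefined above it: a fractional power of a negative base). Such
  combinations are reported as the CA cap $\min_i e_{\max,i}$ with a
  warning rather than silently clamped — the cap is the CA asymptote, but
  claiming the equation was *solved* there would be false.
* **Iso-geometry.** Isoboles and ternary iso-surfaces are extracted by a
  log-spaced scan (default $10^{-9}..10^{9}$ in scaled dose, 121 probes)
  for a sign change, refined by Brent. Grid points where the level is
  unattainable are omitted (isoboles) or kept as `NA` (iso-surfaces) and
  counted — honest domains matter for synergy plots. Planarity of ternary
  iso-surfaces in scaled-dose space holds exactly when all slopes are equal
  *and* either all maxima are equal (then $S$ is constant on the surface)
  or the common slope is 1 (then $\sum_i (e_{\max,i}-E)\,m_i = E$ is
  affine). Note the degenerate level $E = u_{\max}/2$: there $S^\gamma = 1$
  forces $S = 1$ for *any* slopes, so planarity tests must use other
  levels; the bundled tests use 0.25 and 0.75.
* **Fitting.** `fit_hill()` minimises unweighted squared error on the
  effect fraction over $(e_{\max}, \ln d_{50}, \ln \gamma)$ —
  positivity without constraints — with fixed multi-starts
  $\gamma_0 \in \{0.5, 1, 2, 8\}$ and $d_{50,0}$ at the dose nearest the
  observed half-maximum, then a Gauss–Newton polish (L-BFGS-B alone stalls
  around $10^{-8}$ RMSE on noiseless data; the polish reaches machine
  precision). Standard errors are Gauss–Newton linearisations; they are
  honest for interior truths but cannot describe the truncation when the
  true $e_{\max}$ sits on the bound 1. The fit is deterministic; the `seed`
  argument exists only for interface symmetry.
* **Default grids.** Surface and difference grids default to 61 log-spaced
  doses spanning $d_{50}\cdot 10^{\pm 3}$ per axis; the printed figures do
  not state their ranges, so these are package choices, exposed as
  arguments everywhere.

## What the synthetic generator does and does not emulate

`simulate_curve_data()` and `simulate_mixture_grid()` draw log-spaced dose
designs (checkerboards with zero edges for mixtures), truth from any
implemented surface — including Greco's $\alpha$ to inject synergy
($\alpha>0$) or antagonism ($\alpha<0$) — and additive Gaussian noise on
the effect fraction, clipped to $[0,1]$ with clipping counted. Defaults
(8 doses over 4 decades for curves, $6\times 6$ grids over 4 decades for
mixtures, $\sigma = 0.02$ in the recovery studies) reflect a common
plate-style experiment.

Real assay noise is rarely additive-Gaussian: mortality counts are
binomial, variance usually shrinks near the 0% and 100% plateaus, and
replicates share plate effects. None of that is modelled. A green
round-trip test therefore establishes that the estimation and prediction
machinery is self-consistent — not that the error model matches any
particular assay. Published mixture tables are not reproduced either: their
raw experimental data live in the cited primary sources, so the table
*workflow* (unit-slope vs free-slope fits per agent, mixture-prediction
RMSE as the synergy indicator) is exercised end to end on synthetic data
instead.

## Known limitations

* No interaction parameter exists for the Hill surface itself; deviation
  from it (per-point residuals, prediction RMSE, flagged regions in
  `synergy_report()`) is the synergy measure. Confidence bands for those
  deviations would need an error model and are out of scope.
* The polynomial mixing-function generalisations (Minto/Fidler) are not
  implemented; truncated after linear terms they coincide with the Hill
  surface, which is covered, but the higher-order forms violate the
  boundary and sham conditions and are under-specified in print.
* Effects are single-endpoint fractions in $[0,1]$; multi-endpoint or
  time-resolved responses are not addressed.
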