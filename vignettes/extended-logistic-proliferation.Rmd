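---
title: "Modelling cell proliferation with an extended logistic law and correlated noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell proliferation with an extended logistic law and correlated noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolifr)
```

## The growth law

Cells recolonising a scratch wound proliferate at a rate that depends on
their own density twice over: cell–cell cooperation makes the intrinsic
proliferation rate itself density dependent, and growth-inhibiting
molecules in the culture medium (penicillin, streptomycin) exert negative
feedback on top of ordinary contact inhibition. `prolifr` models the scaled
cell density $x(t)$ by

$$\frac{dx}{dt} \;=\; r_p\,x^{\alpha+1}\!\left(1-\Big(\frac{x}{K}\Big)^{\beta}\right)
\;-\; n\,x^{\delta+1},$$

a logistic law extended in three directions:

| parameter | meaning | units | typical fitted value |
|---|---|---|---|
| $r_p$ | constant intrinsic proliferation rate | per hour | 0.13 |
| $K$ | carrying capacity of the culture environment | scaled density | 1.4–3.4 |
| $\alpha$ | cell–cell cooperation regulator ($r = r_p x^\alpha$) | — | 0.4–1.2 |
| $\beta$ | crowding / environmental-resistance exponent on $(x/K)$ | — | 1.0–1.4 |
| $n$ | negative-feedback rate from growth inhibitors | per hour | 0.01–0.08 |
| $\delta$ | inhibitor-interaction regulator ($c = n x^\delta$ per cell) | — | 0.07–0.2 |

The density scale is deliberately unit-agnostic: published scratch-assay
fits express $K$ in the same arbitrary scaled units as the data, and the
package follows suit.

With $n > 0$ the law is bistable. Besides the stable origin there is an
interior unstable root — the *conditional threshold density*, below which
the population decays to extinction exactly as in a strong Allee effect —
and an upper stable root, the *conditional maximum sustainable stable cell
density* (MSSCD), which replaces $K$ as the realised long-run density:

```{r equilibria}
p1 <- assay_params(1)   # fitted seeding-1 hexad of the reference assay
find_equilibria(p1)
```

`inflection_densities()` returns the roots of $f'(x)$ (where the absolute
rate peaks and troughs), `max_rpr_density()` the density of maximum
per-capita rate — a fitness measure for the proliferating population — and
`potential()` the landscape $U(x) = -\int_0^x f$, whose interior maximum
and minimum sit at the threshold and the MSSCD.

### Closed-form approximations

Expanding $f$ to second order about $K$ yields a quadratic whose two roots
approximate the MSSCD (minus branch, `mssd_approx()`) and the threshold
(plus branch, `threshold_approx()`). The minus branch is excellent — it
agrees with the numeric MSSCD to four decimals for the seeding-1 hexad and
to within 2% for the other two — because the MSSCD lies near $K$. The plus
branch is *not* trustworthy: the threshold lies far below $K$, where the
expansion has no business being accurate (0.243 vs the numeric 0.0671 for
seeding 1). `threshold_approx()` therefore returns the numeric root
alongside the formula value, and all quantitative reporting in the package
uses numeric roots; the expansion formulas are exposed as explicit
`_approx` operations. When the expansion discriminant is negative (strong
feedback with steep inhibitor regulation) the conditional MSSCD does not
exist and the approximation reports that as a typed result rather than an
error.

For equal regulators ($\alpha = \delta$, $r_p > n$) everything collapses to
closed form: the only equilibria are the unstable origin and the stable
$K(1-n/r_p)^{1/\beta}$, and the per-capita rate peaks at
$K\!\left(\alpha(r_p-n)/(r_p(\alpha+\beta))\right)^{1/\beta}$. These exact
cases double as oracles in the test suite.

### Numerical choices

Interior roots are found by scanning a composite grid — half log-spaced
from $10^{-8}K$ (the threshold can sit two orders of magnitude below $K$),
half linear up to `search_upper` (default $3K$; all interior equilibria lie
below $K$ when $n>0$ since $f(K)<0$) — and bisecting every sign change to
$|\Delta x| \le 10^{-12}K$. Stability at the origin is classified by the
sign of $f$ at $10^{-6}K$ because $f$ is not differentiable at 0 for
$\delta < 1$. Trajectories use an adaptive solver (`deSolve::lsoda`,
relative tolerance $10^{-9}$, absolute $10^{-12}$) with the state clipped
at zero inside the right-hand side. Degenerate exponents ($\beta = 1$,
$\delta \in \{0,1\}$) need no special-casing: the $(\beta-1)$ and
$(\delta-1)$ factors in the closed forms simply vanish.

## Fitting: Fisher RPR profiles and exhaustive grid search

Scratch assays yield short replicated series (15 time points in the
reference design), far too short for stable six-parameter nonlinear least
squares. The package therefore implements the grid-search protocol:
replicates are averaged, the mean series is converted to a density–RPR
profile with Fisher's relative-growth-rate estimator
$\mathrm{RPR}_i = (\ln \bar x_{i+1} - \ln \bar x_i)/(t_{i+1}-t_i)$, and the
residual sum of squares against the model RPR $f(x)/x$ is minimised over
the full Cartesian product of candidate values (10 per parameter in the
shipped presets, i.e. $10^6$ hexads per seeding).

Three details are left open by the protocol and were fixed here as package
choices:

* **Pairing density.** Nothing says which density accompanies each rate
  increment. The default is the arithmetic midpoint
  $(\bar x_i + \bar x_{i+1})/2$ — the standard centred estimate — with
  `left` and `geometric_mean` available as explicit policies.
* **Tie-breaking.** Ties on the RSS are broken by lexicographically
  smallest grid indices in the order $(r_p, K, n, \alpha, \beta, \delta)$,
  making the arg-min independent of evaluation order.
* **Initial density for the time-domain RSS.** `rss_density()` starts the
  integrated trajectory at the first observed mean density unless told
  otherwise.

The search itself is factorised rather than enumerated: for fixed
$(K, \beta, \alpha)$ the model RPR is linear in $(r_p, n)$ across the
$\delta$ levels, so the RSS over all $(r_p, n, \delta)$ combinations
reduces to a handful of dot products. The full $10^6$-hexad search runs in
well under a minute with $O(1)$ memory per hexad, and the winning RSS is
re-evaluated directly (not from the factorised expansion) before being
reported. `fit_logistic()` runs the same machinery restricted to
$\alpha = 0, \beta = 1, n = 0$ as the nested baseline. No automatic grid
refinement is attempted — the protocol's "repeated tuning" is left to the
user, via `param_grid()`.

```{r fit, eval = FALSE}
design <- assay_design(n_seedings = 1, n_replicates = 3,
                       obs_noise_sd = 0, initial_densities = 0.1, seed = 1)
ts <- synth_timeseries(assay_params(1), design)
grid_search(rpr_profile(ts), assay_grid(1))
```

## The stochastic analog

Heterogeneity of the inhibitor molecules perturbs the feedback rate
multiplicatively ($n \to n + \varepsilon(t)$) and environmental fluctuation
enters additively, giving the Stratonovich equation

$$\frac{dx}{dt} = f(x) - x^{\delta+1}\varepsilon(t) + \Gamma(t),$$

with zero-mean Gaussian white noises of strengths
$\langle\varepsilon\varepsilon'\rangle = 2D\delta(\cdot)$,
$\langle\Gamma\Gamma'\rangle = 2Q\delta(\cdot)$ and cross-correlation
$2\lambda\sqrt{DQ}\,\delta(\cdot)$. The equivalent one-dimensional
Fokker–Planck equation
$\partial_t P = -\partial_x[A P] + \partial_x^2[B P]$ has noise-induced
drift and diffusion

$$A(x) = f(x) + D(\delta+1)x^{2\delta+1} - \lambda\sqrt{DQ}(\delta+1)x^{\delta},
\qquad
B(x) = Dx^{2\delta+2} - 2\lambda\sqrt{DQ}\,x^{\delta+1} + Q,$$

and stationary density
$P_{st}(x) \propto B(x)^{-1}\exp\int^x A/B$. `stationary_pdf()` evaluates
this by cumulative trapezoid quadrature of $A/B$ on a uniform grid
(default 8001 points), exponentiates after subtracting the running
maximum, truncates the infinite upper limit at `x_max` (default $3K$,
raised automatically until the tail is below $10^{-10}$ of the peak), and
normalises to unit mass. Extrema of $P_{st}$ satisfy $A - B' = 0$ and are
located with the same root engine as the deterministic equilibria
(`sspdf_extrema()`); `stationary_flux()` checks the defining property
$J = AP - (BP)' \equiv 0$ by finite differences, skipping a thin layer
near the origin where fractional powers make the drift's derivatives
unbounded and central differences lose their nominal order. $B$ is
provably nonnegative for $|\lambda| \le 1$; at exactly $|\lambda| = 1$ it
is a perfect square with an interior zero, which the quadrature
regularises by $10^{-12}\max(Q,D)$ and flags in the result.

A first-order expansion of $A - B' = 0$ about $K$ gives the stochastic
conditional MSSCD (`mssd_stochastic_approx()`), which rises with $Q$ and
$\lambda$ and falls with $D$. Its published second-order condition
contains a cross-noise coefficient that is dimensionally inconsistent as
printed; the package evaluates it with $\lambda\sqrt{DQ}$, the form the
equal-regulator special case uses throughout.

### Simulating ensembles

`simulate_ensemble()` integrates sample paths two ways:

* **`ito_em`** (default): Euler–Maruyama on
  $dx = A\,dt + \sqrt{2B}\,dW$, the Itô equation whose Fokker–Planck
  equation is *exactly* the one above — so long-horizon ensembles converge
  to `stationary_pdf()`. This is the convention every
  distribution-comparison in the package relies on.
* **`stratonovich_heun`**: a Heun predictor–corrector on the original
  two-noise Stratonovich form with Cholesky-correlated increments
  $dW_2 = \lambda\,dW_1 + \sqrt{1-\lambda^2}\,dW_3$, kept as an
  independent cross-check; at moderate step sizes the two schemes are
  statistically indistinguishable.

The function default is $dt = 10^{-3}$ h. The longer analyses in the test
suite and acceptance script use $dt = 10^{-2}$ h with horizons of 250–400 h
and 500–2000 paths; halving $dt$ at those settings moves the terminal
Kolmogorov–Smirnov distance by less than 0.01, which is the convergence
guard that fixed the choice. All ensembles are bitwise-reproducible from
`(seed, dt, scheme, boundary)`.

### Extinction: occupancy versus survival

The boundary at $x = 0$ is a genuine modelling fork, and the package
exposes both prongs.

With the default **reflecting** boundary ($x \leftarrow |x|$ after each
step) ensembles converge to the stationary density above. In that
*occupancy* reading, weak uncorrelated noise ($D = Q = 0.01$,
$\lambda = 0$) parks only a few percent of the stationary mass near zero,
and even strong multiplicative noise ($D = 0.05$) leaves the stationary
mode at an interior density — near-zero visits are frequent but brief.

With an **absorbing** boundary a path that touches zero is extinct
forever, and the terminal mass at zero is the *cumulative extinction
probability* — a survival reading. Started at the MSSCD, the same noise
settings then separate dramatically, because the correlation controls the
diffusion at the well bottom:
$B(\mathrm{MSSCD})$ shrinks roughly sixteen-fold between $\lambda = 0$ and
$\lambda = 1$ at $D = Q = 0.01$. Perfectly correlated noise keeps
essentially every path alive in a symmetric bump at the MSSCD;
uncorrelated noise extinguishes the majority (a dominant zero mode beside
a surviving bump); $D = 0.05$ extinguishes nearly all paths within 400 h;
and with $D = 0$ extinction by additive noise alone is slow, so the
stationary mode at the MSSCD describes the population on these horizons.
The acceptance suite evaluates each qualitative regime under the reading
in which it is well-posed — stationary occupancy for the sustained
regimes, survival for the extinction-dominated ones — because no single
boundary convention exhibits all four at once; conflating the two readings
is, in our analysis, the easiest way to misread steady-state histograms of
this model.

`classify_steady_state()` turns terminal densities into a mode report:
Freedman–Diaconis bins for the surviving mass plus a dedicated extinction
bin $[0, 0.05K)$, peaks accepted when their prominence clears both 5% of
the tallest bin and a $3\sqrt{\text{count}}$ Poisson floor, and peaks
separated by valleys shallower than half the lower peak merged (sampling
noise on one bump, not bimodality).

## Synthetic assay data

`synth_timeseries()` emulates the reference experimental design — three
seeding conditions, three replicates, observations every 2 h to 18 h then
every 6 h to 48 h — by integrating the deterministic law from per-seeding
initial densities and adding independent Gaussian observation noise to the
densities (never the times), truncated at zero. Defaults: initial
densities $(0.1, 0.15, 0.2)$, loosely mirroring the 12k/16k/20k
cells-per-well seeding ratios of the reference assay (the absolute density
scale being undefined there), and `obs_noise_sd = 0.02`, about 1–2% of a
typical $K$ — a placeholder, since the assay's true error magnitude is
unpublished.

What passing tests on such data do show: the full pipeline (generator →
Fisher profile → $10^6$-hexad search) recovers an on-grid generating hexad
exactly in the noiseless limit, and degrades gracefully under small
observation noise. What they do not show: anything about real assays'
error structure — correlated imaging errors, heteroscedasticity, drift —
none of which the white-noise generator emulates, nor whether the printed
RSS values of the reference fits used midpoint, left, or another pairing
(indeterminable from the protocol description). Refitting real scratch
assay data remains a supported workflow via `read_timeseries()` and the
CLI, not a package guarantee.

## Known limitations

* The stationary machinery covers white noise only; exponentially
  correlated (coloured) noise is out of scope.
* No transient Fokker–Planck solver: time-dependent distributions come
  from Monte-Carlo ensembles only.
* Noise parameters $(D, Q, \lambda)$ are inputs, not fitted quantities.
* The plus-branch threshold approximation is reported for completeness but
  should never replace the numeric root.
* Confidence intervals for grid-search estimates are not provided; the
  protocol itself offers none.
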