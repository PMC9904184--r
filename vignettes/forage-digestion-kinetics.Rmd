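---
title: "Forage digestion kinetics: models, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forage digestion kinetics: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

This vignette is the package's account of its science: the two measurement
models it implements, the assumptions behind them, what the synthetic-data
generators do and do not emulate, and every numerical choice a maintainer
might want to revisit.

## The in vitro gas production model

Fermenting a forage with equine caecal inoculum in a sealed bottle
produces gas roughly in proportion to substrate degradation. An automated
system records headspace gauge pressure on a 10-minute grid for 48 h and
vents the bottle whenever the gauge exceeds a threshold (0.75 psi by
default), so a single reading never reflects total gas. `cumulative_gas()`
reconstructs the cumulative gauge-equivalent pressure as

> current gauge reading + sum of all pressure released by vents so far,

converts it to moles with the ideal gas law $n = pV/RT$ and to volume with
the 22,400 mL/mol molar volume at standard conditions, and divides by
grams of substrate dry matter. The conversion chain is linear in pressure,
which is what makes the venting bookkeeping exact: the reconstruction is
invariant to when, how often, or whether the bottle vented (a property the
test suite checks to 10⁻⁹ mL/g DM).

The cumulative curve is summarised by the monophasic sigmoidal model

$$G(t) = \frac{A}{1 + (B/t)^C}$$

with $A$ the asymptotic gas production (mL/g DM, a proxy for potential
digestibility), $B$ the half-time (h; $G(B) = A/2$ exactly), and $C$ a
dimensionless shape constant. Only the single-phase member of the summed
sigmoidal family is implemented; multiphasic variants are out of scope.
The time of maximum rate of gas production is

$$t_{RM} = B\,(C-1)^{1/C},$$

defined only for $C > 1$ (below that the curve has no interior
inflection); `t_rm()` returns `NA` there rather than an error. Note that
$t_{RM} < B$ holds only for $1 < C < 2$, with equality at $C = 2$;
fitted shape constants for grass substrates fall in roughly $[1.2, 2.0]$,
so in practice the maximum rate precedes the half-time.

### Assumptions

* Readings are gauge pressure above ambient; the headspace behaves
  ideally at incubation temperature.
* The substrate's own volume is negligible against the headspace.
* A vent resets the gauge to zero at the vent timestamp and the released
  pressure is recorded exactly.
* $G(0) = 0$ by continuity ($t$ sits in a denominator exponent); the
  $t = 0$ reading is excluded from fitting since it carries no
  information.

### Constants and tunables

| quantity | default | unit | rationale |
|---|---|---|---|
| headspace volume | 0.150 | L | 250 mL bottle − 66 mL buffer − 34 mL inoculum; substrate volume ignored |
| temperature | 312.15 | K | 39 °C incubator |
| gas constant | 8.314472 | L·kPa·K⁻¹·mol⁻¹ | CODATA |
| molar volume | 22,400 | mL/mol | ideal gas at 273.15 K, 101.325 kPa |
| psi → kPa | 6.894757 | kPa/psi | exact definition |
| vent threshold | 0.75 | psi | instrument release setting |

All are fields of `incubation_constants()` and configurable. The headspace
volume and temperature are the two the instrument does not dictate; both
scale the pressure-to-volume conversion linearly, so misspecifying them
rescales $A$ but leaves $B$, $C$ and $t_{RM}$ untouched.

### Blank correction

Blank bottles (inoculum and buffer, no substrate) gas on their own.
`blank_correct()` subtracts the timepoint-wise **mean blank volume in
mL/bottle** from the substrate bottle's mL before DM normalisation,
interpolating linearly where time grids differ. Whether to correct is a
toggle (`fit_gas_study(blank_correction = )`), because instrument reports
differ in whether their cumulative output is already net of blanks; both
modes are first-class. Corrected values may go slightly negative early in
the incubation; they are kept and counted (`n_negative` attribute), never
clamped, since clamping would bias the subsequent fit.

### Fitting

`fit_monophasic()` minimises $\sum (G_{obs} - G_{model})^2$ by
Levenberg–Marquardt (`minpack.lm::nlsLM`) under box bounds, falling back
to bounded Gauss–Newton (`nls` "port") if that fails. Numerical choices:

* **Initialisation**: $A_0 = 1.1 \max G$; $B_0$ = linearly interpolated
  first crossing of $A_0/2$; $C_0 = 1.5$ (the middle of the plausible
  range).
* **Bounds**: $A \in (0, 5\max G]$, $B \in (0, 96]$ h, $C \in [0.1, 10]$ —
  wide enough never to bind for real curves, tight enough to stop the
  optimiser wandering when data are degenerate.
* **Tolerances**: parameter/function tolerance $10^{-16}$
  (i.e. `tol^2` with `tol = 1e-8`), at most 1000 iterations. On noiseless
  synthetic curves this recovers parameters to better than $10^{-6}$
  relative, which the tests assert.
* **Degenerate input**: an all-zero curve raises an error; fewer than 6
  positive-time points raises an error; an optimiser failure returns a
  *flagged* fit (`converged = FALSE`, with the message), never a silent
  one.

The fit object is a classed S3 model with `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals`, `deviance` and `plot` methods; an
independent Nelder–Mead optimiser in the test suite confirms the RSS
minimum is the same.

## The mobile-bag model

Porous bags of feed are swallowed, transit the stomach and small
intestine, and are fished from the caecum with a magnet every hour for
10 h; stragglers appear in faeces. The package computes:

* **Transit time** $\sum_i t_i M_i$: $t_i$ is the midpoint of the $i$-th
  hourly check and $M_i$ the fraction of caecum-recovered bags first seen
  there. A bag found at the check at hour $k$ is assigned $t_i = k - 0.5$
  h: hourly withdrawal only brackets arrival to the interval $(k-1, k]$,
  and its midpoint is the natural point estimate.
* **Recovery rates**: caecal = caecum count / intubated × 100; total adds
  faecal recoveries. Wash controls never enter the denominator.
* **Pooling**: residues are pooled by grass × harvest × pore × interval
  (1–3, 4–6, 7–10 h; midpoints 2, 5, 8.5 h). Pooled mass is the sum of
  member masses and pooled composition the residue-mass-weighted mean, so
  pool-level disappearance equals the feed-mass-weighted mean of per-bag
  disappearance when feed composition is shared — an identity the tests
  verify. Faeces-recovered and lost bags are excluded from transit time,
  pooling and disappearance; they count only toward total recovery, since
  post-caecal residues no longer measure *precaecal* digestion.
* **Washing loss** is reported alongside, never subtracted from, in vivo
  disappearance: the two answer different questions (instantly soluble
  fraction vs. total precaecal loss), and subtracting would double-count
  solubles that would also have left an intubated bag.
* **Common-slope regression**: `common_slope_fit()` fits
  $dDM = b\,t + a_g$ by OLS — one shared slope, one intercept per
  grass × harvest group, no interaction (dummy-coded ANCOVA). The shared
  slope equals the pooled within-group slope
  $\sum_g S_{xy}^{(g)} / \sum_g S_{xx}^{(g)}$, which the tests check
  against a hand-written oracle to $10^{-10}$. Per-bag points at exact
  check midpoints are the default regression input; interval midpoints
  are used only when nothing finer exists. Rank deficiency (one distinct
  time, or an empty group) raises a singular-design error.

The intercept of each line is the extrapolated disappearance at zero
residence time — operationally, the instantly soluble washout of that
feed.

## What the generators emulate

`simulate_incubation()` inverts the measurement chain: evaluate $G(t)$ on
the grid, add the inoculum background (the blank curve) when
`background = TRUE`, convert mL → moles → kPa → psi, vent whenever the
gauge would cross the threshold, add Gaussian sensor noise to gauge
readings (sd 0.01 psi by default — instrument resolution is not public,
and 0.01 psi ≈ 0.07 mL/g DM is conservative), truncated at zero with the
$t=0$ reading pinned to exactly 0. Replicate bottles vary by independent
lognormal factors on $A$, $B$, $C$ (sdlog 0.05); the joint distribution of
replicate parameters is unknown, so independence is assumed. Default
ground truth spans A ∈ [112, 186] mL/g DM, B ∈ [7.6, 12.1] h,
C ∈ [1.24, 1.95] across 12 grass × harvest substrates.

`simulate_bag_study()` draws each intubated bag's fate (caecum with
probability 0.78, faeces to a 0.97 total, else lost), a lognormal transit
time (target mean 4.7 h, sd 1.7 h) discretised to hourly checks and
truncated at 10 h for caecal bags, then sets dDM from the common-slope
model (slope 0.608 %/h; intercepts 38.01 / 32.51 / 35.29 / 21.37 % for
PR-early / PR-late / CF-early / CF-late) plus Gaussian noise (sd 2
percentage points, truncated to [0, 100]). Residue mass follows from dDM;
each nutrient's residue content follows from a soluble-fraction plus
first-order model, $d(t) = s + (1-s)(1 - e^{-kt})$, with sugars nearly
all soluble (s = 0.93–0.97), fructan s = 0.70 but fast-degrading, fibre
s = 0.02 and slow, protein in between. Wash-control bags lose exactly the
soluble fraction per nutrient, and their dry matter loss is the group's
regression intercept plus noise — the intercept *is* the zero-residence
loss, so the generator uses it rather than inventing an independent
parameter.

`simulate_feeds()` draws block-replicate compositions around grass ×
harvest means with Gaussian noise applied to the component sugars, WSC
being formed as their sum — generated feeds therefore pass
`wsc_consistency()` at tolerance zero by construction. The means encode
the qualitative maturation pattern: protein falls, fibre rises, fructan
accumulates late in some species but not in cocksfoot or meadow fescue.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: microbial community or pH dynamics, correlated
replicate kinetics, autocorrelated sensor drift, diurnal or horse-level
variation in gut motility, pore-size effects on disappearance (the
generator's nutrient model is pore-blind even though the analysis
stratifies by pore), bag-to-bag feed composition variation, and any
systematic assay bias in the enzymatic sugar chemistry. Recovery of the
generating parameters demonstrates the estimators are correct, not that
the biological values are.

## Reproducibility and problem sizes

Every generator is a pure function of (scenario, seed): the RNG state is
saved and restored around each call, so generators neither disturb nor
depend on the caller's stream, and equal seeds give identical output. The
test suite exercises full-size single studies (289-point traces, 352-bag
designs) and keeps Monte-Carlo loops moderate by design — 100 seeds for
noisy-fit recovery, 220 for slope recovery, 25 replicate bag studies for
the transit/recovery targets — sizes at which the binomial and regression
standard errors are already several times smaller than the tolerances
being asserted.

## Known limitations

* Only the monophasic model is fitted; substrates with genuinely biphasic
  gas curves (e.g. high-sugar plus high-fibre mixtures) will show lack of
  fit that the residual sd and `plot()` reveal but the package will not
  resolve into phases.
* Disappearance is bookkeeping on a DM basis including ash; an ash-free
  basis is not offered because residue ash was not part of the data
  model.
* The Latin square randomisation is a cyclic square with rows, columns
  and symbols permuted by seed — a uniformly random Latin square is not
  attempted (nor needed for balance).
* The two-way least-squares summary provided by `common_slope_fit()` is
  descriptive; mixed-model inference, multiple-comparison letters and
  P-values are deliberately out of scope.
* Internal-standard bottles (e.g. sugar beet pulp) are fitted like any
  substrate; no normalisation to the standard is applied.
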