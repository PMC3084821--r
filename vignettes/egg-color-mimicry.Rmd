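---
title: "Egg-color mimicry in avian color space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg-color mimicry in avian color space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggmimicry)
```

This vignette documents the models implemented in **eggmimicry**, the
assumptions behind them, the tunable parameters with their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The avian tetrahedral color space

Birds with an ultraviolet-sensitive (UVS-type) retina have four cone
classes (uv, s, m, l). A reflectance spectrum $R(\lambda)$ stimulates
cone $i$ with quantum catch

$$Q_i = \int_{300}^{700} R(\lambda)\, C_i(\lambda)\, d\lambda ,$$

evaluated by the trapezoid rule on a canonical 300–700 nm grid with
1-nm spacing (`canonical_grid()`); input spectra on other grids are
linearly interpolated. The illuminant is ideal (spectrally flat): no
von-Kries adaptation or receptor-noise model is applied, so the
representation captures *relative* spectral shape only. Catches are
normalized to sum to one, which makes the mapping invariant to scaling
the spectrum by any positive constant — brightness is deliberately
outside the space (its contrast is handled separately by
`brightness_contrast()`, the absolute difference of integrated
reflectance, isolated behind one function so an alternative achromatic
proxy can be swapped in).

The normalized stimulations $(uv, s, m, l)$ live on a 3-simplex that is
mapped to Cartesian coordinates

$$x = \tfrac{1 - 2s - m - uv}{2}\sqrt{3/2}, \qquad
  y = \tfrac{-1 + 3m + uv}{2\sqrt 2}, \qquad
  z = uv - \tfrac14 ,$$

placing the achromatic point at the origin, the uv vertex at
$(0, 0, 0.75)$, every vertex at circumradius $0.75$, and the edge
length at $\sqrt{3/2}$. Hue is the direction of the color vector —
longitude $\theta = \mathrm{atan2}(y, x) \in (-\pi, \pi]$ and latitude
$\phi = \arcsin(z/r)$ — and saturation is its length $r$. At $r = 0$
the angles are undefined; both are reported as 0 with an `achromatic`
flag (the pole uses the same $\theta = 0$ convention). The mimicry
metric $\Delta T_C$ is the Euclidean distance between two colors.

**Cone sensitivities.** The bundled curve set
(`inst/extdata/uvs_cone_sensitivities_synthetic.csv`) is a constructed
stand-in built from Govardovskii A1 alpha-band templates at typical
average UVS peaks (371, 448, 503, 563 nm); measured average curves,
where available, can be supplied via `bird_visual_system(path =)`.
Each curve is normalized to unit trapezoid area so that a flat spectrum
is *exactly* achromatic — an analytic anchor the tests rely on.

**Robinson projection.** Hue spheres are flattened with the classic
cartographic Robinson projection: the published coefficient table at
5° latitude intervals, cubic-spline interpolated, on a unit sphere
($px = 0.8487\,X(|\phi|)\,\theta$, $py = 1.3523\,Y(|\phi|)\,
\mathrm{sign}(\phi)$).

**Hue is circular.** Everywhere the package reasons about "the range of
observed hues" — the sampling envelope, landscape binning, percentile
band exclusion — it works along the contiguous arc of the hue circle,
defined as the complement of the largest empty gap among the observed
$\theta$ values. A naive linear min/max range silently explodes to the
whole circle as soon as a single value wraps past $\pm\pi$, and a
landscape peak near the cut then reappears at the other end of the axis
as a spurious second maximum. When the arc straddles the cut, landscape
curves are reported on a continuous axis extending past $\pi$.

## The host discrimination function

Egg-exchange experiments yield binary outcomes (rejection = 1). The
discrimination function is a binomial logistic regression (logit link)
of outcome on $\Delta T_C$ and candidate covariates, fitted by
iteratively reweighted least squares; convergence is declared when the
relative deviance change falls below $10^{-8}$ (at most 100
iterations). Complete separation and rank-deficient designs raise
explicit errors naming the problem. Model selection
(`backward_eliminate()`) is stepwise backward deletion: at each step
every currently droppable term is tested by the change in deviance
against $\chi^2$ on the term's degrees of freedom, and the term with
the largest $p \ge \alpha$ (default $\alpha = 0.05$; ties broken toward
the smaller deviance change) is removed, interactions always before
their main effects, until every remaining term is significant. A
`method = "single"` variant performs one round of single-term deletions
from the full model; note that with interactions present, a main effect
can be masked by its own interaction columns under single deletion,
which is why sequential elimination is the default.

`predict_rejection()` applies the fitted univariate curve, optionally
with pointwise delta-method confidence intervals on the linear
predictor scale. With the generator's default truth
$\beta = (-2, 60)$, rejection crosses 50% at $\Delta T_C = 1/30 \approx
0.033$ — the scale at which the calibrated synthetic populations put
the optimal egg near coin-flip odds.

A practical note on backward elimination with many null candidates: at
$\alpha = 0.05$, each truly null term independently survives to the
minimal model with probability near 0.05, so with nine null candidates
the minimal model contains *only* the true term in roughly
$0.95^9 \approx 63\%$ of replicates. This is a property of stepwise
testing itself, not of the implementation; the true contrast term is
essentially always retained.

## Optimal mimicry and selection landscapes

For a host population, `pairwise_contrasts()` builds the symmetric
matrix of clutch contrasts; the **optimal egg** is the clutch with the
lowest mean contrast to all *other* clutches (self-pairings excluded;
ties broken toward the lowest index), and the achievable bounds are the
minimum and maximum of those per-clutch means — the lowest average
contrast any egg restricted to observed clutch colors can achieve, and
the highest average contrast an egg can have while still perfectly
matching at least one clutch. `cuckoo_fitness_profile()` evaluates real
or hypothetical parasite eggs against *all* clutch pairings (a parasite
egg is not a clutch, so no pairing is excluded; an egg placed exactly
on the optimal clutch color therefore has mean contrast
`lower_bound * (n-1)/n`, about 1% below the bound at n = 88). The
reported SD of rejection probabilities is across clutch pairings.

`sample_host_space()` draws hypothetical parasite colors evenly in hue
and saturation over the host's occupied region: $\theta$ uniform on the
observed hue arc, $\phi$ uniform on the observed latitude range, and
$r$ uniform on $(0, r_{\max}]$ with $r_{\max}$ the smaller of the gamut
boundary along the drawn direction (`gamut_max_saturation()`, an exact
ray–simplex intersection) and the largest observed host saturation.
`acceptance_landscape()` averages $1 - P(\text{reject})$ over clutches
for each sample, summarizes along $\theta$ with equal-count bins
(default 50; the acceptance tests use 25 bins at $n = 3000$, i.e. 120
samples per bin, putting the Monte-Carlo standard error of a bin mean
near 0.01), and joins the bin means with an interpolating natural cubic
spline — interpolation, not smoothing, so the curve passes through the
bin means exactly. `count_landscape_peaks()` calls two maxima distinct
only when the dip between them is at least 0.05 acceptance units
(default), i.e. clearly above bin-mean noise; shallower saddles count
as one plateau. `exclude_theta_band()` removes clutches strictly
between two empirical hue percentiles (type-7 linear-interpolation
quantiles on the arc coordinate) to emulate increasingly bimodal host
distributions.

## Permutation statistics

All Monte-Carlo p-values follow the add-one convention
$p = (b + 1)/(n_\text{perm} + 1)$, where $b$ counts permuted statistics
as or more extreme than the observed one, and every test takes a
per-call `seed` (the caller's RNG state is restored). Exhaustive
enumeration (`exhaustive = TRUE`, $n \le 9$) gives exact p-values.

* **MRPP**: $\delta = \sum_g (n_g/N)\,\bar d_g$ with $\bar d_g$ the
  mean within-group pairwise distance; labels are permuted; the
  chance-corrected effect size $A = 1 - \delta/E[\delta]$ is always
  reported with $E[\delta]$ the overall mean pairwise distance. The
  disparity-style effect size sometimes quoted alongside MRPP results
  depends on a definition published elsewhere; $A$ and $\delta$ are
  reported unconditionally and a disparity statistic can be layered on
  top once its exact form is fixed.
* **Mantel / partial Mantel**: Pearson correlation of the upper
  triangles; rows and columns of one matrix are permuted
  simultaneously; one-sided toward positive concordance by default.
  The partial test correlates the elementwise least-squares residuals
  of both matrices on the controlled matrix and permutes the
  residualized first matrix.
* **Permutational MANOVA** (one factor or single continuous
  regressor): Gower-centered inner-product matrix
  $G = -\tfrac12 C D^{(2)} C$, pseudo-$F$ from the hat-matrix partition
  of $\mathrm{tr}(G)$, partial $R^2 = SS_\text{model}/SS_\text{total}$,
  p-value by permuting raw observations. For Euclidean distances and a
  categorical factor this reproduces the classical one-way ANOVA $F$
  exactly.
* **Dispersion (multivariate Levene analogue)**: Euclidean distances
  to group centroids compared by ordinary ANOVA, with optional Tukey
  HSD pairwise comparisons.
* **Great-circle distances**: haversine on a sphere of radius
  6371.009 km (the mean Earth radius; configurable, since published
  analyses sometimes use an equatorial radius).

Default permutation counts are 1000 for Mantel-type tests and 10000
for MRPP and permutational MANOVA.

## The synthetic-data generator

The generator is the package's test bed; it emulates the *structure* of
egg-color data from a two-host brood-parasite system, not any
particular data set.

* **Populations** (`synth_population()`): hue longitudes from a von
  Mises mixture (the natural circular analogue of unimodal vs bimodal
  hue structure), latitudes and saturations from normals truncated to
  the gamut, one egg per clutch (within-clutch color variation in the
  study species is negligible; an intraclutch spread knob is
  deliberately absent because no quantitative figure exists to
  calibrate one).
* **Presets** (`preset_scenario()`): the *brambling-like* preset (232
  clutches, single component at $\mu = 2.0$, $\kappa = 10$, saturation
  $0.103 \pm 0.018$) and the *chaffinch-like* preset (157 clutches,
  modes at 1.7 and 2.3 with $\kappa = 6$, saturation $0.070 \pm
  0.016$). Both are calibrated so the population mean pairwise
  $\Delta T_C$ is close to 0.045. The chaffinch preset is intentionally
  a *moderately* bimodal, heavy-shouldered distribution — "thicker at
  the tails" — rather than two disjoint clusters: its mode separation
  (about 0.04 in $\Delta T_C$ units) is below twice the logistic
  transition scale of the default discrimination law, the regime in
  which the acceptance landscape shows a broad plateau rather than two
  distinct adaptive peaks. Strong, well-separated bimodality for
  detection tests is a separate configuration, not the species preset.
* **Spectra** (`synth_spectrum()`): a target $(\theta, \phi, r)$ is
  converted to cone catches and a spectrum is assembled as a
  non-negative combination of a flat component and smooth Gaussian
  bumps (sd 15 nm, centers every 10 nm) via non-negative least squares
  against the basis' quantum-catch matrix. Positivity is guaranteed by
  construction, the mapped color matches the target to far better than
  the guaranteed $\Delta T_C \le 0.005$, and targets outside the
  spectral locus of the basis raise an explicit error. A small
  fixed-shape basis solved without the positivity constraint was
  rejected at design time: its locus misses saturations the presets
  need, whereas the constrained dictionary reaches $r \ge 0.14$ for
  every hue.
* **Trials** (`synth_trials()`): random clutch-egg pairings with
  Bernoulli outcomes from $\mathrm{logit}^{-1}(\beta_0 + \beta_1
  \Delta T_C)$ (default truth $(-2, 60)$), plus nuisance covariates
  (brightness, shape, volume contrasts, species) that are null by
  default and can be given true effects through `nuisance_beta`.

All randomness flows from a single seed per call and the global RNG
state is restored afterwards.

**What passing tests do and do not show.** The generator produces
smooth, noiseless-by-default spectra, perfectly logistic hosts, and
independent trials. Real data add instrument noise, pigment-specific
spectral shapes, museum-storage color drift, replicated individuals and
imperfectly known sensitivities — none of which are emulated. Green
tests therefore validate the *computational pipeline* (geometry,
estimators, permutation machinery), not biological conclusions about
any real host-parasite system.

## Problem sizes and runtime choices

The test suite and the acceptance script use the preset population
sizes (232 and 157 clutches), 288 or 2000 trials per fitted model, 100
seeded replicates for rate-style checks (type-I error, coverage,
retention), 200 replicates for the p-value uniformity and CI coverage
checks, 3000 sampled colors per landscape, and 199–999 permutations in
Monte-Carlo significance tests (10000 remains the analysis default).
These sizes were chosen so each stochastic assertion has comfortable
statistical margin while the whole suite completes in a few minutes.

## Known limitations

* No receptor-noise (JND) discriminability model; contrasts are plain
  Euclidean distances in the tetrahedral space.
* The bundled sensitivity curves are template stand-ins; analyses of
  real spectra should supply measured average curves.
* The optimal-egg search is restricted to observed clutch colors — the
  definition of "best achievable mimic" used here — rather than a
  continuous optimizer over the gamut.
* The brightness-contrast proxy (integrated reflectance difference) is
  one of several reasonable achromatic measures; it is isolated behind
  `brightness_contrast()` for exactly that reason.
* Multi-factor permutational MANOVA with interaction strata is out of
  scope; only single-variable partitions are provided.
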