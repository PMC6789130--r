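---
title: "Methods: geolocation, phenology, space use and isotopic assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geolocation, phenology, space use and isotopic assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puffintrack)
```

This vignette documents the models implemented in `puffintrack`, the
assumptions behind them, the parameters that matter, and the design
decisions taken where the underlying field methodology leaves latitude.

## Threshold geolocation

### Model

A light logger on a bird's leg records ambient light (0–64 arbitrary
units). The *threshold method* defines sunrise/sunset as the times the
trace crosses a fixed threshold (default 10). `detect_twilights()`
locates crossings by linear interpolation between adjacent samples and
pairs them into light-day and dark-night pairs, giving two position fixes
per day. Longitude comes from the pair midpoint: at local solar noon the
true solar time is 12:00, so
`lon = (720 − EoT − t_mid) / 4` degrees, with `EoT` the equation of time
in minutes (night pairs add 180°). Latitude solves

`sin(EA) = sin(φ) sin(δ) + cos(φ) cos(δ) cos(H₀)`

with `H₀ = 7.5° × day length (h)`. The solar ephemeris (declination,
equation of time) uses the standard NOAA polynomial series, accurate to
~0.01° — negligible against geolocation error (order 10² km). Elevations
are geometric: refraction is not modelled separately because the
calibrated EA absorbs it.

### Sun elevation angle calibration

EA is a device property. `calibrate_ea()` grid-searches (default −5° to
−2° by 0.25°) over a window in late incubation/chick-rearing when birds
are assumed colony-centred, scoring each candidate by the median
great-circle distance of its fixes to the colony. Ties go to the
candidate with fewer on-land fixes (if a coastline polygon is supplied),
then to the candidate nearest −3.5°, the centre of the plausible range
for this logger family.

### Filtering cascade

`filter_track()` *flags* rather than deletes, so filter provenance stays
auditable, and flagging is recomputed from scratch on each call (hence
idempotent):

* **equinox** — day length carries almost no latitude information near
  the equinoxes. Windows are asymmetric: 10 days on the winter side, 5 on
  the summer side. "Winter side" is read as the side toward the winter
  solstice (before the March equinox, after the September one), because
  latitude error grows as day lengths approach their winter extreme.
  Equinox dates are computed from the declination zero-crossing, not
  hard-coded.
* **lat_bounds** — retained latitudes must fall in [30, 52]°N, the
  plausible range for this study system.
* **speed** — a single forward pass flags any fix whose implied speed
  from the *last retained* fix exceeds 55 km h⁻¹. An iterative variant
  (repeat until stable) is available via `method = "iterative"`.
* fixes whose latitude is unsolvable (`|argument| > 1`) or degenerate
  (day length within `eps_hours = 0.1` h of 12 h) carry `lat_missing`.

### Numerical choices

Latitude has two algebraic roots `φ = θ ± acos(C/R)`; both are wrapped to
[−180°, 180°] and the root inside [−90°, 90°] is taken (the other lies
poleward of 90° throughout the study envelope). Dark periods shorter than
4 h are physically impossible at the study latitudes and treated as
shading artifacts: their two crossings are removed and the surviving
neighbouring pair is flagged `interference` — a reproducible surrogate
for the manual inspection used with real traces. Light spikes shorter
than 1 h at night are removed symmetrically.

The two-fixes-per-day convention (noon fix from the light-day pair,
midnight fix from the dark pair, each dated by its midpoint's civil date)
is a choice; field practice varies and no single convention is canonical.

## Phenology from immersion and light

Night visits are runs of completely dry 10-min blocks totalling ≥ 2 h
inside a night interval (the run-length threshold rescales with block
length, so 5-min blocks need 24 blocks). Day visits are dates whose every
daytime light sample is below threshold — cave incubation. Night/day
intervals come from the colony solar model at −6° (civil twilight),
matching the crepuscular attendance of these birds.

Derived dates:

* non-breeding bounds: last/first night visit around the *longest* gap
  between night visits, which must exceed `min_migration_days = 30`
  (guarding against mid-season absences); two equally long gaps raise an
  error rather than guessing;
* laying — males: first day-visit run of length ≥ 2 (males take the first
  long incubation shift); females: first colony visit (night *or* day —
  the attendance record, not only cave days) after the longest absence
  exceeding `exodus_min_days = 5` (the pre-laying exodus). The search
  stops at the bird's last day visit so the post-breeding migration gap
  can never masquerade as an exodus. For pairs, the start of the first
  alternating pattern of abutting, non-overlapping day-visit runs by the
  two partners is used, falling back to the sex rule; the alternating-runs
  reading is one interpretation of shared incubation and is isolated in
  the pair branch;
* hatching proxy: the last day visit (daytime attendance ceases shortly
  after hatching); no correction for post-hatch brooding days is applied;
* imputation: a failed logger's return date is the cohort median of
  observed first night visits (≥ 3 birds); with an even cohort the
  *earlier* central date is taken, for determinism.

## Space use

Retained fixes are projected with a spherical Lambert conformal conic
(standard parallels 33°N/45°N, central meridian 5°E, radius 6371.0088 km)
— conformal, with scale error below ~0.6 % between the parallels, well
under geolocation error. `kernel_density()` evaluates a Gaussian-kernel
KDE with a full (unconstrained) bandwidth matrix by linear binning and
FFT convolution on cell centres (default 1×1 km). The grid covers the
data bounding box plus 4 kernel SDs: at 3 SDs a boundary point loses
~5×10⁻³ of its kernel mass, which would break the normalization
invariant (Σ density × cell area = 1 ± 10⁻³); 4 SDs keeps truncation
below 3×10⁻⁴. Grids beyond `max_cells = 4e6` are refused with a
suggestion to coarsen.

`plugin_bandwidth()` implements a 2-stage unconstrained plug-in: data are
pre-sphered; the fourth-order integrated density-derivative functionals
ψᵣ (|r| = 4) are estimated by pairwise kernel evaluation with a
normal-scale pilot `g = (4 / (6n))^(1/8)` on the sphered scale; then
`AMISE(H) = (4π n)⁻¹ |H|^(−1/2) + ¼ Σ ψ-weighted bias terms`
is minimised over symmetric positive-definite `H` via a Cholesky
parameterisation, and the result back-transformed — making the selector
exactly equivariant under affine rescaling. For Gaussian data with exact
functionals this reproduces the normal reference `H = n^(−1/3) Σ`; its
behaviour is validated against that reference only. Near-collinear
scatters are ridged with a warning.

Contours are highest-density regions: the smallest set of cells, in
descending density order, holding ≥ p % of the total grid mass — nested
by construction. Pooled population estimates weight birds equally
(weights 1/nᵢ per fix); per-fix pooling is available by passing uniform
weights. Whether real pooled maps should weight birds or fixes equally is
genuinely open; birds-equal is the default because unequal logger
lifespans otherwise dominate the map.

## Isotopic assignment

Feather δ¹⁵N/δ¹³C are processed as follows:

* **Lipid normalization** applies only to prey muscle with C:N strictly
  greater than 3.15. The equation registry ships the Post et al. (2007)
  aquatic equation (δ¹³C′ = δ¹³C − 3.32 + 0.99·C:N) as the named default,
  recorded in the output's `equation` attribute, because the specific
  equation used with the original prey data is not public.
* **Trophic discrimination**: prey values are shifted by +3.7 ‰ (δ¹⁵N)
  and +1.9 ‰ (δ¹³C) into consumer-feather space.
* **Ward clustering** (`stats::hclust`, `ward.D2`) groups samples in
  isotope space; tests verify the merge heights against a brute-force
  Lance–Williams enumeration.
* **Standard ellipses**: SEA = π √(λ₁λ₂) from the sample covariance
  eigenvalues; SEAc multiplies by (n−1)/(n−2).
* **Discriminant analysis**: classical two-group LDA with pooled
  within-group covariance, emitting the canonical function (unit pooled
  within-group variance, zero at the mean midpoint, positive toward the
  Atlantic group), Fisher classification functions, and Wilks'
  Λ = det(W)/det(T) with both Rao's F and Bartlett's χ² transforms —
  both are emitted because which approximation the original software
  used is not stated. **Priors are equal** in the Fisher constants even
  though training groups are unbalanced: with proportional priors the
  rarer Mediterranean class would be penalised at the boundary, and
  nothing indicates size-proportional priors were used; the choice is
  material and therefore explicit (`priors` argument).
* The published P1/P6 coefficient sets ship as presets
  (`discriminant_preset()`), evaluated exactly as typeset — no
  re-derivation is attempted since the training data are unpublished.
  Chick-down reference samples are context only and never enter training.

## The synthetic generator

`simulate_schedule()` encodes the study system's annual cycle: colonies
attended January–June and October–December, laying in early/mid March
(population means: day-of-year 60 Mallorca, 77 Menorca, 81 Yelkouan;
SD 5 d), 51-day incubation in alternating 3–5-day shifts, a 10–18-day
female pre-laying exodus ending on the laying date, departure ~45 days
after hatching, return around 5 October, and a non-breeding centroid
drawn from the colony mixture (Atlantic probability 0.85 Mallorca, 0.20
Menorca, 0 Yelkouan; Black Sea destinations are far-eastern
Mediterranean-system centroids — no strait-passage routing). Migration
legs respect a 600 km/day displacement cap; residency is a mean-reverting
walk around the centroid. Construction guarantees that the generator's
truth dates are exactly the dates the phenology rules define (first cave
day = laying; last cave day = hatch; attendance gaps outside the exodus
≤ 4 nights).

`simulate_light()` maps geometric solar elevation through a clipped
linear ramp (width 4°) anchored so light = threshold exactly at the true
EA — the slope is constant through the crossing, keeping interpolation
unbiased and the calibration problem well-posed. Noise is Gaussian jitter
of twilight times (a per-event clock shift of the curve near dawn/dusk),
plus optional daytime shading. Cave days record zero light all day.
`simulate_immersion()` makes in-cave periods fully dry, at-sea nights
rafting-wet (never zero, so an at-sea night cannot imitate a colony
visit), foraging days intermediate, and transit days mostly dry by day.

Isotopes: `feather_isotope_reference()` reproduces the published
population × feather × year means/SDs verbatim; `simulate_isotopes()`
draws bivariate normals from any such table. Those colony cells are
*mixtures* over destinations wherever a colony splits between regions, so
they cannot serve as region-conditional distributions. For birds with a
scheduled destination, `region_signatures()` therefore centres the
Atlantic group on the effectively-pure Atlantic colony cell (P6: 14.5,
−16.1 ‰) and the Mediterranean group between the hybrid colony's majority
cluster and the Yelkouan values (P6: 11.4, −17.5 ‰), with within-region
SDs (1.0, 0.5 ‰) consistent with the near-complete separability of
tracked birds' regions; mixing these signatures at a colony's mixture
approximately reproduces its published cell moments.

What the generator does **not** emulate: oceanographic habitat structure,
weather-driven shading statistics, energetic constraints, logger clock
drift, or behavioural state budgets at sea (dwell times are free
parameters, not estimates of real birds). Passing recovery tests
therefore demonstrates the *correctness of the inference rules under
their own assumptions*, not field accuracy on real loggers, where
shading, weather and behaviour violate the forward model in ways the
calibration constants only partly absorb.

## Problem sizes and tolerances used in validation

The test-suite and the acceptance script use: 50 stationary bird-days
(noiseless geolocation, tolerance 0.5° lat / 0.2° lon), a 30-day
calibration window (EA within ±0.25°, one grid step), 100 bird-years for
phenology (exact recovery at zero noise; laying within 1 day for ≥ 90 %
of birds at 4-min twilight jitter), 10⁴ Gaussian points for KDE checks
(mass 1 ± 10⁻³; 50 % contour mass ±0.02 and area within 5 % of the
analytic value for the smoothed Gaussian N(0, Σ̂ + H)), n = 1000 for the
bandwidth-to-normal-reference comparison (factor 2), ≤ 12-point fixtures
for exact brute-force oracles, and a 500-bird cohort at 0.8 Mediterranean
mixture for assignment recovery (99 % binomial interval). These sizes
were chosen to make each property sharply testable at interactive run
times.

## Known limitations

* Latitude near the equinoxes is reported missing/flagged rather than
  smoothed; no state-space or template-fit refinement is included.
* The spherical (not ellipsoidal) projection and haversine distances are
  adequate at geolocation error scales but not for GPS-grade data.
* The plug-in selector estimates ψᵣ with a scalar normal-scale pilot
  rather than per-functional optimal pilots; for strongly non-Gaussian
  targets the selector inherits normal-scale bias.
* Fisher-score ties are left unassigned rather than broken arbitrarily.
* The pair-based laying rule depends on both partners being logged and on
  clean alternation; noisy shift patterns fall back to the sex rules.
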