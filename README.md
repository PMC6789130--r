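# puffintrack

Year-round movement, phenology and migratory-connectivity analysis for
small burrow-nesting seabirds (Mediterranean *Puffinus* shearwaters)
tracked with archival light/immersion loggers and sampled for feather
stable isotopes.

Small shearwaters cannot carry GPS tags year-round, so their non-breeding
movements are inferred from three indirect data streams, each of which
this package processes end to end:

1. **Threshold light-level geolocation.** Sunrise and sunset are located
   where the logger's light trace crosses a fixed threshold (10 on the
   0–64 sensor scale). Longitude follows from the twilight midpoint (local
   solar noon, corrected by the equation of time); latitude solves the
   day-length equation
   `sin(EA) = sin(φ) sin(δ) + cos(φ) cos(δ) cos(H₀)`
   for φ, where δ is the solar declination, `H₀` the half-day hour angle,
   and EA the *sun elevation angle* — a per-device calibration constant
   recovered by grid search over a colony-centred calibration window
   (smallest median displacement from the colony; ties broken by fewer
   on-land points). Fixes are then flagged (never deleted) by the
   filtering cascade: equinox windows (10 d on the winter side, 5 d on the
   summer side of each equinox), plausible latitudes (30–52°N), and a
   55 km h⁻¹ speed rule.
2. **Immersion/light phenology.** Colony attendance of cave-nesting birds
   leaves unmistakable signatures: a *night visit* is ≥ 2 h of continuous
   dryness in the salt-water immersion trace; a *day visit* (incubation in
   the cave) is complete daytime darkness in the light trace. From these
   events the package infers non-breeding departure/return (last/first
   night visit around the longest absence), laying date (first ≥ 2-day
   day-visit run in males; first visit after the pre-laying exodus in
   females; alternating incubation shifts for pairs) and hatching (last
   day visit), with cohort-median imputation for failed loggers.
3. **Space use.** Retained fixes are projected to a Lambert conformal
   conic km grid; utilization distributions are estimated by fixed-kernel
   KDE with an unconstrained 2-stage plug-in bandwidth matrix, on 1×1 km
   cells, summarised as 25/50/70/90 % highest-density contours.
4. **Isotopic assignment.** Feather δ¹⁵N/δ¹³C (P1 = early, P6 = mid
   non-breeding season) separate Atlantic from Mediterranean foraging.
   The package ships Ward clustering, standard ellipse areas
   (SEAc = SEA·(n−1)/(n−2)), convex hulls, a two-group linear discriminant
   with Fisher classification functions, Wilks' Λ and leave-one-out
   cross-validation, lipid normalization for prey (C:N > 3.15) and trophic
   discrimination correction (+3.7 ‰ δ¹⁵N, +1.9 ‰ δ¹³C) — plus the
   published P1/P6 coefficient presets so untracked birds can be assigned
   without refitting.

Because raw tracking data of this kind are rarely archived, the package
includes a first-class, ground-truthed synthetic generator
(`simulate_schedule()`, `simulate_light()`, `simulate_immersion()`,
`simulate_isotopes()`) that produces annual-cycle behaviour schedules,
solar-geometry light curves with sensor clipping and twilight jitter,
state-dependent immersion traces, and isotope cohorts at the published
population parameters. Every analysis stage is validated by recovering
the generator's truth.

## Worked example

```r
library(puffintrack)

s <- simulate_schedule("Menorca", 2012, seed = 42, sex = "M")
s
#> <behavior_schedule> Men_2012_2369 (Menorca, M) 2012
#>   region: mediterranean | laying 2012-03-22 | hatch 2012-05-12 | depart 2012-06-26 | return 2012-09-28

light <- simulate_light(s, ea_true = -3.5, cadence = 5, seed = 1)
tw    <- detect_twilights(light, threshold = 10)
cal   <- calibrate_ea(tw, colony = s$colony,
                      window = c(s$laying_date + 20, s$hatch_date + 20))
cal
#> <calibration_result> EA = -3.50 deg (median displacement 22.8 km, 0 on land)

fixes <- filter_track(position_from_twilights(tw, ea = cal$ea))
sum(fixes$retained)  # 590 of 671 twilight fixes survive the cascade

imm    <- simulate_immersion(s, seed = 2)
nights <- night_intervals(s$days$date, s$colony[1], s$colony[2])
daysiv <- day_intervals(s$days$date, s$colony[1], s$colony[2])
phenology_summary(detect_night_visits(imm, nights),
                  detect_day_visits(light, daysiv), sex = "M")
#>   last_night_visit first_night_visit laying_date last_day_visit
#> 1       2012-06-26        2012-09-28  2012-03-22     2012-05-12
```

The recovered calibration equals the simulated device angle and all four
dates equal the generator's truth. Space use of the non-breeding fixes:

```r
nb <- fixes[fixes$retained & fixes$date > s$depart_date & fixes$date < s$return_date, ]
xy   <- project_points(nb)
H    <- plugin_bandwidth(xy)
grid <- kernel_density(xy, H, cell_size = 1)
contour_levels(grid)
#> <contour_set>
#>   25%: area 2936.0 km^2 (mass 0.250)
#>   50%: area 6834.0 km^2 (mass 0.500)
#>   70%: area 11423.0 km^2 (mass 0.700)
#>   90%: area 20697.0 km^2 (mass 0.900)
```

Assigning a bird from its P6 feather with the published classifier:

```r
classify(discriminant_preset("p6"), data.frame(d15N = 11.9, d13C = -17.3))
#>          region margin       D
#> 1 mediterranean 6.8966 -2.7276
```

A negative canonical score `D` (and the higher Mediterranean Fisher
score, margin 6.9) assigns this bird to the Mediterranean.

`run_pipeline(pipeline_config(seed = 7, out_dir = "out/run1"))` executes
simulate → geolocate → phenology → kde → isotopes in one call, writing
every interchange file (CSV/GeoJSON/ESRI ASCII/JSON) and a manifest with
per-stage record counts and file hashes.

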