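# stereostair

Stereocilia height reconstruction and hair-bundle morphometry from
SEM tilt series.

Cochlear hair cells sense sound with a staircase of stereocilia rows:
a tallest first row and shorter, mechanotransducing second and third
rows whose heights and tip shapes are actively maintained. Scanning
electron microscopy shows only *projections* of this geometry, so
quantifying the staircase means solving a small inverse problem per
stereocilium. `stereostair` is for researchers who measure hair
bundles from SEM tilt series and want the whole chain — projection
geometry, morphometric statistics, and group comparisons — as tested,
scriptable code.

## The model

For a stereocilium of height *h* inserted at tilt α to the
apical-surface normal and imaged at angle of view τ (stage tilt minus
the tilt at which stereocilia are parallel to the beam), the projected
length is

```
p = h·|sin τ|
```

Three inverse routes recover heights:

* **two views** of the same stereocilium at tilts separated by τ:
  p₁ = h·sin α, p₂ = h·sin(α + τ), solved in closed form for (h, α);
* **reference angle**: with the parallel angle known, h = p / |sin τ|;
* **front-view steps** for rows 2–3: the signed tip-to-tip projection
  s = (h₁ − hᵢ)·sin τ − (i−1)·d·cos(α + τ) is inverted for hᵢ given
  the row-1 height h₁, inter-row base spacing d, α and τ.

On top sit the morphometric quantities (staircase steps, heights
relative to row 1, power-law tip-diameter profiles, wedge-tip heights,
a tip-link classifier, supernumerary counts), Welch/Student group
comparisons with significance stars, and a seeded synthetic bundle
generator with a dose-dependent MET-blocker effect model
(`blocked_fraction(dose, ic50) = dose/(dose + ic50)`) that renders
noisy measurements through the same forward model, so every inverse
computation is verified by round trip. See the methods vignette
(`vignettes/stereostair-methods.Rmd`) for the full model description.

## Worked example

Simulate a control vs. benzamil (30 µM) cohort of outer-hair-cell
bundles, reconstruct every height from the rendered projections, and
compare groups:

```r
library(stereostair)

cfg <- experiment_config(
  bundle_spec = bundle_spec("OHC"),
  treatment   = treatment_spec("benzamil", dose_uM = 30),
  noise       = noise_spec(projection_noise_cv = 0.05),
  n_control = 10, n_treated = 10, seed = 20
)
res <- run_pipeline(cfg, "demo_out")
res$comparisons[, c("measure", "row", "mean_a", "mean_b", "p_value", "stars")]
```

```
[stereostair] simulate     800 projections, 3000 diameter measurements, 20 bundles
[stereostair] reconstruct  595/600 stereocilia resolved
[stereostair] morphometry  595 records
[stereostair] stats        11 contrasts

               measure  row n_a   mean_a n_b    mean_b  p_value stars
1            height_um    1 100 2.39e+00 100  2.38e+00 6.42e-01  n.s.
2            height_um    2 100 1.41e+00 100  9.53e-01 3.00e-26  ****
3            height_um    3 100 6.92e-01  95  3.13e-01 2.33e-37  ****
6  relative_height_pct    3 100 2.89e+01  95  1.32e+01 5.57e-37  ****
8    step_from_row1_um    2 100 9.83e-01 100  1.43e+00 2.22e-26  ****
10        tip_link_pct <NA>  10 9.15e+01  10  9.00e+01 5.12e-01  n.s.
11     n_supernumerary  OHC  10 1.02e+01  10  6.80e+00 1.81e-02     *
```

Reading the table: the tallest (non-transducing) row is statistically
unchanged by the blocker (n.s.), the transducing rows 2–3 are strongly
shortened (heights down, staircase steps up, ****), tip-link
percentages per cell are unaffected, and supernumerary stereocilia are
pruned faster under treatment. Five treated stereocilia whose noisy
step measurements implied non-positive heights were reported as
unresolved rather than silently dropped into the averages.

The same stages run from a shell via the thin wrapper
`inst/scripts/stereostair` (subcommands `simulate`, `reconstruct`,
`morphometry`, `stats`, `run-all`; YAML configs, CSV tables, JSON run
manifest).

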