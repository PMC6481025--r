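# ocutort

Quantitative, semi-automatic measurement of retinal and conjunctival vessel
tortuosity from ocular photographs — for researchers studying vascular
markers of systemic disease (the motivating case is Fabry disease, where
tortuous retinal and conjunctival vessels are a diagnostic clue), and for
anyone who needs an objective replacement for eyeballed tortuosity grades.

The pipeline mirrors clinical practice. An operator marks three points along
a vessel in an 8-bit TIFF/PNG photograph; the package

1. computes a multiscale Hessian **vesselness field** on the (inverted)
   green channel,
2. snaps the clicks to the vessel ridge and recovers the centerline between
   the outer marks as a **minimal-cost path**, smoothed and refined to
   sub-pixel accuracy, and
3. measures three turning-angle **tortuosity indices** on the trace,
   resampled at a fixed 5 px arc-length spacing with turning angles
   `theta_k = acos(v_{k-1}·v_k / |v_{k-1}||v_k|)`:
   * **SOAM** — sum of angles metric, `sum(theta_k) / L` (rad/px),
   * **PAD** — product of angle-distance, `sum(theta_k d_k) / L` with
     `d_k` the mean of the adjacent chord lengths,
   * **I2e** — triangular index, the mean arc-to-chord ratio
     `(|p_{k-e} p_k| + |p_k p_{k+e}|) / |p_{k-e} p_{k+e}|` over sliding
     point triplets (`e = 2` by default); 1 exactly on a straight line.

A cohort layer reproduces the small case-control analysis around the
measurements (exact / tie-corrected Mann–Whitney comparisons per site and
index, OLS regressions on age and systemic covariates, demographic
summaries, α = 0.05, no multiplicity correction), and a synthetic-data layer
generates vessel images and two-group cohorts with known ground-truth
tortuosity for validation and power studies.

## Worked example

Simulate one vessel image, trace it from three seed points, and measure it:

```r
library(ocutort)

cl  <- gen_centerline(curve_params("sinusoid", span_px = 400,
                                   amplitude_px = 10, wavelength_px = 100,
                                   sample_spacing_px = 2))
cl  <- transform_polyline(cl, dx = 20, dy = 40)
img <- rasterize_vessel(cl, raster_params(image_size = c(100, 440)))

seeds <- unclass(cl)[c(1, ceiling(nrow(cl) / 2), nrow(cl)), ]  # 0/50/100%
trace <- trace_segment(img, seeds)
compute_tortuosity(trace, site = "retina")
#> Tortuosity of one vessel segment
#>   segment: NA / NA / retina / NA
#>   arc length: 423.2 px (87 samples at 5 px)
#>   SOAM: 0.02079 rad/px   PAD: 0.10343   I2e: 1.00712
```

SOAM says the trace turns by ~0.021 rad per pixel of arc; PAD is SOAM
weighted by the 5 px sampling distance; I2e exceeds 1 by the mean bulge of
the curve over its local chords. The simulated vessel's true metrics (from
`compute_tortuosity(cl)`) agree within about 1%.

Simulate and analyse a whole case-control study (11 + 11 subjects, both
eyes, 5 retinal + 12 conjunctival segments each, with a 1.6× amplitude
effect injected at the retina and nasal conjunctiva):

```r
co      <- gen_cohort(cohort_params(n_per_group = 11, rng_seed = 42))
metrics <- tortuosity_table(co)
run_study(metrics, co$subjects)
#> Case-control vessel tortuosity study
#>   control: n = 11 (5M/6F), age 54.2 +/- 13.4 [34.8-70.1]
#>   FD: n = 11 (5M/6F), age 55.4 +/- 10.4 [35.5-68.4]
#>   45 rank tests, 33 regressions, 30 skipped
#>   significant at alpha = 0.05:
#>     FD_vs_control    conj_nasal     soam  p = 0.0008113
#>     FD_vs_control    conj_nasal     pad   p = 0.0006388
#>     FD_vs_control    conj_nasal     i2e   p = 0.000501
#>     FD_vs_control    retina         soam  p = 0.0008113
#>     FD_vs_control    retina         pad   p = 0.001026
#>     FD_vs_control    retina         i2e   p = 0.0006388
```

Group differences surface exactly where the effect was injected — retina and
nasal conjunctiva — and nowhere else; comparisons that cannot run on
simulated data (e.g. regressions on GFR, which the simulator does not
generate) are listed in the report's `skipped` table with reasons.
`run_pipeline(pipeline_config(...))` wraps the same steps end-to-end and
writes `traces.csv`, `metrics.csv`, `report.json` and `tests.csv`;
`inst/cli/ocutort.R` exposes `simulate` / `trace` / `metrics` / `compare` /
`report` subcommands for shell use. The packaged clinical table of the
11-patient case series is available as `fabry_table1()`.

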