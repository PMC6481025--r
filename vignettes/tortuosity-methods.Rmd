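---
title: "Measuring ocular vessel tortuosity: models, algorithms and design choices"
author: "ocutort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular vessel tortuosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocutort)
```

## The problem

Increased tortuosity of retinal and bulbar-conjunctival vessels is a clinical
marker in several systemic conditions, most prominently Fabry disease, an
X-linked lysosomal storage disorder in which glycosphingolipid accumulates in
the vascular endothelium. Clinicians grade this tortuosity by eye; `ocutort`
implements an objective, semi-automatic measurement pipeline: an operator
marks three points along a vessel in a fundus or conjunctival photograph, the
software recovers the vessel centerline between the outer marks, and three
turning-angle indices quantify how twisted the recovered curve is. A cohort
layer then compares cases against controls, and a simulation layer generates
synthetic vessels and cohorts with known ground truth so that every stage of
the pipeline can be validated quantitatively.

## The three tortuosity indices

All three indices operate on a centerline polyline \(p_1, \dots, p_n\)
(pixel coordinates) with chord vectors \(v_k = p_{k+1} - p_k\), arc length
\(L = \sum_k |v_k|\), and turning angles
\(\theta_k = \arccos\!\big(v_{k-1} \cdot v_k / (|v_{k-1}||v_k|)\big)\)
at interior vertices (the `acos` argument is clamped to \([-1, 1]\) to absorb
floating-point drift):

* **SOAM** (sum of angles metric): \(\sum_k \theta_k / L\), the total
  absolute turning per unit arc length, in radians per pixel. On a circular
  arc of radius \(r\) it converges to the curvature \(1/r\).
* **PAD** (product of angle-distance):
  \(\sum_k \theta_k d_k / L\) with \(d_k = (|v_{k-1}| + |v_k|)/2\), each
  angle weighted by its local inter-sample distance. Under exactly uniform
  spacing \(s\), \( \mathrm{PAD} = s \cdot \mathrm{SOAM} \) — an identity
  the test suite asserts.
* **I2e** (triangular index): the mean over admissible \(k\) of
  \((|p_{k-e} - p_k| + |p_k - p_{k+e}|) / |p_{k-e} - p_{k+e}|\), a sliding
  inscribed-triangle arc-to-chord ratio with step \(e\) (default 2). Each
  term is \(\ge 1\) by the triangle inequality, with equality exactly on a
  straight line. On a circle sampled at arc step \(\Delta s\),
  \(\mathrm{I2e} = 1/\cos(e\,\Delta s / 2r)\) exactly.

These formulas are this package's normative definitions. The precise
normalizations used by the original analysis software (including the meaning
of the "2" and "e" in I2e, and whether angles were in degrees or radians)
are not public; the definitions above follow the standard constructions in
the vessel-morphometry literature and are frozen here so that every number
the package produces is reproducible from first principles.

### Why resampling is part of the metric

Turning-angle statistics depend on how densely the curve is sampled: a
staircase sampled every pixel turns much more often than the same curve
sampled every 5 px. `compute_tortuosity()` therefore resamples every input
at a fixed arc-length spacing (`resample_spacing_px`, default 5 px) before
measuring, making values comparable across segments whose traced lengths
range from 250 to 500 px. Resampling anchors its interior sample positions
at the curve midpoint, so a remainder (when the length is not a multiple of
the spacing) is split between the two end intervals; this makes resampling
commute with reversing the curve, and hence all three indices are exactly
invariant under reversal — an invariant the tests check to 1e-9 together
with rigid-motion invariance and the scaling law (SOAM scales as \(1/s\),
PAD and I2e are scale-free when the spacing is scaled along).

## Semi-automatic centerline tracing

The tracing contract mirrors clinical practice: the operator clicks three
locations along the vessel's course, and the software does the rest.

1. **Vesselness field.** RGB input is reduced to the green channel (the
   highest-contrast channel in ocular photography), inverted so vessels
   become bright, and filtered with a multiscale Hessian ridge detector:
   at each scale \(\sigma \in \{1.5, 2.5, 3.5\}\) px the scale-normalized
   ridge strength \(\sigma^2 \max(-\lambda_2, 0)\) is computed from the
   smaller Hessian eigenvalue \(\lambda_2\), maximized over scales, and
   min–max normalized to \([0, 1]\).
2. **Click correction.** Each seed is moved to the vesselness maximum
   within `snap_radius` (default 5 px). This is the step that makes the
   pipeline robust to click placement: two observers clicking within a few
   pixels of each other land on the same ridge point, so their traces —
   and tortuosity values — coincide. Endpoints of the returned trace are
   therefore the *refined* seeds, not the raw clicks.
3. **Minimal-cost path.** An 8-connected lattice graph over the image
   carries edge weights \(|u - v| \cdot (\varepsilon + 1 - \bar V_{uv})\),
   where \(\bar V_{uv}\) is the mean vesselness of the two endpoint pixels
   and \(\varepsilon = 0.05\) keeps all pixels reachable. The shortest path
   (Dijkstra, via `igraph`) is computed seed1→seed2 and seed2→seed3 and
   concatenated. Each half is searched in a canonical node order so that
   tie-breaking between equal-cost staircase paths cannot depend on the
   direction of tracing; reversing the seed order provably reverses the
   polyline and leaves all metrics unchanged.
4. **Smoothing and sub-pixel refinement.** The grid path is smoothed with
   a centered moving average (window 5) and then re-centered on the vessel
   by two sub-pixel passes: at each point, the inverted intensity (lightly
   smoothed, \(\sigma = 1\) px) is sampled at offsets \(-1, 0, +1\) px
   along the local normal and the point is moved to the vertex of the
   fitted parabola. Without this, the half-pixel quantization of a grid
   path adds a turning-noise floor of roughly 0.002–0.003 rad/px, which is
   a substantial relative error precisely for the gently curved vessels a
   control cohort contributes. The refinement field is deliberately only
   lightly smoothed: heavy smoothing displaces the ridge of a curved tube
   toward its center of curvature by about \(\sigma^2 \kappa\), biasing
   tortuosity downward.

`validate_segment()` then checks the trace against the acquisition
protocol — arc length within the site window (350–500 px retina, 250–400 px
conjunctival sectors), no self-intersection, adequate ridge support — and
warns rather than fails, leaving the decision with the operator.

Whether the original software traced only between the outer seeds or
extrapolated beyond them is unknown; this implementation traces strictly
between the refined outer seeds.

## Synthetic vessels and cohorts

Real patient images from tortuosity studies are not publicly deposited, so
the package ships a generator that plays two roles: ground truth for
validating the tracer and metrics, and a cohort simulator for studying the
statistical pipeline's operating characteristics.

* **Curves.** Lines, circular arcs (known curvature → known SOAM),
  sinusoids, and seeded random-curvature walks. The cohort model uses
  sinusoids because, at fixed wavelength, amplitude is a single monotone
  ground-truth axis that drives all three indices together.
* **Images.** A centerline is rendered with a Gaussian cross-section
  (full width at half depth `vessel_width_px`, default 6 px) on a uniform
  background, vessels darker than background as in fundus photography,
  using exact point-to-segment distances, then quantized to 8 bits
  (1536 × 1024 default frame, matching the acquisition format). Optional
  additive Gaussian noise. Not modelled: branching trees, the optic disc
  and macula, illumination gradients — so tests passing on these images
  validate the geometry pipeline, not robustness to real-world clutter.
* **Cohorts.** Two groups of `n_per_group` subjects (default 11 + 11, the
  study scale), sexes balanced 5M/6F at n = 11, ages uniform on 30–71
  years. Each subject carries a latent lognormal amplitude factor
  (`subject_sd_log = 0.3`) shared by both eyes; each segment (5 retinal +
  3 per conjunctival sector, per eye) draws an extra lognormal perturbation
  (`segment_sd_log = 0.15`), a random phase, and a chord length uniform in
  its site window. The case group's amplitude is multiplied by
  `effect_multiplier[site]`, default 1.6 at the retina and nasal
  conjunctiva and 1.0 elsewhere — an effect concentrated at the clinically
  reported sites and sized to be detectable but not trivial at n = 11.
  No per-group tortuosity means or SDs are published for the original
  cohort, so these parameters are calibrated to detectability, not to the
  study's (unknown) effect sizes.

## Cohort statistics

The analysis layer reproduces a small case-control design at \(\alpha =
0.05\) with no multiple-testing correction (every test compares exactly two
groups):

* **Unit of analysis.** Segment values are averaged within eye, then across
  the two eyes, giving one value per subject × site × metric. Averaging
  before testing avoids treating two correlated eyes as independent
  observations; a per-eye mode is available (`stats_config(aggregation =
  "eye")`) because the original clustering treatment is unstated.
* **Mann–Whitney.** U from midrank summation. With \(n_1 + n_2 \le 16\)
  and no ties the two-sided p-value is exact (twice the smaller tail of
  the exact null distribution); otherwise a normal approximation with tie
  correction and continuity correction is used. The threshold sits just
  above the study's 11 + 11 comparison, and the suite verifies both that
  the exact branch equals a full enumeration oracle for all no-tie
  configurations with \(n_1 + n_2 \le 10\) and that the two branches agree
  within their worst-case analytic discrepancy (0.011 at n = 8 + 8).
* **Regressions.** OLS of each index on age (within each group) and on the
  systemic covariates GFR and MWT (within cases; an `mssi` column is
  accepted when present), plus, per index, the regression of the mean
  conjunctival value on the retinal value across subjects. Any comparison
  that cannot run (absent covariate, fewer than 3 complete pairs, constant
  covariate) is recorded in the report's `skipped` table with a reason.
* **MWT vs IVSD.** The interventricular septum appears under both names in
  the source material; the package treats them as one covariate (`mwt`).

## Operating characteristics, problem sizes, and what the tests show

The suite validates the pipeline's statistics by simulation, with sizes
chosen to keep a full run in minutes on one CPU:

* **Type-I error.** 1000 null cohorts (effect multiplier 1, retina only,
  11 + 11 subjects, 2 eyes × 5 segments); each replicate runs centerline
  generation → metrics → aggregation → Mann–Whitney on SOAM. The rejection
  rate at \(\alpha = 0.05\) must fall in the 99% binomial interval around
  0.05. Rasterization and re-tracing are excluded from these replicates —
  the tracer's fidelity is established separately (below), and its
  sub-pixel errors are orders of magnitude below the between-subject
  variation that drives the test statistic.
* **Power.** Effect multipliers {1, 1.5, 2, 3} at 500 replicates each with
  common random numbers across arms (replicate *i* reuses the same seed in
  every arm, so the power curve is a paired comparison); the rejection
  rate must be non-decreasing.
* **Tracing fidelity.** 20 random noiseless vessels (amplitude 5–14 px,
  wavelength 80–140 px, span 260–450 px): mean deviation from ground truth
  ≤ 1 px, and traced metrics within 2% of the true centerline's metrics
  over the traced extent (between the refined outer seeds — comparing
  curves over different extents would conflate end truncation with tracing
  error).
* **Repeatability.** The seed-jitter harness re-traces each vessel 20
  times with every seed coordinate perturbed by ±3 px; the coefficient of
  variation of each metric stays below 2%, the desk-scale analog of an
  intra/inter-observer repeatability study. `scripts/acceptance.R`
  recomputes this benchmark from scratch on 10 images.

What these simulations do *not* show: performance on real photographs with
branching vessels, uneven illumination, or pathology other than tortuosity.
The synthetic model isolates the quantities the pipeline is supposed to
measure; field performance additionally depends on image quality and
operator segment selection, which are outside the model.

## Numerical and design notes

* Coordinates are 0-based pixel centers, x rightward, y downward.
* Degenerate inputs: a straight line yields exactly (SOAM, PAD, I2e) =
  (0, 0, 1); a curve folding back on itself makes the I2e base vanish and
  raises an error; polylines with fewer than `min_points` (10) resampled
  points are rejected; a constant image yields an all-zero vesselness map
  with a warning, and tracing on it still returns a (straight) path since
  the cost floor \(\varepsilon\) keeps the graph connected.
* `run_pipeline()` measures simulated centerlines directly by default;
  `trace_images = TRUE` additionally rasterizes and re-traces every
  segment, exercising the full imaging path at ~1 s/segment.
* Arteries and veins are not distinguished, matching the source protocol.
* Reports exclude timestamps so identical seeds give byte-identical output.
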