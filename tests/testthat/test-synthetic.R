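test_that("curve parameters are validated", {
  expect_error(curve_params("line", span_px = 0), "span_px")
  expect_error(curve_params("sinusoid", span_px = 100, amplitude_px = -1),
               "amplitude_px")
  expect_error(curve_params("sinusoid", span_px = 100, wavelength_px = 0),
               "wavelength_px")
  expect_error(curve_params("arc", span_px = 100, amplitude_px = 0),
               "radius")
  expect_error(curve_params("spiral", span_px = 100))
})

test_that("straight centerlines are exactly degenerate for all metrics", {
  line <- gen_centerline(curve_params("line", span_px = 400,
                                      sample_spacing_px = 5))
  expect_equal(nrow(line), 81L)
  expect_true(all(unclass(line)[, 2] == 0))
  r <- compute_tortuosity(line)
  expect_identical(c(r$soam, r$pad, r$i2e), c(0, 0, 1))
})

test_that("arc centerlines carry their analytic curvature", {
  arc <- gen_centerline(curve_params("arc", span_px = 400,
                                     amplitude_px = 200,
                                     sample_spacing_px = 2))
  expect_equal(arc_length(arc), 400, tolerance = 1e-3)
  expect_lt(abs(soam(arc) - 1 / 200) / (1 / 200), 0.01)
  # all points at radius 200 from the center (0, 200)
  m <- unclass(arc)
  expect_equal(sqrt(m[, 1]^2 + (m[, 2] - 200)^2), rep(200, nrow(m)),
               tolerance = 1e-9)
})

test_that("sinusoid spans its chord and is sampled near-uniformly", {
  p <- gen_centerline(curve_params("sinusoid", span_px = 400,
                                   amplitude_px = 15, wavelength_px = 100,
                                   sample_spacing_px = 2))
  m <- unclass(p)
  expect_equal(unname(m[1, 1]), 0)
  expect_equal(unname(m[nrow(m), 1]), 400)
  # spacing is uniform in arc length along the dense interpolant; Euclidean
  # steps are shorter by at most the chord-vs-arc curvature correction
  steps <- sqrt(rowSums(diff(m)^2))
  interior <- steps[2:(length(steps) - 1)]
  expect_true(all(abs(interior - 2) < 0.01))
  expect_true(all(steps <= 2 + 1e-6))
  expect_false(self_intersects(p))
})

test_that("random-curvature curves are reproducible under their seed", {
  a <- gen_centerline(curve_params("random_curvature", span_px = 300,
                                   curvature_sd = 0.1, rng_seed = 99))
  b <- gen_centerline(curve_params("random_curvature", span_px = 300,
                                   curvature_sd = 0.1, rng_seed = 99))
  expect_identical(unclass(a), unclass(b))
  d <- gen_centerline(curve_params("random_curvature", span_px = 300,
                                   curvature_sd = 0.1, rng_seed = 100))
  expect_false(identical(unclass(a), unclass(d)))
})

test_that("cohort bookkeeping matches the acquisition protocol", {
  co <- gen_cohort(cohort_params(n_per_group = 11, rng_seed = 1))
  expect_equal(nrow(co$subjects), 22L)
  expect_equal(sum(co$subjects$group == "FD"), 11L)
  # per subject: 2 eyes x (5 retina + 4 x 3 conjunctival) = 34 segments
  expect_equal(length(co$traces), 22L * 34L)
  idx <- as.data.frame(co)
  per_site <- table(idx$site) / (22L * 2L)
  expect_equal(unname(per_site[["retina"]]), 5)
  expect_equal(unname(per_site[["conj_nasal"]]), 3)
  # sexes balanced as in the study design: 5 M / 6 F per group
  expect_equal(sum(co$subjects$sex == "M" & co$subjects$group == "FD"), 5L)
  expect_equal(sum(co$subjects$sex == "F" & co$subjects$group == "FD"), 6L)
  # chord lengths inside the per-site windows
  ret <- idx$span_px[idx$site == "retina"]
  expect_true(all(ret >= 350 & ret <= 500))
  conj <- idx$span_px[idx$site != "retina"]
  expect_true(all(conj >= 250 & conj <= 400))
})

test_that("cohorts are bitwise reproducible under a fixed seed", {
  a <- gen_cohort(cohort_params(n_per_group = 3, sites = "retina",
                                rng_seed = 5))
  b <- gen_cohort(cohort_params(n_per_group = 3, sites = "retina",
                                rng_seed = 5))
  expect_identical(a$subjects, b$subjects)
  expect_identical(lapply(a$traces, function(t) unclass(t$polyline)),
                   lapply(b$traces, function(t) unclass(t$polyline)))
})

test_that("cohort amplitudes recover the injected effect multiplier", {
  cp <- cohort_params(n_per_group = 500, sites = c("retina", "conj_nasal",
                                                   "conj_temporal"),
                      segments_per_site = c(retina = 1, conj_nasal = 1,
                                            conj_temporal = 1),
                      effect_multiplier = c(retina = 1.6, conj_nasal = 1.6,
                                            conj_temporal = 1),
                      rng_seed = 20)
  idx <- as.data.frame(gen_cohort(cp))
  for (site in c("retina", "conj_nasal", "conj_temporal")) {
    fd <- mean(idx$amplitude_px[idx$site == site &
                                  grepl("^FD", idx$subject_id)])
    ct <- mean(idx$amplitude_px[idx$site == site &
                                  grepl("^C", idx$subject_id)])
    target <- cp$effect_multiplier[[site]]
    expect_lt(abs(fd / ct - target) / target, 0.05)
  }
})
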