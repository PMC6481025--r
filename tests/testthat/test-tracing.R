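test_that("vesselness peaks on the centerline at every cross-section", {
  fix <- make_vessel_fixture(amplitude_px = 10, span_px = 240,
                             sample_spacing_px = 1)
  V <- vesselness_map(fix$image)
  expect_true(all(V >= 0 & V <= 1))
  truth <- unclass(fix$truth)
  xs <- seq(round(min(truth[, 1])) + 10, round(max(truth[, 1])) - 10, by = 2)
  for (x in xs) {
    ypeak <- which.max(V[, x + 1]) - 1L
    ytrue <- truth[which.min(abs(truth[, 1] - x)), 2]
    expect_lte(abs(ypeak - ytrue), 1 + 1e-9)
  }
})

test_that("a constant image yields an all-zero map with a warning", {
  flat <- vessel_image(matrix(128, 32, 48))
  expect_warning(V <- vesselness_map(flat), "constant")
  expect_true(all(V == 0))
})

test_that("vesselness along the centerline is rotation-robust", {
  base <- make_vessel_fixture(amplitude_px = 8, span_px = 200,
                              sample_spacing_px = 1)
  ridge_mean <- function(fixlike) {
    V <- vesselness_map(fixlike$image)
    m <- round(unclass(fixlike$truth))
    interior <- m[10:(nrow(m) - 10), , drop = FALSE]
    mean(V[cbind(interior[, 2] + 1, interior[, 1] + 1)])
  }
  # rebuild the same vessel rotated by 37 degrees
  rot <- transform_polyline(base$truth, angle = 37 * pi / 180)
  mr <- unclass(rot)
  mr[, 1] <- mr[, 1] - min(mr[, 1]) + 20
  mr[, 2] <- mr[, 2] - min(mr[, 2]) + 20
  rot <- as_polyline(mr)
  h <- ceiling(max(mr[, 2])) + 20; w <- ceiling(max(mr[, 1])) + 20
  rimg <- rasterize_vessel(rot, raster_params(image_size = c(h, w)))
  v0 <- ridge_mean(base)
  v1 <- ridge_mean(list(image = rimg, truth = rot))
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("traced centerlines stay within a pixel of the ground truth", {
  fix <- make_vessel_fixture(amplitude_px = 10)
  tr <- vessel_tracer(fix$image)
  path <- trace_segment(tr, fix$seeds)
  dense <- unclass(resample_polyline(fix$truth, 0.25))
  dev <- dist_to_curve(unclass(path), dense)
  expect_lt(mean(dev), 1)
  expect_lt(max(dev), 2)
})

test_that("tracing a straight vessel returns a near-zero SOAM", {
  m <- cbind(c(20, 220, 420), c(32, 32, 32))
  line <- as_polyline(m[c(1, 3), ])
  img <- rasterize_vessel(line, raster_params(image_size = c(64, 440)))
  path <- trace_segment(img, m)
  expect_lte(compute_tortuosity(path)$soam, 0.002)
})

test_that("reversing the seed order leaves the metrics unchanged", {
  fix <- make_vessel_fixture(amplitude_px = 12)
  tr <- vessel_tracer(fix$image)
  fwd <- trace_segment(tr, fix$seeds)
  bwd <- trace_segment(tr, fix$seeds[3:1, ])
  a <- compute_tortuosity(fwd); b <- compute_tortuosity(bwd)
  expect_equal(b$soam, a$soam, tolerance = 1e-9)
  expect_equal(b$pad, a$pad, tolerance = 1e-9)
  expect_equal(b$i2e, a$i2e, tolerance = 1e-9)
  # and the traced arc length dominates the seed1-seed3 distance
  expect_gte(arc_length(fwd),
             sqrt(sum((fix$seeds[3, ] - fix$seeds[1, ])^2)) - 1e-9)
})

test_that("tracing fidelity holds across many random noiseless vessels", {
  set.seed(31)
  devs <- replicate(20, {
    fix <- make_vessel_fixture(amplitude_px = runif(1, 4, 14),
                               wavelength_px = runif(1, 80, 140),
                               span_px = runif(1, 250, 450),
                               phase = runif(1, 0, 2 * pi))
    path <- trace_segment(fix$image, fix$seeds)
    dense <- unclass(resample_polyline(fix$truth, 0.25))
    dev <- dist_to_curve(unclass(path), dense)
    c(mean(dev), max(dev))
  })
  expect_lt(max(devs[1, ]), 1)   # mean deviation <= 1 px on every vessel
  expect_lt(max(devs[2, ]), 2)   # worst-case deviation <= 2 px
})

test_that("seed validation enforces the triplet contract", {
  fix <- make_vessel_fixture(span_px = 200)
  tr <- vessel_tracer(fix$image)
  expect_error(trace_segment(tr, cbind(c(-5, 50, 100), c(10, 10, 10))),
               "bounds")
  s <- fix$seeds; s[2, ] <- s[1, ]
  expect_error(trace_segment(tr, s), "distinct|10 px")
  s <- fix$seeds; s[2, ] <- s[1, ] + c(4, 0)
  expect_error(trace_segment(tr, s), "10 px")
  expect_error(trace_segment(tr, c(1, 2, 3)), "three")
})

test_that("background seeds still trace but validation warns", {
  # seeds far enough from the vessel that even the minimal-cost path has no
  # incentive to detour onto the ridge
  fix <- make_vessel_fixture(amplitude_px = 6, span_px = 200, margin = 120)
  far <- cbind(c(120, 220, 320), c(8, 8, 8))
  tr <- vessel_tracer(fix$image)
  path <- trace_segment(tr, far)
  expect_s3_class(path, "polyline")
  msgs <- suppressWarnings(validate_segment(path, segment_spec("retina"),
                                            tr))
  expect_true(any(grepl("vesselness", msgs)))
})

test_that("validate_segment applies the per-site length windows", {
  mk <- function(len) as_polyline(cbind(seq(0, len, 5), 0))
  expect_length(suppressWarnings(
    validate_segment(mk(420), segment_spec("retina"))), 0L)
  expect_warning(validate_segment(mk(300), segment_spec("retina")),
                 "arc length")
  expect_length(suppressWarnings(
    validate_segment(mk(300), segment_spec("conj_nasal"))), 0L)
  expect_warning(validate_segment(mk(450), segment_spec("conj_nasal")),
                 "arc length")
  crossing <- as_polyline(cbind(c(0, 150, 150, 0), c(0, 5, 0, 5)))
  expect_warning(validate_segment(crossing, segment_spec("conj_nasal")),
                 "self-intersecting")
})

test_that("seed-jitter repeats stay tightly reproducible", {
  fix <- make_vessel_fixture(amplitude_px = 10)
  tr <- vessel_tracer(fix$image)
  res <- seed_jitter_cv(tr, fix$seeds, n_repeats = 10, rng_seed = 8)
  expect_true(all(res$cv < 0.02))
  expect_equal(dim(res$values), c(10L, 3L))
})
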