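# Shared fixtures built in code at test time.

# A sinusoidal vessel placed in a compact noiseless image, with its
# ground-truth centerline and canonical 0/50/100% seed triplet.
make_vessel_fixture <- function(amplitude_px = 10, wavelength_px = 100,
                                span_px = 400, phase = 0,
                                sample_spacing_px = 2, margin = 20,
                                noise_sd = 0, noise_seed = NULL,
                                quantize = TRUE) {
  cl <- gen_centerline(curve_params("sinusoid", span_px = span_px,
                                    amplitude_px = amplitude_px,
                                    wavelength_px = wavelength_px,
                                    sample_spacing_px = sample_spacing_px,
                                    phase = phase))
  m <- unclass(cl)
  m[, 1] <- m[, 1] - min(m[, 1]) + margin
  m[, 2] <- m[, 2] - min(m[, 2]) + margin
  h <- ceiling(max(m[, 2])) + margin
  w <- ceiling(max(m[, 1])) + margin
  truth <- as_polyline(m)
  img <- rasterize_vessel(truth,
                          raster_params(image_size = c(h, w),
                                        noise_sd = noise_sd),
                          noise_seed = noise_seed, quantize = quantize)
  n <- nrow(m)
  list(truth = truth, image = img,
       seeds = m[c(1, ceiling(n / 2), n), , drop = FALSE])
}
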