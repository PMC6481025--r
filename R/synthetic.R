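#' Parametric centerline families
#'
#' `curve_params()` bundles the parameters of a synthetic vessel centerline;
#' `gen_centerline()` realizes it as a [polyline][as_polyline] sampled at
#' approximately uniform arc-length spacing. Four families are available:
#'
#' * `line` — a straight chord of length `span_px`.
#' * `arc` — a circular arc of radius `amplitude_px` and arc length
#'   `span_px`; its curvature `1/amplitude_px` is the analytic ground truth
#'   for SOAM.
#' * `sinusoid` — `y = amplitude_px * sin(2*pi*x/wavelength_px + phase)` for
#'   `x` in `[0, span_px]`; at fixed wavelength the amplitude is a monotone
#'   one-parameter tortuosity axis driving all three indices, which is why
#'   the cohort simulator uses this family.
#' * `random_curvature` — a seeded random walk in heading with per-step
#'   turning angles `N(0, curvature_sd)`, step length `sample_spacing_px`.
#'
#' @param family one of `"line"`, `"arc"`, `"sinusoid"`,
#'   `"random_curvature"`.
#' @param span_px chord length in pixels (`line`, `sinusoid`), or arc length
#'   (`arc`, `random_curvature`). Must be positive.
#' @param amplitude_px peak deviation from the chord (`sinusoid`) or circle
#'   radius (`arc`); `>= 0`.
#' @param wavelength_px sinusoid period in pixels (> 0).
#' @param curvature_sd per-step turning-angle SD in radians
#'   (`random_curvature`).
#' @param sample_spacing_px arc-length step of the returned polyline (> 0).
#' @param phase sinusoid phase offset, radians.
#' @param rng_seed integer seed (`random_curvature` only); identical
#'   parameters and seed give an identical curve.
#' @return `curve_params()`: an object of class `curve_params`;
#'   `gen_centerline()`: a `polyline` starting at the origin with its chord
#'   along the +x axis.
#' @examples
#' p <- gen_centerline(curve_params("sinusoid", span_px = 400,
#'                                  amplitude_px = 10, wavelength_px = 100))
#' compute_tortuosity(p)
#' @export
curve_params <- function(family = c("line", "arc", "sinusoid",
                                    "random_curvature"),
                         span_px, amplitude_px = 0, wavelength_px = 100,
                         curvature_sd = 0.05, sample_spacing_px = 2,
                         phase = 0, rng_seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(span_px) || span_px <= 0) stop("span_px must be positive")
  if (amplitude_px < 0) stop("amplitude_px must be >= 0")
  if (wavelength_px <= 0) stop("wavelength_px must be positive")
  if (sample_spacing_px <= 0) stop("sample_spacing_px must be positive")
  if (curvature_sd < 0) stop("curvature_sd must be >= 0")
  if (family == "arc" && amplitude_px <= 0)
    stop("an arc needs a positive radius (amplitude_px)")
  structure(list(family = family, span_px = span_px,
                 amplitude_px = amplitude_px, wavelength_px = wavelength_px,
                 curvature_sd = curvature_sd,
                 sample_spacing_px = sample_spacing_px, phase = phase,
                 rng_seed = rng_seed),
            class = "curve_params")
}

#' @rdname curve_params
#' @param params a `curve_params` object.
#' @export
gen_centerline <- function(params) {
  stopifnot(inherits(params, "curve_params"))
  sp <- params$sample_spacing_px
  span <- params$span_px
  m <- switch(params$family,
    line = {
      x <- seq(0, span, by = sp)
      if (span - x[length(x)] > 1e-9) x <- c(x, span)
      cbind(x, 0)
    },
    arc = {
      r <- params$amplitude_px
      t <- seq(0, span / r, by = sp / r)
      if (span / r - t[length(t)] > 1e-12) t <- c(t, span / r)
      cbind(r * sin(t), r * (1 - cos(t)))
    },
    sinusoid = {
      if (params$amplitude_px == 0) {
        x <- seq(0, span, by = sp)
        if (span - x[length(x)] > 1e-9) x <- c(x, span)
        cbind(x, 0)
      } else {
        dense <- min(sp, params$wavelength_px / 50)
        x <- seq(0, span, by = dense)
        if (span - x[length(x)] > 1e-9) x <- c(x, span)
        y <- params$amplitude_px *
          sin(2 * pi * x / params$wavelength_px + params$phase)
        y <- y - y[1L]  # start on the chord axis
        poly_mat(resample_polyline(cbind(x, y), sp))
      }
    },
    random_curvature = with_seed(params$rng_seed, {
      n <- max(2L, ceiling(span / sp))
      turn <- stats::rnorm(n - 1L, 0, params$curvature_sd)
      heading <- cumsum(c(0, turn))
      cbind(c(0, cumsum(sp * cos(heading))),
            c(0, cumsum(sp * sin(heading))))
    })
  )
  as_polyline(m)
}

#' Rasterization parameters
#'
#' Controls how a centerline is rendered into a vessel-like image. The vessel
#' has a Gaussian cross-section: pixel intensity is
#' `background_level - vessel_contrast * exp(-d^2 / (2 * sigma^2)) + noise`,
#' where `d` is the exact Euclidean distance from the pixel center to the
#' centerline and `sigma` is derived from `vessel_width_px`, the full width
#' at half depth (`sigma = width / (2*sqrt(2*log(2)))`). Vessels are darker
#' than the background, as in fundus and conjunctival photography; the single
#' synthesized channel plays the role of the green channel. Intensities are
#' clipped to `[0, 255]` and rounded to 8-bit levels.
#'
#' @param image_size `(height, width)` in pixels; defaults to the
#'   1024 x 1536 acquisition format.
#' @param vessel_width_px full width at half depth of the vessel profile.
#' @param vessel_contrast intensity drop at the centerline (0-255); must not
#'   exceed `background_level`.
#' @param background_level background intensity (0-255).
#' @param noise_sd additive Gaussian noise SD in intensity units (0 = none).
#' @param profile cross-section profile; only `"gaussian"` is defined.
#' @return an object of class `raster_params`.
#' @export
raster_params <- function(image_size = c(1024, 1536), vessel_width_px = 6,
                          vessel_contrast = 120, background_level = 200,
                          noise_sd = 0, profile = "gaussian") {
  profile <- match.arg(profile, "gaussian")
  if (length(image_size) != 2L || any(image_size < 8))
    stop("image_size must be (height, width), each >= 8 px")
  if (background_level < 0 || background_level > 255)
    stop("background_level must be in [0, 255]")
  if (vessel_contrast < 0 || vessel_contrast > background_level)
    stop("vessel_contrast must be in [0, background_level]")
  if (vessel_width_px <= 0) stop("vessel_width_px must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 vessel_width_px = vessel_width_px,
                 vessel_contrast = vessel_contrast,
                 background_level = background_level, noise_sd = noise_sd,
                 profile = profile),
            class = "raster_params")
}

#' Construct a vessel image object
#'
#' A `vessel_image` holds an 8-bit raster (grayscale matrix or
#' `height x width x 3` RGB array, values 0-255) plus acquisition metadata.
#' Pixel `(x, y)` in 0-based pixel-center coordinates is stored at
#' `pixels[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix or 3-channel array with values in `[0, 255]`.
#' @param site,eye optional ocular site / eye labels.
#' @param bit_depth bits per sample (8 for everything this package writes).
#' @return an object of class `vessel_image`.
#' @export
vessel_image <- function(pixels, site = NA_character_, eye = NA_character_,
                         bit_depth = 8L) {
  if (!(is.matrix(pixels) ||
        (is.array(pixels) && length(dim(pixels)) == 3L &&
           dim(pixels)[3L] == 3L)))
    stop("pixels must be a matrix or an h x w x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, site = site, eye = eye,
                 bit_depth = as.integer(bit_depth)),
            class = "vessel_image")
}

image_dim <- function(img) dim(img$pixels)[1:2]

# Green channel (or the single channel) as a plain matrix.
green_channel <- function(img) {
  px <- img$pixels
  if (length(dim(px)) == 3L) px[, , 2L] else px
}

#' @export
print.vessel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<vessel_image: %d x %d px, %s, %d-bit%s%s>\n",
              d[2L], d[1L],
              if (length(d) == 3L) "RGB" else "grayscale", x$bit_depth,
              if (!is.na(x$site)) paste0(", site=", x$site) else "",
              if (!is.na(x$eye)) paste0(", eye=", x$eye) else ""))
  invisible(x)
}

#' @export
plot.vessel_image <- function(x, ...) {
  g <- green_channel(x)
  graphics::image(0:(ncol(g) - 1L), 0:(nrow(g) - 1L),
                  t(g)[, nrow(g):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "x (px)", ylab = "y (px)", useRaster = TRUE, ...)
  invisible(x)
}

#' Render a centerline into a synthetic vessel image
#'
#' Computes, for every pixel within reach of the curve, the exact Euclidean
#' distance to the piecewise-linear centerline and applies the Gaussian
#' cross-section of [raster_params()]. Contributions beyond `4*sigma + 1` px
#' are below half an intensity level and are truncated.
#'
#' @param centerline a [polyline][as_polyline] in image coordinates; it must
#'   keep a margin of at least `vessel_width_px` from the image border.
#' @param rp a [raster_params()].
#' @param noise_seed optional seed for the additive noise (ignored when
#'   `noise_sd = 0`).
#' @param site,eye metadata passed to [vessel_image()].
#' @param quantize round intensities to whole 8-bit levels (the default,
#'   matching acquired images); `FALSE` keeps the continuous profile, which
#'   is useful when analysing the profile itself.
#' @return a [vessel_image()].
#' @export
rasterize_vessel <- function(centerline, rp = raster_params(),
                             noise_seed = NULL, site = NA_character_,
                             eye = NA_character_, quantize = TRUE) {
  stopifnot(inherits(rp, "raster_params"))
  m <- poly_mat(as_polyline(centerline))
  h <- rp$image_size[1L]; w <- rp$image_size[2L]
  mar <- rp$vessel_width_px
  if (min(m[, 1L]) < mar || max(m[, 1L]) > w - 1 - mar ||
      min(m[, 2L]) < mar || max(m[, 2L]) > h - 1 - mar)
    stop(sprintf(paste0("centerline out of bounds: it must fit inside the ",
                        "%d x %d image with a %.3g px margin"), w, h, mar))
  sigma <- rp$vessel_width_px / (2 * sqrt(2 * log(2)))
  cutoff <- ceiling(4 * sigma) + 1L
  d2 <- matrix(Inf, h, w)
  for (k in seq_len(nrow(m) - 1L)) {
    p1 <- m[k, ]; p2 <- m[k + 1L, ]
    xs <- max(0L, floor(min(p1[1L], p2[1L])) - cutoff):
      min(w - 1L, ceiling(max(p1[1L], p2[1L])) + cutoff)
    ys <- max(0L, floor(min(p1[2L], p2[2L])) - cutoff):
      min(h - 1L, ceiling(max(p1[2L], p2[2L])) + cutoff)
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    dx <- p2[1L] - p1[1L]; dy <- p2[2L] - p1[2L]
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((X - p1[1L]) * dx + (Y - p1[2L]) * dy) / len2))
    dd <- (X - (p1[1L] + t * dx))^2 + (Y - (p1[2L] + t * dy))^2
    rows <- ys + 1L; cols <- xs + 1L
    d2[rows, cols] <- pmin(d2[rows, cols], dd)
  }
  img <- rp$background_level -
    rp$vessel_contrast * ifelse(d2 <= cutoff^2, exp(-d2 / (2 * sigma^2)), 0)
  if (rp$noise_sd > 0)
    img <- img + with_seed(noise_seed,
                           matrix(stats::rnorm(h * w, 0, rp$noise_sd), h, w))
  img <- pmin(pmax(img, 0), 255)
  if (quantize) img <- round(img)
  vessel_image(img, site = site, eye = eye)
}

#' Cohort simulation parameters
#'
#' Defines a two-group (cases vs controls) imaging study of per-site vessel
#' segments, mirroring the acquisition protocol: two eyes per subject, five
#' retinal segments and three segments per conjunctival sector, segment chord
#' lengths drawn uniformly within site-specific windows (350-500 px retina,
#' 250-400 px conjunctiva).
#'
#' The tortuosity model is a sinusoid whose amplitude carries the group
#' effect: a subject's latent amplitude is lognormal around
#' `base_amplitude_px` (times `effect_multiplier[site]` in the case group),
#' shared across both eyes, and each segment draws a small additional
#' lognormal perturbation (`segment_sd_log`). Hence at every site the
#' case/control ratio of expected amplitudes equals `effect_multiplier[site]`
#' exactly.
#'
#' @param n_per_group subjects per group (>= 2; the study design is 11 + 11).
#' @param sites character vector of ocular sites, subset of `retina`,
#'   `conj_nasal`, `conj_temporal`, `conj_superior`, `conj_inferior`.
#' @param segments_per_site named integer vector, segments per site; default
#'   5 for the retina and 3 per conjunctival sector.
#' @param base_amplitude_px mean control-group sinusoid amplitude (default
#'   8 px at a 100 px wavelength: a moderately tortuous vessel).
#' @param effect_multiplier named numeric vector of multiplicative case-group
#'   amplitude effects; default 1.6 at `retina` and `conj_nasal`, 1 at the
#'   other sectors. All values must be positive.
#' @param subject_sd_log between-subject lognormal SD (default 0.3).
#' @param segment_sd_log within-subject, between-segment lognormal SD
#'   (default 0.15).
#' @param wavelength_px sinusoid wavelength (default 100 px).
#' @param length_windows named list of `(min, max)` chord-length windows per
#'   site; defaults to 350-500 px (retina) and 250-400 px (conjunctiva).
#' @param sample_spacing_px arc-length step of generated centerlines.
#' @param age_range ages are drawn uniformly over this interval (default
#'   30-71 years).
#' @param rng_seed integer seed; the whole cohort is reproducible under it.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 11,
                          sites = c("retina", "conj_nasal", "conj_temporal",
                                    "conj_superior", "conj_inferior"),
                          segments_per_site = NULL, base_amplitude_px = 8,
                          effect_multiplier = NULL, subject_sd_log = 0.3,
                          segment_sd_log = 0.15, wavelength_px = 100,
                          length_windows = NULL, sample_spacing_px = 5,
                          age_range = c(30, 71), rng_seed = NULL) {
  all_sites <- c("retina", "conj_nasal", "conj_temporal", "conj_superior",
                 "conj_inferior")
  sites <- match.arg(sites, all_sites, several.ok = TRUE)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  def_seg <- c(retina = 5L, conj_nasal = 3L, conj_temporal = 3L,
               conj_superior = 3L, conj_inferior = 3L)
  segments_per_site <- if (is.null(segments_per_site)) def_seg[sites] else {
    s <- def_seg[sites]
    s[names(segments_per_site)[names(segments_per_site) %in% sites]] <-
      segments_per_site[names(segments_per_site) %in% sites]
    s
  }
  if (any(segments_per_site < 1)) stop("segments_per_site counts must be >= 1")
  def_eff <- c(retina = 1.6, conj_nasal = 1.6, conj_temporal = 1,
               conj_superior = 1, conj_inferior = 1)
  effect_multiplier <- if (is.null(effect_multiplier)) def_eff[sites] else {
    e <- def_eff[sites]
    if (is.null(names(effect_multiplier)) &&
        length(effect_multiplier) == 1L) {
      e[] <- effect_multiplier
    } else {
      e[names(effect_multiplier)[names(effect_multiplier) %in% sites]] <-
        effect_multiplier[names(effect_multiplier) %in% sites]
    }
    e
  }
  if (any(effect_multiplier <= 0)) stop("effect_multiplier values must be > 0")
  def_win <- list(retina = c(350, 500), conj_nasal = c(250, 400),
                  conj_temporal = c(250, 400), conj_superior = c(250, 400),
                  conj_inferior = c(250, 400))
  length_windows <- length_windows %||% def_win[sites]
  if (base_amplitude_px <= 0) stop("base_amplitude_px must be positive")
  if (subject_sd_log < 0 || segment_sd_log < 0)
    stop("lognormal SDs must be >= 0")
  if (length(age_range) != 2L || age_range[1L] <= 0 ||
      age_range[2L] < age_range[1L])
    stop("age_range must be (min, max) with 0 < min <= max")
  structure(list(n_per_group = as.integer(n_per_group), sites = sites,
                 segments_per_site = segments_per_site,
                 base_amplitude_px = base_amplitude_px,
                 effect_multiplier = effect_multiplier,
                 subject_sd_log = subject_sd_log,
                 segment_sd_log = segment_sd_log,
                 wavelength_px = wavelength_px,
                 length_windows = length_windows,
                 sample_spacing_px = sample_spacing_px,
                 age_range = age_range, rng_seed = rng_seed),
            class = "cohort_params")
}

#' Simulate a two-group cohort of vessel centerlines
#'
#' Generates `2 * n_per_group` subjects (groups `FD` and `control`, sexes
#' balanced within group, ages uniform over `age_range`) and, for every
#' subject, eye (`OD`, `OS`) and configured site, the configured number of
#' sinusoidal centerline segments. The latent per-subject amplitude is shared
#' between the two eyes; segments add independent lognormal noise, a random
#' phase and a chord length drawn from the site's window. Deterministic under
#' `cp$rng_seed`.
#'
#' @param cp a [cohort_params()].
#' @return an object of class `vessel_cohort`: a list with
#'   \describe{
#'     \item{subjects}{data frame `subject_id, group, sex, age`.}
#'     \item{traces}{list of segment records, each with `subject_id, group,
#'       eye, site, segment_id, amplitude_px, span_px` and the `polyline`.}
#'     \item{params}{the `cohort_params` used.}
#'   }
#' @examples
#' co <- gen_cohort(cohort_params(n_per_group = 3, sites = "retina",
#'                                rng_seed = 1))
#' head(tortuosity_table(co))
#' @export
gen_cohort <- function(cp) {
  stopifnot(inherits(cp, "cohort_params"))
  with_seed(cp$rng_seed, {
    n <- cp$n_per_group
    ids <- c(sprintf("FD%02d", seq_len(n)), sprintf("C%02d", seq_len(n)))
    groups <- rep(c("FD", "control"), each = n)
    # balanced sexes within group: 6 F / 5 M at the study's n = 11
    sex_one <- rep_len(c("F", "M"), n)
    subjects <- data.frame(subject_id = ids, group = groups,
                           sex = c(sex_one, sex_one),
                           age = round(stats::runif(2L * n, cp$age_range[1L],
                                                    cp$age_range[2L]), 1L),
                           stringsAsFactors = FALSE)
    traces <- vector("list",
                     2L * n * 2L * sum(cp$segments_per_site))
    ti <- 0L
    for (s in seq_len(2L * n)) {
      subj_factor <- exp(stats::rnorm(1L, 0, cp$subject_sd_log))
      for (eye in c("OD", "OS")) {
        for (site in cp$sites) {
          mult <- if (groups[s] == "FD") cp$effect_multiplier[[site]] else 1
          win <- cp$length_windows[[site]]
          for (seg in seq_len(cp$segments_per_site[[site]])) {
            amp <- cp$base_amplitude_px * mult * subj_factor *
              exp(stats::rnorm(1L, 0, cp$segment_sd_log))
            span <- stats::runif(1L, win[1L], win[2L])
            phase <- stats::runif(1L, 0, 2 * pi)
            pl <- gen_centerline(curve_params(
              "sinusoid", span_px = span, amplitude_px = amp,
              wavelength_px = cp$wavelength_px,
              sample_spacing_px = cp$sample_spacing_px, phase = phase))
            ti <- ti + 1L
            traces[[ti]] <- list(subject_id = ids[s], group = groups[s],
                                 eye = eye, site = site,
                                 segment_id = sprintf("%s_%s_%s_%d", ids[s],
                                                      eye, site, seg),
                                 amplitude_px = amp, span_px = span,
                                 polyline = pl)
          }
        }
      }
    }
    structure(list(subjects = subjects, traces = traces, params = cp),
              class = "vessel_cohort")
  })
}

#' @export
print.vessel_cohort <- function(x, ...) {
  cat(sprintf("<vessel_cohort: %d subjects (%d per group), %d traces>\n",
              nrow(x$subjects), x$params$n_per_group, length(x$traces)))
  cat("  sites:", paste(x$params$sites, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.vessel_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$traces, function(tr)
    data.frame(subject_id = tr$subject_id, group = tr$group, eye = tr$eye,
               site = tr$site, segment_id = tr$segment_id,
               amplitude_px = tr$amplitude_px, span_px = tr$span_px,
               n_points = nrow(tr$polyline), stringsAsFactors = FALSE)))
}
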