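#' Tracing configuration
#'
#' Parameters of the semi-automatic centerline tracer.
#'
#' @param scales Gaussian smoothing scales (pixels) of the multiscale
#'   vesselness filter; the response is maximized over scales. The defaults
#'   bracket vessels of 4-10 px width.
#' @param epsilon floor added to the path cost (`cost = step length *
#'   (epsilon + 1 - vesselness)`); keeps every pixel reachable at finite
#'   cost.
#' @param smooth_window centered moving-average window (samples, odd)
#'   applied to the raw 8-connected path.
#' @param snap_radius operator clicks are refined to the vesselness maximum
#'   within this Chebyshev radius (pixels) before tracing; 0 disables click
#'   correction. Refinement is what makes repeated tracings of the same
#'   vessel insensitive to a few pixels of click jitter.
#' @param refine_iters sub-pixel refinement passes applied to the traced
#'   path: each pass fits a parabola to the (inverted, lightly smoothed)
#'   intensity sampled across the local path normal and moves the point to
#'   its vertex, the standard ridge-following correction for the half-pixel
#'   bias of a grid path. 0 disables refinement.
#' @param refine_sigma Gaussian pre-smoothing scale (pixels) of the
#'   intensity field used for sub-pixel refinement. Kept small: a heavily
#'   smoothed field displaces the ridge of a curved vessel toward its
#'   center of curvature (by roughly `sigma^2 * curvature`), biasing
#'   tortuosity down.
#' @return an object of class `tracing_config`.
#' @export
tracing_config <- function(scales = c(1.5, 2.5, 3.5), epsilon = 0.05,
                           smooth_window = 5, snap_radius = 5,
                           refine_iters = 2, refine_sigma = 1) {
  if (any(scales <= 0)) stop("scales must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be a positive odd integer")
  if (snap_radius < 0) stop("snap_radius must be >= 0")
  if (refine_iters < 0) stop("refine_iters must be >= 0")
  if (refine_sigma <= 0) stop("refine_sigma must be positive")
  structure(list(scales = scales, epsilon = epsilon,
                 smooth_window = as.integer(smooth_window),
                 snap_radius = as.integer(snap_radius),
                 refine_iters = as.integer(refine_iters),
                 refine_sigma = refine_sigma),
            class = "tracing_config")
}

# Separable Gaussian convolution with replicated edges (shift-and-add).
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  # columns (x direction)
  mp <- m[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (o in seq_along(k)) out <- out + k[o] * mp[, o:(o + w - 1L)]
  # rows (y direction)
  mp <- out[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (o in seq_along(k)) out <- out + k[o] * mp[o:(o + h - 1L), ]
  out
}

# Central-difference partial derivatives with replicated edges.
diff_x <- function(m) {
  w <- ncol(m)
  (m[, c(2:w, w)] - m[, c(1L, 1:(w - 1L))]) / 2
}
diff_y <- function(m) {
  h <- nrow(m)
  (m[c(2:h, h), ] - m[c(1L, 1:(h - 1L)), ]) / 2
}

#' Multiscale Hessian vesselness map
#'
#' Ridge response on the inverted green channel (vessels are darker than
#' background, so after inversion they are bright ridges). At each scale
#' `s`, the image is Gaussian-smoothed, the Hessian computed by central
#' differences, and the scale-normalized ridge strength
#' `s^2 * max(-lambda2, 0)` taken, where `lambda2` is the more negative
#' Hessian eigenvalue (large across a bright ridge, near zero along it).
#' The response is maximized over scales and min-max normalized to `[0, 1]`
#' per image. A constant image has no ridges: the map is all zeros and a
#' warning is raised.
#'
#' @param image a [vessel_image()] (RGB input is reduced to its green
#'   channel) or a plain intensity matrix.
#' @param scales smoothing scales in pixels; see [tracing_config()].
#' @return a matrix of the image's size with values in `[0, 1]`.
#' @export
vesselness_map <- function(image, scales = tracing_config()$scales) {
  g <- if (inherits(image, "vessel_image")) green_channel(image)
       else as.matrix(image)
  g <- (255 - g) / 255  # invert: vessels become bright ridges
  resp <- matrix(0, nrow(g), ncol(g))
  for (s in scales) {
    sm <- gauss_blur(g, s)
    gx <- diff_x(sm); gy <- diff_y(sm)
    hxx <- diff_x(gx); hyy <- diff_y(gy); hxy <- diff_y(gx)
    # smaller (more negative) eigenvalue of the 2x2 Hessian
    lam2 <- ((hxx + hyy) - sqrt((hxx - hyy)^2 + 4 * hxy^2)) / 2
    resp <- pmax(resp, s^2 * pmax(-lam2, 0))
  }
  rng <- range(resp)
  if (rng[2L] - rng[1L] <= .Machine$double.eps) {
    warning("no ridge structure found (constant image?): ",
            "vesselness map is all zeros")
    return(matrix(0, nrow(g), ncol(g)))
  }
  (resp - rng[1L]) / (rng[2L] - rng[1L])
}

#' Build a reusable tracer for one image
#'
#' Precomputes the vesselness map and the weighted 8-connected lattice graph
#' whose shortest paths define traced centerlines, so that many segments (or
#' repeated tracings) of the same image do not repeat that work. The cost of
#' an edge between neighbouring pixels `u`, `v` is
#' `|u - v| * (epsilon + 1 - (V(u) + V(v)) / 2)` with `V` the vesselness;
#' minimal-cost paths therefore hug the vessel ridge.
#'
#' @param image a [vessel_image()] or intensity matrix.
#' @param config a [tracing_config()].
#' @return an object of class `vessel_tracer`.
#' @export
vessel_tracer <- function(image, config = tracing_config()) {
  stopifnot(inherits(config, "tracing_config"))
  g <- if (inherits(image, "vessel_image")) green_channel(image)
       else as.matrix(image)
  refine_field <- gauss_blur((255 - g) / 255, config$refine_sigma)
  V <- vesselness_map(g, config$scales)
  h <- nrow(V); w <- ncol(V)
  # node id = y * w + x + 1 (0-based x, y); vesselness in id order:
  v <- as.vector(t(V))
  id <- seq_len(h * w)
  x <- (id - 1L) %% w
  y <- (id - 1L) %/% w
  e_from <- c(id[x < w - 1L],            # right
              id[y < h - 1L],            # down
              id[x < w - 1L & y < h - 1L],  # down-right
              id[x > 0L & y < h - 1L])   # down-left
  e_to <- c(id[x < w - 1L] + 1L,
            id[y < h - 1L] + w,
            id[x < w - 1L & y < h - 1L] + w + 1L,
            id[x > 0L & y < h - 1L] + w - 1L)
  e_len <- c(rep(1, sum(x < w - 1L)), rep(1, sum(y < h - 1L)),
             rep(sqrt(2), sum(x < w - 1L & y < h - 1L)),
             rep(sqrt(2), sum(x > 0L & y < h - 1L)))
  wt <- e_len * (config$epsilon + 1 - (v[e_from] + v[e_to]) / 2)
  gr <- igraph::make_graph(rbind(e_from, e_to), n = h * w, directed = FALSE)
  structure(list(graph = gr, weights = wt, vesselness = V,
                 refine_field = refine_field, dim = c(h, w),
                 config = config),
            class = "vessel_tracer")
}

# Bilinear interpolation of a matrix field at 0-based (x, y) positions,
# clamped to the image domain.
interp_field <- function(V, x, y) {
  h <- nrow(V); w <- ncol(V)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  V[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    V[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
    V[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
    V[cbind(y1 + 1, x1 + 1)] * fx * fy
}

# One sub-pixel refinement pass: move every path point along its local
# normal to the vertex of a parabola fitted to the field at offsets
# -1, 0, +1 px. Point-wise and symmetric under path reversal.
refine_pass <- function(m, V) {
  n <- nrow(m)
  tx <- c(m[2L, 1L] - m[1L, 1L], m[3:n, 1L] - m[1:(n - 2L), 1L],
          m[n, 1L] - m[n - 1L, 1L])
  ty <- c(m[2L, 2L] - m[1L, 2L], m[3:n, 2L] - m[1:(n - 2L), 2L],
          m[n, 2L] - m[n - 1L, 2L])
  len <- sqrt(tx^2 + ty^2)
  nx <- -ty / len; ny <- tx / len
  v0 <- interp_field(V, m[, 1L], m[, 2L])
  vp <- interp_field(V, m[, 1L] + nx, m[, 2L] + ny)
  vm <- interp_field(V, m[, 1L] - nx, m[, 2L] - ny)
  den <- vm - 2 * v0 + vp
  delta <- ifelse(abs(den) > 1e-12, 0.5 * (vm - vp) / den, 0)
  delta <- pmin(pmax(delta, -1), 1)
  m + cbind(nx * delta, ny * delta)
}

#' @export
print.vessel_tracer <- function(x, ...) {
  cat(sprintf("<vessel_tracer: %d x %d px, %d-edge lattice>\n",
              x$dim[2L], x$dim[1L], length(x$weights)))
  invisible(x)
}

# Normalize a seed triplet given as length-6 numeric (x1,y1,...,y3) or 3x2
# matrix; validate against image dimensions.
check_seeds <- function(seeds, dm) {
  if (!is.matrix(seeds) && is.numeric(seeds) && length(seeds) == 6L)
    seeds <- matrix(seeds, 3L, 2L, byrow = TRUE)
  if (!is.matrix(seeds) || !all(dim(seeds) == c(3L, 2L)))
    stop("seeds must be three (x, y) points: a 3 x 2 matrix or a length-6 ",
         "vector x1,y1,x2,y2,x3,y3")
  if (any(seeds[, 1L] < 0) || any(seeds[, 1L] > dm[2L] - 1L) ||
      any(seeds[, 2L] < 0) || any(seeds[, 2L] > dm[1L] - 1L))
    stop("seed out of image bounds")
  r <- round(seeds)
  if (anyDuplicated(split(r, row(r))) > 0 ||
      nrow(unique(r)) < 3L)
    stop("seeds must be pairwise distinct")
  d <- sqrt(rowSums((seeds[-1L, , drop = FALSE] -
                       seeds[-3L, , drop = FALSE])^2))
  if (any(d < 10))
    stop("consecutive seeds must be at least 10 px apart")
  r
}

# Refine one (x, y) seed to the vesselness maximum within a square window.
snap_seed <- function(seed, V, radius) {
  if (radius == 0L) return(seed)
  h <- nrow(V); w <- ncol(V)
  xs <- max(0L, seed[1L] - radius):min(w - 1L, seed[1L] + radius)
  ys <- max(0L, seed[2L] - radius):min(h - 1L, seed[2L] + radius)
  win <- V[ys + 1L, xs + 1L, drop = FALSE]
  best <- arrayInd(which.max(win), dim(win))
  c(xs[best[1L, 2L]], ys[best[1L, 1L]])
}

#' Trace a vessel centerline from three operator seeds
#'
#' Emulates the semi-automatic protocol in which the operator clicks three
#' locations along a vessel's course: each click is first refined to the
#' nearest vesselness ridge maximum (within `snap_radius`), then the
#' minimal-cost 8-connected path is computed from the first to the second
#' refined seed and from the second to the third, the two halves are
#' concatenated, and the result is smoothed with a centered moving average
#' (`smooth_window` samples, edges replicated) followed by `refine_iters`
#' sub-pixel passes that re-center each point on the vessel's intensity
#' ridge (see [tracing_config()]) — without them a grid path carries up to
#' half a pixel of quantization, which inflates the turning-angle metrics
#' of gently curved vessels.
#'
#' @param x a [vessel_tracer()] (preferred when tracing the same image more
#'   than once) or a [vessel_image()] / intensity matrix.
#' @param seeds three `(x, y)` points ordered along the vessel: a 3 x 2
#'   matrix or a length-6 vector `x1,y1,x2,y2,x3,y3`; 0-based pixel
#'   coordinates.
#' @param config a [tracing_config()]; ignored (the tracer's own
#'   configuration is used) when `x` is already a `vessel_tracer`.
#' @return a [polyline][as_polyline] with attribute `seeds` (the refined
#'   integer seed positions actually traced between).
#' @export
trace_segment <- function(x, seeds, config = tracing_config()) {
  tracer <- if (inherits(x, "vessel_tracer")) x
            else vessel_tracer(x, config)
  dm <- tracer$dim
  seeds <- check_seeds(seeds, dm)
  snapped <- t(apply(seeds, 1L, snap_seed, V = tracer$vesselness,
                     radius = tracer$config$snap_radius))
  w <- dm[2L]
  ids <- snapped[, 2L] * w + snapped[, 1L] + 1L
  # each half is traced in a canonical node order (and flipped back if
  # needed) so that equal-cost tie-breaking inside the shortest-path search
  # cannot depend on the operator's seed ordering
  half <- function(a, b) {
    flip <- a > b
    if (flip) { tmp <- a; a <- b; b <- tmp }
    sp <- igraph::shortest_paths(tracer$graph, from = a, to = b,
                                 weights = tracer$weights,
                                 output = "vpath")
    path <- as.integer(sp$vpath[[1L]])
    if (length(path) == 0L)
      stop("tracing failure: no finite-cost path between seeds")
    if (flip) rev(path) else path
  }
  p1 <- half(ids[1L], ids[2L])
  p2 <- half(ids[2L], ids[3L])
  path <- c(p1, p2[-1L])
  # smooth in a canonical orientation as well, so the float summation order
  # of the moving average cannot depend on the seed ordering either
  flip_out <- path[1L] > path[length(path)]
  if (flip_out) path <- rev(path)
  m <- cbind(x = (path - 1L) %% w, y = (path - 1L) %/% w)
  win <- tracer$config$smooth_window
  if (win > 1L && nrow(m) > win) {
    r <- (win - 1L) %/% 2L
    pad_idx <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
    for (j in 1:2) {
      v <- m[pad_idx, j]
      m[, j] <- as.numeric(stats::filter(v, rep(1 / win, win),
                                         sides = 2L))[(r + 1L):(r + nrow(m))]
    }
  }
  for (i in seq_len(tracer$config$refine_iters))
    m <- refine_pass(m, tracer$refine_field)
  if (flip_out) m <- m[nrow(m):1L, , drop = FALSE]
  out <- as_polyline(m)
  attr(out, "seeds") <- snapped
  out
}

#' Segment specification for a given ocular site
#'
#' Encodes the acquisition protocol per site: expected segment arc-length
#' window (350-500 px for retinal segments, 250-400 px for conjunctival
#' sectors) and the number of segments traced per site (5 retina, 3 per
#' conjunctival sector).
#'
#' @param site one of `retina`, `conj_nasal`, `conj_temporal`,
#'   `conj_superior`, `conj_inferior`.
#' @param eye `"OD"` or `"OS"` (optional).
#' @param expected_length_px override of the `(min, max)` arc-length window.
#' @param n_segments override of the per-site segment count.
#' @return an object of class `segment_spec`.
#' @export
segment_spec <- function(site = c("retina", "conj_nasal", "conj_temporal",
                                  "conj_superior", "conj_inferior"),
                         eye = NA_character_, expected_length_px = NULL,
                         n_segments = NULL) {
  site <- match.arg(site)
  expected_length_px <- expected_length_px %||%
    if (site == "retina") c(350, 500) else c(250, 400)
  n_segments <- n_segments %||% if (site == "retina") 5L else 3L
  if (length(expected_length_px) != 2L ||
      expected_length_px[1L] > expected_length_px[2L])
    stop("expected_length_px must be (min, max)")
  structure(list(site = site, eye = eye,
                 expected_length_px = expected_length_px,
                 n_segments = as.integer(n_segments)),
            class = "segment_spec")
}

#' Validate a traced segment against its site protocol
#'
#' Produces warnings (never errors): an arc length outside the site's
#' expected window, a self-intersecting trace, or a mean vesselness along
#' the path below 0.2 (the path does not follow a vessel — e.g. the seeds
#' were placed on background).
#'
#' @param p a traced [polyline][as_polyline].
#' @param spec a [segment_spec()].
#' @param vesselness optional vesselness matrix (or [vessel_tracer()]) to
#'   check ridge support along the path.
#' @return invisibly, a character vector of warning messages (empty when the
#'   segment is clean); each is also raised via [warning()].
#' @export
validate_segment <- function(p, spec, vesselness = NULL) {
  stopifnot(inherits(spec, "segment_spec"))
  p <- as_polyline(p)
  msgs <- character()
  L <- arc_length(p)
  win <- spec$expected_length_px
  if (L < win[1L] || L > win[2L])
    msgs <- c(msgs, sprintf(
      "arc length %.0f px outside the expected %s window [%.0f, %.0f]",
      L, spec$site, win[1L], win[2L]))
  if (self_intersects(p))
    msgs <- c(msgs, "trace is self-intersecting")
  if (!is.null(vesselness)) {
    V <- if (inherits(vesselness, "vessel_tracer")) vesselness$vesselness
         else vesselness
    m <- round(poly_mat(p))
    m[, 1L] <- pmin(pmax(m[, 1L], 0), ncol(V) - 1L)
    m[, 2L] <- pmin(pmax(m[, 2L], 0), nrow(V) - 1L)
    mv <- mean(V[cbind(m[, 2L] + 1L, m[, 1L] + 1L)])
    if (mv < 0.2)
      msgs <- c(msgs, sprintf(
        "mean vesselness along path is %.2f (< 0.2): trace may not follow a vessel",
        mv))
  }
  for (msg in msgs) warning(msg, call. = FALSE)
  invisible(msgs)
}

#' Seed-jitter reproducibility of the tracing pipeline
#'
#' Re-traces the same vessel `n_repeats` times with every seed coordinate
#' perturbed independently by `Uniform(-jitter_px, +jitter_px)`, computes
#' the three tortuosity indices per repeat, and returns the per-metric
#' coefficient of variation (SD / mean). This is the desk-scale analog of an
#' intra/inter-observer repeatability study: the jitter stands in for
#' click-placement variability between observers or sessions.
#'
#' @param tracer a [vessel_tracer()] (or an image, from which one is built).
#' @param seeds the nominal seed triplet (see [trace_segment()]).
#' @param n_repeats number of repeated tracings (default 20).
#' @param jitter_px half-width of the uniform perturbation (default 3 px).
#' @param metric_cfg a [metric_config()].
#' @param rng_seed optional seed for the jitter draws.
#' @return a list with `cv` (named per-metric CV, as a fraction), `values`
#'   (`n_repeats x 3` matrix of metric values) and `n_repeats`.
#' @export
seed_jitter_cv <- function(tracer, seeds, n_repeats = 20, jitter_px = 3,
                           metric_cfg = metric_config(), rng_seed = NULL) {
  if (!inherits(tracer, "vessel_tracer")) tracer <- vessel_tracer(tracer)
  seeds <- check_seeds(seeds, tracer$dim)
  vals <- with_seed(rng_seed, {
    out <- matrix(NA_real_, n_repeats, 3L,
                  dimnames = list(NULL, c("soam", "pad", "i2e")))
    for (r in seq_len(n_repeats)) {
      jit <- matrix(stats::runif(6L, -jitter_px, jitter_px), 3L, 2L)
      s <- seeds + jit
      s[, 1L] <- pmin(pmax(s[, 1L], 0), tracer$dim[2L] - 1L)
      s[, 2L] <- pmin(pmax(s[, 2L], 0), tracer$dim[1L] - 1L)
      tr <- trace_segment(tracer, s)
      v <- tort_metrics(poly_mat(tr), metric_cfg$resample_spacing_px,
                        metric_cfg$i2e_step, metric_cfg$min_points,
                        metric_cfg$eps_den)
      out[r, ] <- v[c("soam", "pad", "i2e")]
    }
    out
  })
  cv <- apply(vals, 2L, function(col) stats::sd(col) / mean(col))
  list(cv = cv, values = vals, n_repeats = n_repeats)
}
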