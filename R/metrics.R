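#' Metric configuration
#'
#' Settings shared by all tortuosity computations. `resample_spacing_px`
#' fixes the arc-length sampling step applied before any metric (turning
#' angles depend on sampling, so the spacing must be pinned for values to be
#' comparable across segments); `i2e_step` is the triplet half-width `e` of
#' the triangular index; polylines with fewer than `min_points` points after
#' resampling are rejected; `eps_den` guards the I2e denominator against
#' curves that fold back onto themselves.
#'
#' @param resample_spacing_px arc-length spacing in pixels (default 5).
#' @param i2e_step integer step `e >= 1` of the triangular index (default 2).
#' @param min_points minimum number of resampled points (default 10).
#' @param eps_den smallest admissible I2e denominator (default 1e-9).
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(resample_spacing_px = 5, i2e_step = 2,
                          min_points = 10, eps_den = 1e-9) {
  if (resample_spacing_px <= 0) stop("resample_spacing_px must be positive")
  if (i2e_step < 1 || i2e_step != round(i2e_step))
    stop("i2e_step must be an integer >= 1")
  if (min_points < 3) stop("min_points must be at least 3")
  structure(list(resample_spacing_px = resample_spacing_px,
                 i2e_step = as.integer(i2e_step),
                 min_points = as.integer(min_points),
                 eps_den = eps_den),
            class = "metric_config")
}

#' Turning angles of a polyline
#'
#' At every interior vertex, the absolute angle between the incoming and
#' outgoing chord vectors: `theta_k = acos(v_{k-1} . v_k / (|v_{k-1}||v_k|))`,
#' clamped into `[-1, 1]` before `acos` to absorb floating-point drift, so
#' `theta_k` lies in `[0, pi]` (0 for collinear triplets).
#'
#' @param p a [polyline][as_polyline] with at least 3 points; for tortuosity
#'   work, resample first (see [resample_polyline()]).
#' @return numeric vector of `n - 2` angles in radians.
#' @examples
#' turning_angles(as_polyline(cbind(c(0, 1, 1), c(0, 0, 1))))  # pi/2
#' @export
turning_angles <- function(p) {
  m <- poly_mat(as_polyline(p))
  if (nrow(m) < 3L) stop("turning angles need at least 3 points")
  v <- m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  nv <- nrow(v)
  nn <- sqrt(rowSums(v^2))
  ca <- rowSums(v[-nv, , drop = FALSE] * v[-1L, , drop = FALSE]) /
    (nn[-nv] * nn[-1L])
  acos(pmin(1, pmax(-1, ca)))
}

#' Sum of angles metric (SOAM)
#'
#' Total absolute turning along the curve normalized by its arc length:
#' `SOAM = sum(theta_k) / L`, in radians per pixel. Zero exactly on straight
#' lines; for a circular arc of radius `r` it converges to `1/r` (the
#' curvature) as the sampling refines.
#'
#' @inheritParams turning_angles
#' @return SOAM in radians/pixel.
#' @export
soam <- function(p) {
  p <- as_polyline(p)
  sum(turning_angles(p)) / arc_length(p)
}

#' Product of angle-distance (PAD)
#'
#' Each turning angle weighted by its local inter-sample distance
#' `d_k = (|v_{k-1}| + |v_k|) / 2`, summed and normalized by arc length:
#' `PAD = sum(theta_k * d_k) / L` (dimensionless). Under exactly uniform
#' spacing `s`, `PAD = s * SOAM`.
#'
#' @inheritParams turning_angles
#' @return PAD (dimensionless, >= 0).
#' @export
pad <- function(p) {
  m <- poly_mat(as_polyline(p))
  if (nrow(m) < 3L) stop("PAD needs at least 3 points")
  nn <- seg_lengths(m)
  nv <- length(nn)
  d <- (nn[-nv] + nn[-1L]) / 2
  sum(turning_angles(p) * d) / sum(nn)
}

#' Triangular index (I2e)
#'
#' A sliding inscribed-triangle arc/chord ratio: for each vertex `k` with
#' both neighbours `e` samples away, the ratio of the two triangle sides to
#' the base, `(|p_{k-e} - p_k| + |p_k - p_{k+e}|) / |p_{k-e} - p_{k+e}|`,
#' averaged over all admissible `k`. Each term is `>= 1` by the triangle
#' inequality, with equality exactly on straight lines.
#'
#' @inheritParams turning_angles
#' @param e integer step (`>= 1`); the polyline needs at least `2e + 1`
#'   points.
#' @param eps_den degenerate-triangle guard: an error is raised if any base
#'   `|p_{k-e} - p_{k+e}|` falls below this (the curve folds back on itself).
#' @return I2e (dimensionless, >= 1).
#' @examples
#' i2e(as_polyline(cbind(c(0, 1, 1), c(0, 0, 1))), e = 1)  # sqrt(2)
#' @export
i2e <- function(p, e = 2, eps_den = 1e-9) {
  m <- poly_mat(as_polyline(p))
  e <- as.integer(e)
  if (e < 1L) stop("e must be an integer >= 1")
  n <- nrow(m)
  if (n < 2L * e + 1L)
    stop(sprintf("I2e with e = %d needs at least %d points, got %d",
                 e, 2L * e + 1L, n))
  k <- (e + 1L):(n - e)
  a <- sqrt(rowSums((m[k - e, , drop = FALSE] - m[k, , drop = FALSE])^2))
  b <- sqrt(rowSums((m[k, , drop = FALSE] - m[k + e, , drop = FALSE])^2))
  base <- sqrt(rowSums((m[k - e, , drop = FALSE] -
                          m[k + e, , drop = FALSE])^2))
  if (any(base < eps_den))
    stop("degenerate triangle in I2e: curve folds back on itself")
  mean((a + b) / base)
}

# Fast internal path: resample + all three metrics on a bare matrix.
# Returns c(soam, pad, i2e, arc_length, n_points). Used in simulation loops
# where the construction/validation overhead of the S3 surface matters.
tort_metrics <- function(m, spacing, e, min_points = 10L, eps_den = 1e-9) {
  if (reversed_orientation(m)) m <- m[nrow(m):1L, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums((m[-1L, , drop = FALSE] -
                                   m[-nrow(m), , drop = FALSE])^2))))
  L0 <- s[length(s)]
  targets <- resample_targets(L0, spacing)
  q <- cbind(stats::approx(s, m[, 1L], xout = targets)$y,
             stats::approx(s, m[, 2L], xout = targets)$y)
  n <- nrow(q)
  if (n < min_points)
    stop(sprintf("only %d points after resampling (min_points = %d)",
                 n, min_points))
  v <- q[-1L, , drop = FALSE] - q[-n, , drop = FALSE]
  nn <- sqrt(rowSums(v^2))
  nv <- length(nn)
  ca <- rowSums(v[-nv, , drop = FALSE] * v[-1L, , drop = FALSE]) /
    (nn[-nv] * nn[-1L])
  theta <- acos(pmin(1, pmax(-1, ca)))
  L <- sum(nn)
  soam_v <- sum(theta) / L
  pad_v <- sum(theta * (nn[-nv] + nn[-1L]) / 2) / L
  k <- (e + 1L):(n - e)
  a <- sqrt(rowSums((q[k - e, , drop = FALSE] - q[k, , drop = FALSE])^2))
  b <- sqrt(rowSums((q[k, , drop = FALSE] - q[k + e, , drop = FALSE])^2))
  base <- sqrt(rowSums((q[k - e, , drop = FALSE] -
                          q[k + e, , drop = FALSE])^2))
  if (any(base < eps_den))
    stop("degenerate triangle in I2e: curve folds back on itself")
  c(soam = soam_v, pad = pad_v, i2e = mean((a + b) / base),
    arc_length_px = L, n_points = n)
}

#' Compute all three tortuosity indices of a centerline segment
#'
#' Resamples the polyline at `config$resample_spacing_px` and computes SOAM,
#' PAD and I2e, together with provenance fields identifying the segment.
#'
#' @param p a raw [polyline][as_polyline] (traced or synthetic centerline).
#' @param config a [metric_config()].
#' @param subject_id,eye,site,segment_id optional provenance, carried into
#'   the result.
#' @return an object of class `tortuosity`: a list with elements `soam`
#'   (rad/px), `pad`, `i2e`, `n_points`, `arc_length_px`,
#'   `resample_spacing_px` and the provenance fields.
#' @examples
#' straight <- as_polyline(cbind(seq(0, 400, 5), 0))
#' compute_tortuosity(straight)  # (0, 0, 1)
#' @export
compute_tortuosity <- function(p, config = metric_config(),
                               subject_id = NA_character_,
                               eye = NA_character_, site = NA_character_,
                               segment_id = NA_character_) {
  stopifnot(inherits(config, "metric_config"))
  m <- poly_mat(as_polyline(p))
  v <- tort_metrics(m, config$resample_spacing_px, config$i2e_step,
                    config$min_points, config$eps_den)
  structure(list(soam = unname(v["soam"]), pad = unname(v["pad"]),
                 i2e = unname(v["i2e"]),
                 n_points = unname(v["n_points"]),
                 arc_length_px = unname(v["arc_length_px"]),
                 resample_spacing_px = config$resample_spacing_px,
                 subject_id = subject_id, eye = eye, site = site,
                 segment_id = segment_id),
            class = "tortuosity")
}

#' @export
print.tortuosity <- function(x, ...) {
  cat("Tortuosity of one vessel segment\n")
  if (!is.na(x$subject_id) || !is.na(x$site))
    cat(sprintf("  segment: %s / %s / %s / %s\n", x$subject_id, x$eye,
                x$site, x$segment_id))
  cat(sprintf("  arc length: %.1f px (%d samples at %.3g px)\n",
              x$arc_length_px, x$n_points, x$resample_spacing_px))
  cat(sprintf("  SOAM: %.5f rad/px   PAD: %.5f   I2e: %.5f\n",
              x$soam, x$pad, x$i2e))
  invisible(x)
}

#' @export
as.data.frame.tortuosity <- function(x, ...) {
  data.frame(subject_id = x$subject_id, eye = x$eye, site = x$site,
             segment_id = x$segment_id, arc_length_px = x$arc_length_px,
             soam = x$soam, pad = x$pad, i2e = x$i2e,
             stringsAsFactors = FALSE)
}

#' Tortuosity metrics for a set of traces
#'
#' Applies [compute_tortuosity()] to every trace of a cohort (as returned by
#' [gen_cohort()]) or to a plain list of polylines, and binds the results
#' into the package's metrics table (one row per segment).
#'
#' @param traces a `vessel_cohort`, or a list whose elements are polylines or
#'   lists with a `polyline` element plus optional `subject_id`, `eye`,
#'   `site`, `segment_id` fields.
#' @param config a [metric_config()].
#' @return a data frame with columns `subject_id, eye, site, segment_id,
#'   arc_length_px, soam, pad, i2e`.
#' @export
tortuosity_table <- function(traces, config = metric_config()) {
  if (inherits(traces, "vessel_cohort")) traces <- traces$traces
  if (inherits(traces, "polyline")) traces <- list(traces)
  norm <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (inherits(tr, "polyline") || is.matrix(tr))
      tr <- list(polyline = tr)
    tr$segment_id <- tr$segment_id %||% names(traces)[i] %||% as.character(i)
    if (!nzchar(tr$segment_id)) tr$segment_id <- as.character(i)
    tr
  })
  vals <- vapply(norm, function(tr)
    tort_metrics(poly_mat(as_polyline(tr$polyline)),
                 config$resample_spacing_px, config$i2e_step,
                 config$min_points, config$eps_den),
    numeric(5L))
  field <- function(f, default) vapply(norm, function(tr)
    as.character(tr[[f]] %||% default), character(1L))
  data.frame(subject_id = field("subject_id", NA_character_),
             eye = field("eye", NA_character_),
             site = field("site", NA_character_),
             segment_id = field("segment_id", NA_character_),
             arc_length_px = vals["arc_length_px", ],
             soam = vals["soam", ], pad = vals["pad", ],
             i2e = vals["i2e", ], stringsAsFactors = FALSE)
}
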