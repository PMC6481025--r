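#' Polylines: ordered 2-D point sequences in pixel coordinates
#'
#' A polyline is the package's representation of a vessel centerline segment:
#' an `n x 2` numeric matrix with columns `x` (rightward) and `y` (downward),
#' pixel units, 0-based pixel centers. `as_polyline()` validates and
#' normalizes input (a matrix or a data frame with `x`/`y` columns), dropping
#' zero-length steps so consecutive points are always distinct.
#'
#' @param p an `n x 2` numeric matrix, or a data frame with columns `x`, `y`.
#' @return an object of class `polyline` (a numeric matrix).
#' @examples
#' p <- as_polyline(cbind(x = c(0, 1, 1), y = c(0, 0, 1)))
#' arc_length(p)
#' chord_length(p)
#' @export
as_polyline <- function(p) {
  if (inherits(p, "polyline")) return(p)
  if (is.data.frame(p)) {
    if (!all(c("x", "y") %in% names(p)))
      stop("data-frame polyline needs columns 'x' and 'y'")
    p <- cbind(p$x, p$y)
  }
  if (!is.matrix(p) || ncol(p) != 2L)
    stop("a polyline is an n x 2 matrix of (x, y) pixel coordinates")
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("polyline coordinates must be finite")
  if (nrow(p) >= 2L) {
    keep <- c(TRUE, rowSums(abs(p[-1L, , drop = FALSE] -
                                  p[-nrow(p), , drop = FALSE])) > 0)
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) < 2L) stop("a polyline needs at least 2 distinct points")
  dimnames(p) <- list(NULL, c("x", "y"))
  class(p) <- c("polyline", class(p))
  p
}

poly_mat <- function(p) {
  m <- unclass(p)
  attr(m, "seeds") <- NULL
  m
}

#' @rdname as_polyline
#' @export
arc_length <- function(p) {
  m <- poly_mat(as_polyline(p))
  sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

#' @rdname as_polyline
#' @export
chord_length <- function(p) {
  m <- poly_mat(as_polyline(p))
  sqrt(sum((m[nrow(m), ] - m[1L, ])^2))
}

# segment lengths |p_{k+1} - p_k| as a plain vector
seg_lengths <- function(m) {
  sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Places points along the piecewise-linear interpolant of `p` at uniform
#' arc-length steps. The original first and last points are preserved
#' exactly; when the total length is not a multiple of `spacing`, the
#' remainder is split symmetrically between the two end intervals (interior
#' samples are anchored at the curve midpoint), so resampling commutes with
#' reversing the point order — a property the tortuosity metrics inherit.
#'
#' Turning-angle tortuosity indices depend on the sampling of the curve, so
#' every metric in this package is computed after resampling at a fixed
#' spacing (5 px by default, see [metric_config()]) to make values comparable
#' across segments of different lengths.
#'
#' @param p a [polyline][as_polyline].
#' @param spacing target arc-length spacing, pixels (> 0).
#' @return a `polyline` with points at uniform spacing.
#' @examples
#' p <- as_polyline(cbind(c(0, 100), c(0, 0)))
#' nrow(resample_polyline(p, 5))  # 21 points
#' @export
resample_polyline <- function(p, spacing) {
  p <- as_polyline(p)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number")
  m <- poly_mat(p)
  flip <- reversed_orientation(m)
  if (flip) m <- m[nrow(m):1L, , drop = FALSE]
  s <- c(0, cumsum(seg_lengths(m)))
  L <- s[length(s)]
  targets <- resample_targets(L, spacing)
  out <- cbind(stats::approx(s, m[, 1L], xout = targets)$y,
               stats::approx(s, m[, 2L], xout = targets)$y)
  out[1L, ] <- m[1L, ]
  out[nrow(out), ] <- m[nrow(m), ]
  if (flip) out <- out[nrow(out):1L, , drop = FALSE]
  as_polyline(out)
}

# Deterministic orientation rule (lexicographic comparison of the two
# endpoints): resampling a polyline and resampling its reversal then give
# bitwise-mirrored results, so downstream metrics are exactly
# reversal-invariant instead of agreeing only to float-summation error.
reversed_orientation <- function(m) {
  a <- m[1L, ]; b <- m[nrow(m), ]
  if (a[1L] != b[1L]) return(a[1L] > b[1L])
  if (a[2L] != b[2L]) return(a[2L] > b[2L])
  FALSE
}

# Arc-length sample positions on [0, L]: interior points at `spacing` steps
# anchored at the midpoint L/2, endpoints always included. The position set
# is symmetric under s -> L - s, which makes resampling commute with
# reversal; when L is a multiple of spacing this reduces to 0, spacing,
# 2*spacing, ..., L.
resample_targets <- function(L, spacing) {
  k <- floor(L / 2 / spacing + 1e-9)
  targets <- L / 2 + (-k:k) * spacing
  if (targets[1L] > 1e-9) targets <- c(0, targets)
  else targets[1L] <- 0
  if (L - targets[length(targets)] > 1e-9) targets <- c(targets, L)
  else targets[length(targets)] <- L
  targets
}

#' Test a polyline for self-intersection
#'
#' Checks every pair of non-adjacent segments for a proper crossing (shared
#' endpoints of adjacent segments do not count).
#'
#' @param p a [polyline][as_polyline].
#' @return `TRUE` if any two non-adjacent segments cross.
#' @export
self_intersects <- function(p) {
  m <- poly_mat(as_polyline(p))
  ns <- nrow(m) - 1L
  if (ns < 3L) return(FALSE)
  a <- m[1:ns, , drop = FALSE]        # segment starts
  b <- m[2:(ns + 1L), , drop = FALSE] # segment ends
  idx <- which(outer(seq_len(ns), seq_len(ns), function(i, j) j > i + 1L),
               arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Rigid-motion / similarity transform of a polyline
#'
#' Applies rotation by `angle` (radians, counter-clockwise in the x-right /
#' y-down pixel convention this is clockwise on screen) about `center`,
#' isotropic scaling, then translation. Used in tests of the metrics'
#' invariance properties and to place synthetic curves inside an image.
#'
#' @param p a [polyline][as_polyline].
#' @param dx,dy translation, pixels.
#' @param angle rotation angle, radians.
#' @param scale isotropic scale factor (> 0).
#' @param center length-2 rotation/scaling center, default the origin.
#' @return the transformed `polyline`.
#' @export
transform_polyline <- function(p, dx = 0, dy = 0, angle = 0, scale = 1,
                               center = c(0, 0)) {
  m <- poly_mat(as_polyline(p))
  if (scale <= 0) stop("scale must be positive")
  m <- sweep(m, 2L, center)
  if (angle != 0) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
    m <- m %*% t(R)
  }
  m <- m * scale
  m <- sweep(m, 2L, center + c(dx, dy), "+")
  as_polyline(m)
}

#' @export
print.polyline <- function(x, ...) {
  m <- poly_mat(x)
  cat(sprintf("<polyline: %d points, arc length %.1f px, chord %.1f px>\n",
              nrow(m), arc_length(x), chord_length(x)))
  invisible(x)
}

#' @export
plot.polyline <- function(x, ..., asp = 1) {
  m <- poly_mat(x)
  plot(m[, 1L], m[, 2L], type = "l", xlab = "x (px)", ylab = "y (px)",
       ylim = rev(range(m[, 2L])), asp = asp, ...)
  invisible(x)
}

#' @export
lines.polyline <- function(x, ...) {
  m <- poly_mat(x)
  graphics::lines(m[, 1L], m[, 2L], ...)
  invisible(x)
}
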