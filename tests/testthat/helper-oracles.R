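# Independent oracles, kept deliberately naive: these re-derive expected
# values by brute force and must not share code with the package internals.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2L, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Closed-form OLS via the normal equations.
ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, slope_se = se,
       t_statistic = tval,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Naive loop-based tortuosity metrics on an already-sampled polyline
# (no resampling): triplet-by-triplet arithmetic.
naive_metrics <- function(m, e = 2) {
  n <- nrow(m)
  L <- 0
  for (k in 1:(n - 1)) L <- L + sqrt(sum((m[k + 1, ] - m[k, ])^2))
  soam_sum <- 0; pad_sum <- 0
  for (k in 2:(n - 1)) {
    v1 <- m[k, ] - m[k - 1, ]
    v2 <- m[k + 1, ] - m[k, ]
    ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    th <- acos(min(1, max(-1, ct)))
    soam_sum <- soam_sum + th
    pad_sum <- pad_sum + th * (sqrt(sum(v1^2)) + sqrt(sum(v2^2))) / 2
  }
  terms <- c()
  for (k in (e + 1):(n - e)) {
    a <- sqrt(sum((m[k - e, ] - m[k, ])^2))
    b <- sqrt(sum((m[k, ] - m[k + e, ])^2))
    cc <- sqrt(sum((m[k - e, ] - m[k + e, ])^2))
    terms <- c(terms, (a + b) / cc)
  }
  list(soam = soam_sum / L, pad = pad_sum / L, i2e = mean(terms))
}

# Minimum distance from each row of pts to a densely sampled reference curve.
dist_to_curve <- function(pts, ref) {
  vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2)),
    numeric(1))
}
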