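# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force even-odd point-in-polygon (crossing number), boundary-inclusive.
brute_inpolygon <- function(px, py, xp, yp, eps = 1e-9) {
  n <- length(xp)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- xp[i]; y1 <- yp[i]; x2 <- xp[j]; y2 <- yp[j]
      # on-segment check
      d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
      if (d < eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) return(TRUE)
      if ((y1 > y) != (y2 > y)) {
        xin <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (xin > x) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Two-sided p-value of the t distribution by numerical integration of its
# density (independent of stats::pt).
t_p_integrate <- function(tstat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

# Closed-form Pearson r.
pearson_closed_form <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Exact two-sided binomial p at p0 = 1/2 (sum of tail masses <= observed).
binom_two_sided <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(probs[probs <= probs[k + 1] + 1e-12]))
}

# Analytic rotation of (row, col) points.
rotate_rc <- function(p, angle_deg, center) {
  th <- angle_deg * pi / 180
  dr <- p[1] - center[1]; dc <- p[2] - center[2]
  c(cos(th) * dr - sin(th) * dc + center[1],
    sin(th) * dr + cos(th) * dc + center[2])
}

# Small mask builders.
blank_mask <- function(h = 32, w = h) matrix(FALSE, h, w)

disk_mask <- function(h, center, radius) {
  rr <- matrix(seq_len(h), h, h)
  cc <- t(rr)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

annulus_mask <- function(h, center, r_in, r_out) {
  disk_mask(h, center, r_out) & !disk_mask(h, center, r_in)
}

# Measure a phantom through the standard preparation path.
measure_phantom <- function(ph, method = "tda", ...) {
  res <- measure_masks(ph$apical_mask, ph$coronal_mask, method = method, ...)
  res[[method]]$measurement
}
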