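# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, closed forms) so they stay independent of the package's
# vectorized implementations.

# Brute-force two-sample / paired t statistic and two-tailed p from the
# closed-form definitions.
oracle_t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  if (paired) {
    d <- a - b
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    df <- n - 1
  } else if (welch) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  } else {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-tailed p for |t| at df by numerical integration of the t density.
oracle_t_p_quadrature <- function(t_abs, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, t_abs, Inf, rel.tol = 1e-12)$value
}

# Polygon perimeter by an explicit vertex walk.
oracle_polygon_walk <- function(poly) {
  n <- nrow(poly)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    tot <- tot + sqrt((poly$x[j] - poly$x[i])^2 + (poly$y[j] - poly$y[i])^2)
  }
  tot
}

# OLS slope/intercept by the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Horizontal center-line ROI through a movie's lumen.
center_roi <- function(stack, x_pad = 5, thickness_um = 3) {
  h <- dim(stack)[2]; w <- dim(stack)[3]
  line_roi(data.frame(x = c(x_pad, w - x_pad), y = c((h + 1) / 2, (h + 1) / 2)),
           thickness_um = thickness_um, kind = "axial")
}

# Normalized kymograph with periodic diagonal streaks of known slope
# (px/frame), built directly rather than through the movie generator.
streak_kymograph <- function(n_t = 60, width = 120, slope = 2,
                             n_streaks = 5, sigma = 1.5,
                             pixel_size_um = 0.313,
                             frame_interval_s = 0.177) {
  x0 <- seq(1, width, length.out = n_streaks + 1)[-1]
  vals <- matrix(0, n_t, width)
  xs <- seq_len(width)
  for (t in seq_len(n_t)) {
    for (c0 in x0) {
      d <- (xs - (c0 + slope * (t - 1))) %% width
      d <- pmin(d, width - d)
      vals[t, ] <- vals[t, ] + exp(-d^2 / (2 * sigma^2))
    }
  }
  normalize_kymograph(kymograph(vals, pixel_size_um, frame_interval_s))
}

# Rasterized filled disk / rectangle / rotated ellipse label images.
raster_disk <- function(radius, size = 2 * radius + 32) {
  c0 <- (size + 1) / 2
  xy <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix(as.integer((xy$r - c0)^2 + (xy$c - c0)^2 <= radius^2), size, size)
}

raster_rect <- function(h, w, pad = 16) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1L
  m
}

raster_ellipse <- function(a, b, size = 2 * ceiling(a) + 32) {
  c0 <- (size + 1) / 2
  xy <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix(as.integer(((xy$c - c0) / a)^2 + ((xy$r - c0) / b)^2 <= 1),
         size, size)
}
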