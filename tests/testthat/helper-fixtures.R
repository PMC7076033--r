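# Fixtures built in code: gratings, rotations, simple shapes.

# cosine grating with integer wavevector (kx, ky): exact two-impulse DFT
grating <- function(N, kx, ky) {
  x <- matrix(rep(0:(N - 1), each = N), N, N)
  y <- matrix(rep(0:(N - 1), times = N), N, N)
  cos(2 * pi * (kx * x + ky * y) / N)
}

# lattice-exact 90-degree counterclockwise rotation
rot90cc <- function(m) t(m)[, ncol(m):1]

# bilinear rotation about the image center (degrees, counterclockwise)
rotate_bilinear <- function(im, deg) {
  N <- nrow(im)
  c0 <- (N - 1) / 2
  th <- deg * pi / 180
  gx <- matrix(rep(0:(N - 1), each = N), N, N) - c0
  gy <- matrix(rep(0:(N - 1), times = N), N, N) - c0
  sx <- cos(th) * gx + sin(th) * gy + c0
  sy <- -sin(th) * gx + cos(th) * gy + c0
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xx, yy) {
    ok <- xx >= 0 & xx <= N - 1 & yy >= 0 & yy <= N - 1
    v <- matrix(0, N, N)
    v[ok] <- im[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
}

# rasterized filled disk as a one-label mask
disk_mask <- function(radius, pad = 5) {
  n <- 2 * (radius + pad) + 1
  c0 <- radius + pad + 1
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  matrix(as.integer((x - c0)^2 + (y - c0)^2 <= radius^2), n, n)
}

# rasterized filled ellipse (semi-axes a >= b, orientation in degrees)
ellipse_mask <- function(a, b, deg = 0, pad = 5) {
  n <- 2 * ceiling(a + pad) + 1
  c0 <- ceiling(a + pad) + 1
  x <- matrix(rep(seq_len(n), each = n), n, n) - c0
  y <- matrix(rep(seq_len(n), times = n), n, n) - c0
  th <- deg * pi / 180
  u <- (x * cos(th) + y * sin(th)) / a
  v <- (-x * sin(th) + y * cos(th)) / b
  matrix(as.integer(u^2 + v^2 <= 1), n, n)
}

# axis-aligned square mask of side s with top-left corner (r0, c0), 1-based
square_mask <- function(n, s, r0, c0, label = 1L) {
  m <- matrix(0L, n, n)
  m[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- label
  m
}

# brute-force wedge sums over all 180 candidate directions
brute_wedge_sums <- function(p) {
  vapply(0:179, function(d) {
    s <- 0
    for (th in 0:359) {
      r <- (th - d) %% 180
      if (r < 45 || r >= 135) s <- s + p[th + 1]
    }
    s
  }, numeric(1))
}

# brute-force normalized circular correlogram (independent double loop)
brute_correlogram <- function(f, g) {
  fv <- f - mean(f); gv <- g - mean(g)
  fv <- fv / sqrt(sum(fv^2)); gv <- gv / sqrt(sum(gv^2))
  out <- numeric(360)
  for (s in 0:359) {
    acc <- 0
    for (th in 0:359) acc <- acc + fv[th + 1] * gv[(th + s) %% 360 + 1]
    out[s + 1] <- acc
  }
  out
}
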