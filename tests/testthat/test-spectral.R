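# Windowing, angular spectrum, orientation partition and CFOI.

test_that("gaussian window zeroes a constant image and weights by the stated profile", {
  img <- matrix(3.7, 64, 64)
  expect_true(all(gaussian_window(img) == 0))
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64, 64)
  w <- gaussian_window(img, sigma_fraction = 1 / 6)
  N <- 64; sig <- N / 6; c0 <- (N - 1) / 2
  corner_w <- exp(-(2 * c0^2) / (2 * sig^2))
  expect_equal(w[1, 1] / (img[1, 1] - mean(img)), corner_w,
               tolerance = 1e-12)
  expect_error(gaussian_window(matrix(0, 4, 6)),
               class = "validation_error")
})

test_that("windowing suppresses off-ridge spectral leakage of a line", {
  # a tilted line truncated by the image border leaks energy across the
  # spectrum unless the border discontinuity is windowed away
  sp <- fiber_field_spec(width_px = 128, mean_orientation_deg = 30,
                         concentration = 1e6, n_fibers = 1,
                         background_noise_sd = 0, seed = 1L)
  img <- make_fiber_texture(sp)
  off_ridge <- function(im, window) {
    p <- as.numeric(fiber_profile(im, window = window))
    ridge <- which(pmin((0:359 - 120) %% 180, (120 - 0:359) %% 180) <= 8)
    sum(p[-ridge]) / sum(p)
  }
  expect_lt(off_ridge(img, TRUE), off_ridge(img, FALSE))
})

test_that("a pure grating concentrates the profile at its wavevector angle", {
  N <- 128
  img <- grating(N, kx = 4, ky = 7)  # period 14.7 px, inside the low-pass
  p <- as.numeric(fiber_profile(img, window = FALSE))
  ang <- floor((atan2(7, 4) * 180 / pi) %% 360)  # 60
  expect_equal(ang, 60)
  expect_gt(sum(p[c(ang, ang + 180) + 1]) / sum(p), 0.99)
})

test_that("degenerate images are rejected", {
  expect_error(fiber_profile(matrix(1, 64, 64)),
               class = "degenerate_input_error")
  expect_error(cfoi(angular_profile(rep(0, 360), "fiber_magnitude")),
               class = "degenerate_input_error")
})

test_that("fiber profiles are exactly centro-symmetric", {
  for (s in 1:3) {
    img <- make_fiber_texture(fiber_field_spec(width_px = 128,
                                               n_fibers = 40,
                                               concentration = 5,
                                               seed = s))
    p <- as.numeric(fiber_profile(img))
    expect_identical(p, p[((0:359 + 180) %% 360) + 1])
  }
})

test_that("white-noise images give near-flat profiles", {
  # bin sums inherit the deterministic lattice count structure of the
  # annulus (count CV ~ 0.22), so flatness of the image-driven part is
  # checked on the per-sample (count-normalized) angular density
  N <- 512
  k <- c(0:(N / 2 - 1), -(N / 2):-1)
  KX <- matrix(rep(k, each = N), N, N)
  KY <- matrix(rep(k, times = N), N, N)
  r2 <- KX^2 + KY^2
  half <- r2 >= 4 & r2 <= (N / 10)^2 & (KY > 0 | (KY == 0 & KX > 0))
  b <- floor((atan2(KY[half], KX[half]) * 180 / pi) %% 360) %% 360
  cnt <- numeric(360)
  tab <- table(b)
  cnt[as.integer(names(tab)) + 1] <- tab
  cnt <- cnt + cnt[((0:359 + 180) %% 360) + 1]
  pop <- cnt > 0  # a few near-axis bins hold no lattice point at r <= N/10
  cvs <- vapply(1:20, function(s) {
    set.seed(s)
    p <- as.numeric(fiber_profile(matrix(rnorm(N * N), N, N)))[pop] /
      cnt[pop]
    sd(p) / mean(p)
  }, numeric(1))
  expect_true(all(cvs < 0.2))
  # and the wedge-aggregated statistic sees white noise as isotropic
  set.seed(1)
  expect_gt(cfoi(fiber_profile(matrix(rnorm(N * N), N, N))), 0.9)
})

test_that("major orientation matches a brute-force wedge search", {
  set.seed(42)
  for (i in 1:5) {
    p <- runif(360)
    p <- p + p[((0:359 + 180) %% 360) + 1]  # symmetrize
    prof <- angular_profile(p, "fiber_magnitude")
    S <- brute_wedge_sums(p)
    part <- major_orientation(prof)
    expect_identical(part$major_deg, which.max(S) - 1L)
    expect_equal(part$S_major, max(S), tolerance = 1e-12)
    expect_equal(part$S_major + part$S_minor, sum(p), tolerance = 1e-12)
  }
})

test_that("wedge ties break to the smallest angle", {
  p <- rep(1, 360)
  expect_identical(major_orientation(
    angular_profile(p, "fiber_magnitude"))$major_deg, 0L)
  q <- rep(0, 360)
  q[c(10, 190, 100, 280) + 1] <- 1  # equal impulse pairs at 10 and 100
  S <- brute_wedge_sums(q)
  expect_equal(S[10 + 1], S[100 + 1])
  got <- major_orientation(angular_profile(q, "fiber_magnitude"))$major_deg
  # smallest direction among all tied maximizers wins
  expect_identical(got, min(which(S == max(S))) - 1L)
})

test_that("CFOI hits its analytic extremes", {
  expect_equal(cfoi(angular_profile(rep(1, 360), "fiber_magnitude")), 1)
  d <- rep(0, 360); d[c(30, 210) + 1] <- 5
  prof <- angular_profile(d, "fiber_magnitude")
  expect_equal(cfoi(prof), 0)
  # the whole tied run of wedge centers contains the impulse axis
  part <- major_orientation(prof)
  expect_true(part$major_deg %in% c(0:75, 166:179))
})

test_that("CFOI stays in [0, 1] for arbitrary symmetric profiles", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(360)^3
    p <- p + p[((0:359 + 180) %% 360) + 1]
    v <- cfoi(angular_profile(p, "fiber_magnitude"))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("90-degree rotation maps the partition exactly and preserves CFOI", {
  img <- make_fiber_texture(fiber_field_spec(concentration = 30, seed = 3))
  r1 <- image_cfoi(img)
  r2 <- image_cfoi(rot90cc(img))
  expect_equal(r2$cfoi, r1$cfoi, tolerance = 1e-6)
  expect_identical(r2$major_deg, (r1$major_deg + 90L) %% 180L)
})

test_that("CFOI is approximately invariant under a 30-degree rotation", {
  img <- make_fiber_texture(fiber_field_spec(concentration = 30, seed = 3))
  r1 <- image_cfoi(img)
  r3 <- image_cfoi(rotate_bilinear(img, 30))
  expect_lt(abs(r3$cfoi - r1$cfoi), 0.05)
})

test_that("oriented textures give low CFOI with the expected major axis", {
  r <- image_cfoi(make_fiber_texture(
    fiber_field_spec(concentration = 50, mean_orientation_deg = 30,
                     seed = 1)))
  # spectral ridge is orthogonal to the real-space fiber direction
  expect_lt(abs(((r$major_deg - 120 + 90) %% 180) - 90), 5)
  expect_lt(r$cfoi, 0.5)
  r0 <- image_cfoi(make_fiber_texture(
    fiber_field_spec(concentration = 0, seed = 1)))
  expect_gt(r0$cfoi, 0.9)
})
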