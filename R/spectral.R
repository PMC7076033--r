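# Collagen-fiber orientation from windowed 2D Fourier spectra.
#
# The angular magnitude profile f(theta) is obtained by transforming a
# square grayscale SHG crop, low-pass filtering the frequency plane
# (periods >= 10 px retained by default), and summing spectral magnitude
# into 1-degree polar bins. CFOI is the minor/major wedge ratio of that
# profile: 1 = isotropic fibers, -> 0 = parallel fibers.

#' Construct an angular profile
#'
#' A 360-bin circular sequence of nonnegative values indexed by integer
#' degree. Fiber magnitude profiles are centro-symmetric
#' (\code{f(theta) = f(theta + 180)}).
#'
#' @param values numeric vector of length 360, nonnegative.
#' @param kind \code{"fiber_magnitude"} or \code{"cell_radius"}.
#' @return an \code{angular_profile} object.
#' @export
angular_profile <- function(values, kind = c("fiber_magnitude",
                                             "cell_radius")) {
  kind <- match.arg(kind)
  if (length(values) != 360L || any(!is.finite(values)) || any(values < 0))
    stop_osteo("an angular profile has 360 finite nonnegative values",
               "validation_error")
  structure(as.numeric(values), kind = kind, class = "angular_profile")
}

#' Apply mean subtraction and a circular Gaussian window
#'
#' The image mean is subtracted, then pixel (x, y) is weighted by
#' \code{exp(-((x-cx)^2+(y-cy)^2) / (2*sigma^2))} with
#' \code{sigma = sigma_fraction * N}. This suppresses the edge
#' discontinuities that would otherwise leak energy across the Fourier
#' spectrum.
#'
#' @param img square numeric matrix.
#' @param sigma_fraction window scale as a fraction of the image side
#'   (default 1/6).
#' @return windowed matrix (zero mean before weighting).
#' @export
gaussian_window <- function(img, sigma_fraction = 1 / 6) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop_osteo("'img' must be a square matrix", "validation_error")
  check_scalar(sigma_fraction, "sigma_fraction", 0, strict_lower = TRUE)
  N <- nrow(img)
  sig <- sigma_fraction * N
  d <- (0:(N - 1)) - (N - 1) / 2  # symmetric center: 90-degree rotations commute
  w <- exp(-d^2 / (2 * sig^2))
  (img - mean(img)) * outer(w, w)
}

#' Angular magnitude profile of the fiber spectrum, f(theta)
#'
#' Computes the 2D discrete Fourier transform of the (optionally windowed)
#' image, takes the magnitude, removes the DC term and the innermost radial
#' ring (radius < 2, dominated by residual windowing leakage), retains only
#' spatial frequencies whose period is at least \code{lowpass_period_px}
#' pixels, and sums the retained magnitude into 1-degree polar bins.
#' Antipodal frequency samples are binned jointly, so the output satisfies
#' \code{f(theta) == f(theta + 180)} exactly.
#'
#' @param img square numeric matrix (grayscale SHG crop).
#' @param lowpass_period_px shortest retained spatial period, pixels
#'   (default 10, about 3.2 um at 0.32 um/px).
#' @param window apply \code{\link{gaussian_window}} first (default TRUE).
#' @param sigma_fraction passed to \code{\link{gaussian_window}}.
#' @return an \code{angular_profile} of kind \code{fiber_magnitude}.
#' @export
fiber_profile <- function(img, lowpass_period_px = 10, window = TRUE,
                          sigma_fraction = 1 / 6) {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop_osteo("'img' must be a square matrix", "validation_error")
  check_scalar(lowpass_period_px, "lowpass_period_px", 0,
               strict_lower = TRUE)
  N <- nrow(img)
  w <- if (window) gaussian_window(img, sigma_fraction) else img - mean(img)
  if (sd(w) == 0)
    stop_osteo("image has zero variance; angular profile undefined",
               "degenerate_input_error")
  mag <- Mod(fft(w))
  # signed frequency indices; matrix is [row = ky, col = kx]
  k <- c(0:(N %/% 2 - 1), -(N %/% 2):-1)
  KX <- matrix(rep(k, each = N), N, N)
  KY <- matrix(rep(k, times = N), N, N)
  r2 <- KX^2 + KY^2
  rmax <- N / lowpass_period_px
  half <- r2 >= 4 & r2 <= rmax^2 & (KY > 0 | (KY == 0 & KX > 0))
  if (!any(half) || all(mag[half] == 0))
    stop_osteo("no spectral energy in the retained band",
               "degenerate_input_error")
  ang <- (atan2(KY[half], KX[half]) * 180 / pi) %% 360
  b <- floor(ang) %% 360
  vals <- numeric(360)
  sums <- rowsum(mag[half], group = b)
  vals[as.integer(rownames(sums)) + 1L] <- sums[, 1]
  # joint antipodal binning: exact centro-symmetry by construction
  full <- vals + vals[((0:359 + 180) %% 360) + 1L]
  angular_profile(full, "fiber_magnitude")
}

#' Major/minor orientation partition of a fiber profile
#'
#' For every candidate direction d in 0..179 degrees, sums the profile over
#' the 90-degree-wide double wedge centered on d and its antipode
#' (bins theta with \code{((theta - d + 45) mod 180) < 90}). The major
#' orientation maximizes this sum; ties break to the smallest angle. The
#' minor orientation is the perpendicular, and the two wedge sums partition
#' the total profile mass exactly.
#'
#' @param profile an \code{angular_profile} of kind \code{fiber_magnitude}.
#' @return list with \code{major_deg}, \code{S_major}, \code{S_minor}.
#' @export
major_orientation <- function(profile) {
  stopifnot(inherits(profile, "angular_profile"))
  p <- as.numeric(profile)
  if (all(p == 0))
    stop_osteo("all-zero profile", "degenerate_input_error")
  th <- 0:359
  S <- vapply(0:179,
              function(d) sum(p[((th - d + 45) %% 180) < 90]),
              numeric(1))
  major <- which.max(S) - 1L
  S_major <- S[major + 1L]
  list(major_deg = major, S_major = S_major, S_minor = sum(p) - S_major)
}

#' Collagen fiber orientation index (CFOI)
#'
#' The ratio of the summed spectral magnitude in the minor orientation
#' wedge to that in the major orientation wedge. Since the major wedge is
#' the maximizing one, CFOI lies in [0, 1]: 1 means isotropic fibers, 0
#' means all spectral mass on a single axis (perfectly parallel fibers).
#'
#' @param profile an \code{angular_profile} of kind \code{fiber_magnitude}.
#' @return real in [0, 1].
#' @export
cfoi <- function(profile) {
  part <- major_orientation(profile)
  if (part$S_major == 0)
    stop_osteo("degenerate profile: zero major-wedge mass",
               "degenerate_input_error")
  part$S_minor / part$S_major
}

#' CFOI of an image in one call
#'
#' Convenience wrapper: \code{\link{fiber_profile}} then \code{\link{cfoi}}
#' and \code{\link{major_orientation}}.
#'
#' @inheritParams fiber_profile
#' @return list with \code{cfoi}, \code{major_deg}, and \code{profile}.
#' @export
image_cfoi <- function(img, lowpass_period_px = 10, window = TRUE,
                       sigma_fraction = 1 / 6) {
  prof <- fiber_profile(img, lowpass_period_px, window, sigma_fraction)
  part <- major_orientation(prof)
  list(cfoi = part$S_minor / part$S_major, major_deg = part$major_deg,
       profile = prof)
}
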