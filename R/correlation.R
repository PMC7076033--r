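# Orientation correlated index (OCI): circular cross-correlation between
# the fiber spectral profile f(theta) and the cell radius profile g(theta),
# evaluated at a 90-degree shift. The fiber spectral peak is orthogonal to
# the real-space fiber direction, so a high OCI means the cells are
# elongated along the fibers and both distributions are anisotropic.

#' Orientation correlated index between fiber and cell profiles
#'
#' Both profiles are mean-centered and l2-normalized, so the correlation at
#' every shift lies in [-1, 1] (Cauchy-Schwarz). The OCI is the normalized
#' circular cross-correlation
#' \code{sum_theta f(theta) * g((theta + tau) mod 360)} at \code{tau = 90}
#' degrees.
#'
#' @param f an \code{angular_profile} of kind \code{fiber_magnitude}.
#' @param g an \code{angular_profile} of kind \code{cell_radius}.
#' @param tau_deg integer shift in degrees at which the OCI is read off
#'   (default 90).
#' @return list with \code{oci}, \code{tau_deg} and
#'   \code{full_correlogram} (length 360, correlation at every shift).
#' @export
oci <- function(f, g, tau_deg = 90L) {
  stopifnot(inherits(f, "angular_profile"), inherits(g, "angular_profile"))
  check_scalar(tau_deg, "tau_deg", integer = TRUE)
  tau <- as.integer(tau_deg) %% 360L
  fv <- as.numeric(f) - mean(f)
  gv <- as.numeric(g) - mean(g)
  nf <- sqrt(sum(fv^2)); ng <- sqrt(sum(gv^2))
  if (nf == 0 || ng == 0)
    stop_osteo("zero-variance profile: correlation undefined",
               "degenerate_input_error")
  fv <- fv / nf; gv <- gv / ng
  correlogram <- vapply(0:359, function(s) {
    sum(fv * gv[((0:359 + s) %% 360) + 1L])
  }, numeric(1))
  list(oci = correlogram[tau + 1L], tau_deg = tau,
       full_correlogram = correlogram)
}

#' Field-level and per-cell OCI from an image and a mask
#'
#' The fiber profile is computed once for the whole crop; the cell radius
#' profile either per cell (\code{per_cell} rows) or as the mean radius
#' profile over all cells (\code{field} value).
#'
#' @param img square grayscale matrix (SHG crop).
#' @param mask integer label matrix on the same grid.
#' @param tau_deg shift in degrees (default 90).
#' @param lowpass_period_px passed to \code{\link{fiber_profile}}.
#' @return list with \code{field} (OCI against the mean radius profile)
#'   and \code{per_cell} (data.frame label, oci).
#' @export
image_oci <- function(img, mask, tau_deg = 90L, lowpass_period_px = 10) {
  f <- fiber_profile(img, lowpass_period_px = lowpass_period_px)
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0)
    stop_osteo("mask contains no labeled regions", "empty_input_error")
  profs <- lapply(labs, function(l) radius_profile(mask, l))
  per_cell <- data.frame(
    label = labs,
    oci = vapply(profs, function(g) oci(f, g, tau_deg)$oci, numeric(1)))
  gbar <- angular_profile(Reduce(`+`, lapply(profs, as.numeric)) /
                            length(profs), "cell_radius")
  list(field = oci(f, gbar, tau_deg)$oci, per_cell = per_cell)
}
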