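# Per-cell shape metrics from labeled masks: eccentricity of the
# moment-equivalent ellipse and the angular radius profile g(theta).

region_pixels <- function(mask, label) {
  if (!is.matrix(mask))
    stop_osteo("'mask' must be an integer label matrix", "validation_error")
  check_scalar(label, "label", lower = 1, integer = TRUE)
  px <- which(mask == label, arr.ind = TRUE)
  if (nrow(px) == 0)
    stop_osteo(sprintf("label %d not present in mask", label),
               "lookup_error")
  px
}

#' Eccentricity from axis lengths
#'
#' \code{sqrt(1 - L_minor^2 / L_major^2)}: 0 for a circle, 1 for a
#' straight line.
#'
#' @param L_minor,L_major minor and major axis lengths,
#'   \code{0 <= L_minor <= L_major}, \code{L_major > 0}.
#' @return eccentricity in [0, 1].
#' @export
axis_eccentricity <- function(L_minor, L_major) {
  check_scalar(L_major, "L_major", lower = 0, strict_lower = TRUE)
  check_scalar(L_minor, "L_minor", lower = 0, upper = L_major)
  sqrt(1 - L_minor^2 / L_major^2)
}

#' Shape of one labeled cell region
#'
#' Axis lengths are those of the moment-equivalent ellipse: the ellipse
#' with the same second central moments as the pixel region. Eccentricity
#' is \code{sqrt(1 - L_minor^2 / L_major^2)}: 0 for a circle (cuboidal
#' cell), 1 for a straight line (spindle-shaped cell).
#'
#' @param mask integer label matrix (0 = background).
#' @param label positive integer label to measure.
#' @return list with \code{label}, \code{centroid_px} (x, y),
#'   \code{L_major}, \code{L_minor} (full axis lengths, px),
#'   \code{eccentricity}, \code{orientation_deg} (major-axis direction in
#'   [0, 180)), and \code{area_px}.
#' @export
eccentricity <- function(mask, label) {
  px <- region_pixels(mask, label)
  if (nrow(px) < 5)
    stop_osteo(sprintf("region %d has %d px; need >= 5 for stable moments",
                       label, nrow(px)), "degenerate_region_error")
  x <- px[, 2]; y <- px[, 1]
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2); myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  common <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- (mxx + myy) / 2 + common
  l2 <- (mxx + myy) / 2 - common
  l2 <- max(l2, 0)
  if (l1 <= 0)
    stop_osteo("degenerate region: zero spatial extent",
               "degenerate_region_error")
  list(label = as.integer(label),
       centroid_px = c(x = cx, y = cy),
       L_major = 4 * sqrt(l1),
       L_minor = 4 * sqrt(l2),
       eccentricity = axis_eccentricity(4 * sqrt(l2), 4 * sqrt(l1)),
       orientation_deg = (atan2(2 * mxy, mxx - myy) / 2 * 180 / pi) %% 180,
       area_px = nrow(px))
}

#' Angular radius profile of a cell, g(theta)
#'
#' For each 1-degree bin, the mean distance from the region centroid to
#' the boundary pixels whose polar angle falls in the bin. Boundary pixels
#' are region pixels with at least one 4-connected background neighbour.
#' Bins left empty by rasterization are filled by circular linear
#' interpolation; a region populating fewer than 180 bins is rejected.
#'
#' @param mask integer label matrix.
#' @param label positive integer label.
#' @return an \code{angular_profile} of kind \code{cell_radius}.
#' @export
radius_profile <- function(mask, label) {
  px <- region_pixels(mask, label)
  if (nrow(px) < 5)
    stop_osteo("region too small for a radius profile",
               "degenerate_region_error")
  reg <- matrix(FALSE, nrow(mask), ncol(mask))
  reg[px] <- TRUE
  bd <- boundary_pixels(reg)
  cx <- mean(px[, 2]); cy <- mean(px[, 1])
  # each boundary pixel is a unit square subtending a finite angular arc:
  # subpixel points determine which bins the pixel covers, while the
  # radius recorded for every covered bin is the pixel-center distance
  off <- expand.grid(ox = c(-0.5, 0, 0.5), oy = c(-0.5, 0, 0.5))
  dx <- rep(bd[, 2], each = nrow(off)) + rep(off$ox, nrow(bd)) - cx
  dy <- rep(bd[, 1], each = nrow(off)) + rep(off$oy, nrow(bd)) - cy
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  b <- floor(ang) %% 360
  # +0.5: the cell extends to the outer edge of its boundary pixels
  d <- rep(sqrt((bd[, 2] - cx)^2 + (bd[, 1] - cy)^2) + 0.5,
           each = nrow(off))
  vals <- rep(NA_real_, 360)
  means <- rowsum(d, group = b) / as.numeric(table(b))
  vals[as.integer(rownames(means)) + 1L] <- means[, 1]
  pop <- which(!is.na(vals))
  if (length(pop) < 180)
    stop_osteo(sprintf("region %d populates only %d/360 angular bins",
                       label, length(pop)), "degenerate_region_error")
  if (length(pop) < 360) {
    # circular linear interpolation across empty bins
    xs <- c(pop - 360, pop, pop + 360)
    ys <- rep(vals[pop], 3)
    vals <- stats::approx(xs, ys, xout = 0:359 + 1)$y
  }
  angular_profile(vals, "cell_radius")
}

#' Mean eccentricity over all cells of a mask
#'
#' @param mask integer label matrix with at least one region.
#' @param min_area_px regions below this size are skipped (default 5).
#' @return list with \code{mean} (unweighted mean over cells) and
#'   \code{cells}, a data.frame with one row per cell (label, centroid,
#'   axis lengths, eccentricity, orientation, area).
#' @export
mean_eccentricity <- function(mask, min_area_px = 5) {
  if (!is.matrix(mask))
    stop_osteo("'mask' must be an integer label matrix", "validation_error")
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0)
    stop_osteo("mask contains no labeled regions", "empty_input_error")
  rows <- lapply(labs, function(l) {
    if (sum(mask == l) < min_area_px) return(NULL)
    s <- eccentricity(mask, l)
    data.frame(label = s$label, centroid_x = s$centroid_px[["x"]],
               centroid_y = s$centroid_px[["y"]], L_major = s$L_major,
               L_minor = s$L_minor, eccentricity = s$eccentricity,
               orientation_deg = s$orientation_deg, area_px = s$area_px)
  })
  cells <- do.call(rbind, rows)
  if (is.null(cells) || nrow(cells) == 0)
    stop_osteo("no region meets the minimum size", "empty_input_error")
  rownames(cells) <- NULL
  list(mean = mean(cells$eccentricity), cells = cells)
}
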