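# Synthetic image, mask and track generators with known ground truth.
# These emulate the statistical structure of intravital two-photon data:
# SHG-like collagen fiber textures with controllable orientation dispersion,
# elliptical cell masks with programmed eccentricity, 10-min-interval
# centroid tracks, and deforming mask pairs.

#' Specification of a synthetic collagen-fiber texture
#'
#' Fiber orientations are axial (180-degree periodic), so they are sampled
#' from a von Mises distribution on doubled angles and halved: a
#' concentration of 0 yields isotropic fibers, large concentrations yield
#' fibers parallel to \code{mean_orientation_deg}.
#'
#' @param width_px canvas side in pixels (>= 64).
#' @param pixel_size_um physical pixel size in micrometers per pixel.
#' @param mean_orientation_deg mean fiber orientation, degrees in [0, 180).
#' @param concentration von Mises kappa on the doubled-angle scale (>= 0).
#' @param n_fibers number of fiber segments drawn.
#' @param fiber_width_px Gaussian cross-section scale of a fiber, pixels.
#' @param background_noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return an object of class \code{fiber_field_spec}.
#' @export
fiber_field_spec <- function(width_px = 512L, pixel_size_um = 0.32,
                             mean_orientation_deg = 30,
                             concentration = 0, n_fibers = 600L,
                             fiber_width_px = 3, background_noise_sd = 0.05,
                             seed = 1L) {
  check_scalar(width_px, "width_px", lower = 64, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  check_scalar(mean_orientation_deg, "mean_orientation_deg", 0, 180)
  if (mean_orientation_deg == 180)
    stop_osteo("'mean_orientation_deg' must lie in [0, 180)",
               "validation_error")
  check_scalar(concentration, "concentration", lower = 0)
  check_scalar(n_fibers, "n_fibers", lower = 0, integer = TRUE)
  check_scalar(fiber_width_px, "fiber_width_px", 0, strict_lower = TRUE)
  check_scalar(background_noise_sd, "background_noise_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(width_px = as.integer(width_px),
                 pixel_size_um = pixel_size_um,
                 mean_orientation_deg = mean_orientation_deg,
                 concentration = concentration,
                 n_fibers = as.integer(n_fibers),
                 fiber_width_px = fiber_width_px,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "fiber_field_spec")
}

#' Generate a synthetic SHG-like fiber texture
#'
#' Draws \code{n_fibers} anti-aliased line segments with a Gaussian
#' cross-section, orientations drawn von Mises on doubled angles and
#' halved, then adds clipped Gaussian noise. Each fiber contributes a
#' fixed amplitude of 0.6 so that overlaps saturate (clip at 1) the way a
#' detector does, keeping the fiber-to-noise contrast independent of how
#' strongly the fibers overlap. Intensities lie in [0, 1]. The drawn
#' segment orientations are attached as attribute \code{orientations_deg}
#' for ground-truth checks.
#'
#' @param spec a \code{\link{fiber_field_spec}}.
#' @return numeric matrix in [0, 1] with attributes \code{pixel_size_um}
#'   and \code{orientations_deg}.
#' @export
make_fiber_texture <- function(spec) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  N <- spec$width_px
  withr::with_seed(spec$seed, {
    img <- matrix(0, N, N)
    theta <- numeric(0)
    if (spec$n_fibers > 0) {
      # doubled-angle axial sampling; halve back to [0, 180)
      phi <- rvonmises(spec$n_fibers,
                       mu = 2 * spec$mean_orientation_deg * pi / 180,
                       kappa = spec$concentration)
      theta <- (phi / 2) %% pi
      cx <- runif(spec$n_fibers, 0, N - 1)
      cy <- runif(spec$n_fibers, 0, N - 1)
      len <- 1.2 * N
      sig <- spec$fiber_width_px / 2
      amp <- 0.6
      for (i in seq_len(spec$n_fibers))
        img <- add_fiber(img, cx[i], cy[i], theta[i], len, sig, amp)
    }
    if (spec$background_noise_sd > 0)
      img <- img + rnorm(N * N, 0, spec$background_noise_sd)
    img <- pmin(pmax(img, 0), 1)
  })
  attr(img, "pixel_size_um") <- spec$pixel_size_um
  attr(img, "orientations_deg") <- theta * 180 / pi
  img
}

# Add one Gaussian-profile segment, evaluating only a band of pixels
# around the line (parametrized along the axis closest to the fiber
# direction) instead of the whole canvas.
add_fiber <- function(img, cx, cy, theta, len, sig, amp) {
  N <- nrow(img)
  ct <- cos(theta); st <- sin(theta)
  reach <- 4 * sig
  cut2 <- reach^2
  x1 <- cx - (len / 2) * ct; x2 <- cx + (len / 2) * ct
  y1 <- cy - (len / 2) * st; y2 <- cy + (len / 2) * st
  if (abs(ct) >= abs(st)) {
    xs <- max(0, floor(min(x1, x2) - reach)):min(N - 1,
                                                 ceiling(max(x1, x2) + reach))
    if (length(xs) == 0) return(img)
    ycen <- cy + (xs - cx) * (st / ct)
    half <- reach / abs(ct) + 1
    ylo <- pmax(0, floor(ycen - half)); yhi <- pmin(N - 1,
                                                    ceiling(ycen + half))
    keep <- ylo <= yhi
    cnt <- pmax(yhi - ylo + 1, 0) * keep
    px <- rep(xs, cnt)
    py <- unlist(lapply(which(keep), function(j) ylo[j]:yhi[j]))
  } else {
    ys <- max(0, floor(min(y1, y2) - reach)):min(N - 1,
                                                 ceiling(max(y1, y2) + reach))
    if (length(ys) == 0) return(img)
    xcen <- cx + (ys - cy) * (ct / st)
    half <- reach / abs(st) + 1
    xlo <- pmax(0, floor(xcen - half)); xhi <- pmin(N - 1,
                                                    ceiling(xcen + half))
    keep <- xlo <= xhi
    cnt <- pmax(xhi - xlo + 1, 0) * keep
    py <- rep(ys, cnt)
    px <- unlist(lapply(which(keep), function(j) xlo[j]:xhi[j]))
  }
  if (length(px) == 0) return(img)
  dx <- px - cx; dy <- py - cy
  t <- pmin(pmax(dx * ct + dy * st, -len / 2), len / 2)
  d2 <- (dx - t * ct)^2 + (dy - t * st)^2
  hit <- d2 < cut2
  idx <- py[hit] + 1L + px[hit] * N  # row + col offset into the matrix
  img[idx] <- img[idx] + amp * exp(-d2[hit] / (2 * sig^2))
  img
}

#' Specification of a synthetic cell population
#'
#' Cells are ellipses whose axes satisfy
#' \code{eccentricity = sqrt(1 - b^2/a^2)} exactly before rasterization.
#'
#' @param n_cells number of cells to place.
#' @param eccentricity programmed eccentricity in [0, 1).
#' @param orientation_deg a number in [0, 180), or \code{"match_fibers"}
#'   (use the fiber orientation supplied to \code{\link{make_cell_masks}}),
#'   or \code{"random"} (independent uniform orientation per cell).
#' @param mean_area_px mean cell area in pixels; per-cell areas get a small
#'   lognormal jitter (sdlog 0.1) while eccentricity stays exact.
#' @param seed integer RNG seed.
#' @return an object of class \code{cell_population_spec}.
#' @export
cell_population_spec <- function(n_cells = 12L, eccentricity = 0.961,
                                 orientation_deg = "match_fibers",
                                 mean_area_px = 1257, seed = 1L) {
  check_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar(eccentricity, "eccentricity", 0, 1)
  if (eccentricity == 1)
    stop_osteo("'eccentricity' must lie in [0, 1)", "validation_error")
  if (is.character(orientation_deg)) {
    if (!orientation_deg %in% c("match_fibers", "random"))
      stop_osteo("orientation_deg must be numeric, 'match_fibers' or 'random'",
                 "validation_error")
  } else {
    check_scalar(orientation_deg, "orientation_deg", 0, 180)
  }
  check_scalar(mean_area_px, "mean_area_px", 0, strict_lower = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_cells = as.integer(n_cells), eccentricity = eccentricity,
                 orientation_deg = orientation_deg,
                 mean_area_px = mean_area_px, seed = as.integer(seed)),
            class = "cell_population_spec")
}

# pixel included when at least half its area is covered (3x3 subsamples);
# coverage rasterization keeps the measured moments close to the analytic
# ellipse at subpixel center positions
rasterize_ellipse <- function(canvas_px, cx, cy, a, b, theta_rad) {
  r <- ceiling(a) + 1
  xs <- max(0, floor(cx - r)):min(canvas_px - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(canvas_px - 1, ceiling(cy + r))
  dx <- rep(xs, each = length(ys)) - cx
  dy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta_rad); st <- sin(theta_rad)
  cover <- integer(length(dx))
  for (ox in c(-1, 0, 1) / 3) for (oy in c(-1, 0, 1) / 3) {
    u <- ((dx + ox) * ct + (dy + oy) * st) / a
    v <- (-(dx + ox) * st + (dy + oy) * ct) / b
    cover <- cover + (u * u + v * v <= 1)
  }
  inside <- cover >= 5L
  cbind(row = rep(ys, times = length(xs))[inside] + 1,
        col = rep(xs, each = length(ys))[inside] + 1)
}

#' Generate a labeled mask of non-overlapping elliptical cells
#'
#' Cells are placed by rejection sampling (up to 1000 retries per cell);
#' labels run 1..n_cells.
#'
#' @param spec a \code{\link{cell_population_spec}}.
#' @param canvas_px canvas side in pixels.
#' @param fiber_orientation_deg fiber orientation to match when the spec
#'   asks for \code{"match_fibers"}.
#' @return integer matrix of labels (0 = background) with attribute
#'   \code{true_orientation_deg} (per-cell programmed orientation).
#' @export
make_cell_masks <- function(spec, canvas_px = 512L,
                            fiber_orientation_deg = NULL) {
  stopifnot(inherits(spec, "cell_population_spec"))
  check_scalar(canvas_px, "canvas_px", lower = 16, integer = TRUE)
  if (identical(spec$orientation_deg, "match_fibers") &&
      is.null(fiber_orientation_deg))
    stop_osteo("orientation 'match_fibers' needs 'fiber_orientation_deg'",
               "validation_error")
  e <- spec$eccentricity
  ratio <- sqrt(1 - e^2)  # b/a, exact by construction
  withr::with_seed(spec$seed, {
    mask <- matrix(0L, canvas_px, canvas_px)
    orient <- numeric(spec$n_cells)
    for (k in seq_len(spec$n_cells)) {
      area <- spec$mean_area_px * exp(rnorm(1, 0, 0.1))
      a <- sqrt(area / (pi * ratio))
      b <- a * ratio
      th <- if (is.numeric(spec$orientation_deg)) {
        spec$orientation_deg
      } else if (spec$orientation_deg == "match_fibers") {
        fiber_orientation_deg
      } else {
        runif(1, 0, 180)
      }
      if (a + 2 > canvas_px / 2 - 1)
        stop_osteo("cell larger than canvas", "placement_error")
      placed <- FALSE
      for (try in 1:1000) {
        cx <- runif(1, a + 1, canvas_px - a - 2)
        cy <- runif(1, a + 1, canvas_px - a - 2)
        px <- rasterize_ellipse(canvas_px, cx, cy, a, b, th * pi / 180)
        if (nrow(px) >= 5 && all(mask[px] == 0L)) {
          mask[px] <- k
          orient[k] <- th
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_osteo(sprintf("could not place cell %d without overlap", k),
                   "placement_error")
    }
  })
  attr(mask, "true_orientation_deg") <- orient
  mask
}

#' Generate random-walk cell tracks with exact per-step speed
#'
#' Each track starts at a uniform position in a square field and takes
#' \code{n_steps} steps of exactly \code{speed_um_min * step_min}
#' micrometers; the heading evolves by Gaussian turns. Emulates centroid
#' tracks sampled at 10-min intervals.
#'
#' @param n_cells number of tracks.
#' @param speed_um_min programmed speed in micrometers per minute.
#' @param step_min sampling interval in minutes (default 10).
#' @param n_steps number of steps (default 18, i.e. 3 h at 10-min steps).
#' @param turn_sd_deg standard deviation of the per-step heading change.
#' @param seed integer RNG seed.
#' @param field_um side of the square starting field, micrometers.
#' @return data.frame with columns track_id, time_min, x_um, y_um.
#' @export
make_tracks <- function(n_cells, speed_um_min, step_min = 10, n_steps = 18L,
                        turn_sd_deg = 30, seed = 1L, field_um = 163.84) {
  check_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar(speed_um_min, "speed_um_min", lower = 0)
  check_scalar(step_min, "step_min", 0, strict_lower = TRUE)
  check_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  check_scalar(turn_sd_deg, "turn_sd_deg", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  step_len <- speed_um_min * step_min
  withr::with_seed(seed, {
    out <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
      x[1] <- runif(1, 0, field_um); y[1] <- runif(1, 0, field_um)
      h <- runif(1, 0, 2 * pi)
      for (s in seq_len(n_steps)) {
        h <- h + rnorm(1, 0, turn_sd_deg * pi / 180)
        x[s + 1] <- x[s] + step_len * cos(h)
        y[s + 1] <- y[s] + step_len * sin(h)
      }
      out[[i]] <- data.frame(track_id = i,
                             time_min = step_min * (0:n_steps),
                             x_um = x, y_um = y)
    }
  })
  do.call(rbind, out)
}

#' Generate a deforming pair of labeled masks
#'
#' Returns the base mask together with a deformed copy in which each region
#' is boundary-perturbed and translated in proportion to
#' \code{deformation_level}: 0 gives an identical copy, 1 translates each
#' region fully clear of its original footprint (downstream CDI = 1).
#'
#' @param base integer label matrix with at least one region.
#' @param deformation_level real in [0, 1].
#' @param seed integer RNG seed.
#' @return list with elements \code{t0} and \code{t1}, both label matrices.
#' @export
make_deforming_masks <- function(base, deformation_level, seed = 1L) {
  if (!is.matrix(base) || !any(base > 0))
    stop_osteo("'base' must be a label matrix with >= 1 region",
               "validation_error")
  check_scalar(deformation_level, "deformation_level", 0, 1)
  check_scalar(seed, "seed", integer = TRUE)
  base <- matrix(as.integer(base), nrow(base), ncol(base))
  if (deformation_level == 0)
    return(list(t0 = base, t1 = base))
  nr <- nrow(base); nc <- ncol(base)
  withr::with_seed(seed, {
    t1 <- matrix(0L, nr, nc)
    for (lab in sort(unique(base[base > 0]))) {
      px <- which(base == lab, arr.ind = TRUE)
      # boundary perturbation: drop boundary pixels, add rim pixels
      p <- 0.3 * deformation_level
      reg <- matrix(FALSE, nr, nc); reg[px] <- TRUE
      bd <- boundary_pixels(reg)
      drop <- bd[runif(nrow(bd)) < p, , drop = FALSE]
      reg[drop] <- FALSE
      rim <- outer_rim(reg)
      add <- rim[runif(nrow(rim)) < p, , drop = FALSE]
      reg[add] <- TRUE
      px2 <- which(reg, arr.ind = TRUE)
      if (nrow(px2) == 0) px2 <- px
      # translate along the axis with most room; the clearing distance is
      # the region's maximum chord along that axis (for a convex region a
      # shift of chord+1 guarantees disjoint footprints at level 1)
      rr <- range(px2[, 1]); cr <- range(px2[, 2])
      room_down <- nr - rr[2]; room_up <- rr[1] - 1
      room_right <- nc - cr[2]; room_left <- cr[1] - 1
      rooms <- c(down = room_down, up = room_up,
                 right = room_right, left = room_left)
      dir <- names(rooms)[which.max(rooms)]
      chord <- if (dir %in% c("down", "up")) {
        max(vapply(split(px2[, 1], px2[, 2]),
                   function(v) diff(range(v)) + 1, numeric(1)))
      } else {
        max(vapply(split(px2[, 2], px2[, 1]),
                   function(v) diff(range(v)) + 1, numeric(1)))
      }
      sh <- round(deformation_level * (chord + 1))
      sh <- min(sh, max(rooms))
      shifted <- px2
      if (dir == "down") shifted[, 1] <- shifted[, 1] + sh
      if (dir == "up") shifted[, 1] <- shifted[, 1] - sh
      if (dir == "right") shifted[, 2] <- shifted[, 2] + sh
      if (dir == "left") shifted[, 2] <- shifted[, 2] - sh
      keep <- shifted[, 1] >= 1 & shifted[, 1] <= nr &
        shifted[, 2] >= 1 & shifted[, 2] <= nc
      shifted <- shifted[keep, , drop = FALSE]
      t1[shifted[t1[shifted] == 0L, , drop = FALSE]] <- lab
    }
  })
  list(t0 = base, t1 = t1)
}

boundary_pixels <- function(reg) {
  nr <- nrow(reg); nc <- ncol(reg)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- reg
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(reg & !inner, arr.ind = TRUE)
}

outer_rim <- function(reg) {
  nr <- nrow(reg); nc <- ncol(reg)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- reg
  touch <- pad[1:nr, 2:(nc + 1)] | pad[3:(nr + 2), 2:(nc + 1)] |
    pad[2:(nr + 1), 1:nc] | pad[2:(nr + 1), 3:(nc + 2)]
  which(!reg & touch, arr.ind = TRUE)
}

#' Parameter sets for the two qualitative bone-maturation stages
#'
#' \code{day10like} emulates early ectopic bone: strongly oriented collagen
#' fibers, spindle-shaped cells (eccentricity 0.961, the worked per-field
#' day-10 value) aligned with the fibers, and fast cells.
#' \code{day21like} emulates mature bone: isotropic fibers, near-cuboidal
#' cells with random orientation, and slow cells.
#'
#' @param stage one of \code{"day10like"}, \code{"day21like"}.
#' @param seed integer RNG seed, reused across the stage's generators.
#' @return list with elements \code{fiber} (\code{fiber_field_spec}),
#'   \code{cells} (\code{cell_population_spec}), \code{speed_um_min},
#'   \code{deformation_level}, and \code{stage}.
#' @export
scenario_spec <- function(stage = c("day10like", "day21like"), seed = 1L) {
  stage <- match.arg(stage)
  check_scalar(seed, "seed", integer = TRUE)
  if (stage == "day10like") {
    list(stage = stage,
         fiber = fiber_field_spec(concentration = 30,
                                  mean_orientation_deg = 30, seed = seed),
         cells = cell_population_spec(n_cells = 12, eccentricity = 0.961,
                                      orientation_deg = "match_fibers",
                                      seed = seed),
         speed_um_min = 0.5,
         deformation_level = 0.6,
         seed = as.integer(seed))
  } else {
    list(stage = stage,
         fiber = fiber_field_spec(concentration = 0,
                                  mean_orientation_deg = 30, seed = seed),
         cells = cell_population_spec(n_cells = 12, eccentricity = 0.3,
                                      orientation_deg = "random",
                                      seed = seed),
         speed_um_min = 0.15,
         deformation_level = 0.2,
         seed = as.integer(seed))
  }
}
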