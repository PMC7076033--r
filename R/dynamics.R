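# Track-based osteoblast motility and the osteoclast cell deformation
# index (CDI) from mask pairs 10 minutes apart.

#' Mean velocity of one track
#'
#' The mean over consecutive intervals of Euclidean displacement divided by
#' elapsed time (not net displacement over total time), matching the
#' per-cell mean velocity reported by tracking software. Gaps simply yield
#' longer elapsed times; no imputation.
#'
#' @param track data.frame with columns \code{time_min}, \code{x_um},
#'   \code{y_um} (one cell, time-ordered).
#' @return mean velocity in micrometers per minute.
#' @export
mean_velocity <- function(track) {
  req <- c("time_min", "x_um", "y_um")
  if (!is.data.frame(track) || !all(req %in% names(track)))
    stop_osteo("'track' needs columns time_min, x_um, y_um",
               "validation_error")
  if (nrow(track) < 2)
    stop_osteo("a track needs >= 2 time points", "validation_error")
  t <- track$time_min
  if (any(diff(t) <= 0))
    stop_osteo("track timestamps must be strictly increasing",
               "validation_error")
  d <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  mean(d / diff(t))
}

#' Per-track mean velocities with cohort mean and SD
#'
#' Each data point is one cell: the cohort mean and standard deviation are
#' taken over per-track mean velocities.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{time_min},
#'   \code{x_um}, \code{y_um}.
#' @return list with \code{per_track} (data.frame track_id,
#'   mean_velocity_um_min), \code{mean}, \code{sd} (0 for a single track),
#'   and \code{n}.
#' @export
cohort_velocity <- function(tracks) {
  req <- c("track_id", "time_min", "x_um", "y_um")
  if (!is.data.frame(tracks) || !all(req %in% names(tracks)) ||
      nrow(tracks) == 0)
    stop_osteo("'tracks' needs columns track_id, time_min, x_um, y_um",
               "empty_input_error")
  ids <- unique(tracks$track_id)
  v <- vapply(ids, function(id)
    mean_velocity(tracks[tracks$track_id == id, , drop = FALSE]),
    numeric(1))
  per_track <- data.frame(track_id = ids, mean_velocity_um_min = v)
  list(per_track = per_track, mean = mean(v),
       sd = if (length(v) > 1) sd(v) else 0, n = length(v))
}

#' Cell deformation index between two mask frames
#'
#' The fraction of a cell's footprint that changed between frames:
#' symmetric difference area over union area. 0 means the regions are
#' identical (a static cell, associated with high bone-resorptive
#' osteoclast activity), 1 means they are disjoint.
#'
#' @param mask_t0,mask_t1 integer label matrices on the same grid.
#' @param label positive integer label present in both frames.
#' @return list with \code{label}, \code{area_t0_px}, \code{area_t1_px},
#'   \code{changed_area_px}, \code{union_area_px}, \code{cdi}.
#' @export
cdi <- function(mask_t0, mask_t1, label) {
  if (!is.matrix(mask_t0) || !is.matrix(mask_t1) ||
      !identical(dim(mask_t0), dim(mask_t1)))
    stop_osteo("masks must be matrices on the same grid", "validation_error")
  check_scalar(label, "label", lower = 1, integer = TRUE)
  a <- mask_t0 == label
  b <- mask_t1 == label
  if (!any(a) || !any(b))
    stop_osteo(sprintf("label %d absent from one frame (cell lost)", label),
               "lookup_error")
  uni <- sum(a | b)
  changed <- sum(xor(a, b))
  list(label = as.integer(label), area_t0_px = sum(a), area_t1_px = sum(b),
       changed_area_px = changed, union_area_px = uni,
       cdi = changed / uni)
}

#' CDI for every cell shared by two frames
#'
#' @param mask_t0,mask_t1 integer label matrices on the same grid.
#' @return data.frame with one row per shared label.
#' @export
cdi_table <- function(mask_t0, mask_t1) {
  labs <- intersect(unique(mask_t0[mask_t0 > 0]),
                    unique(mask_t1[mask_t1 > 0]))
  if (length(labs) == 0)
    stop_osteo("no shared labels between frames", "empty_input_error")
  rows <- lapply(sort(labs), function(l) {
    r <- cdi(mask_t0, mask_t1, l)
    data.frame(label = r$label, area_t0_px = r$area_t0_px,
               area_t1_px = r$area_t1_px,
               changed_area_px = r$changed_area_px,
               union_area_px = r$union_area_px, cdi = r$cdi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
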