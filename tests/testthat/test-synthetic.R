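# Generators: determinism, ground-truth recovery, degenerate settings.

test_that("fiber textures are deterministic under a fixed seed", {
  sp <- fiber_field_spec(width_px = 128, n_fibers = 40, seed = 11L)
  a <- make_fiber_texture(sp)
  b <- make_fiber_texture(sp)
  expect_identical(a, b)
  sp2 <- fiber_field_spec(width_px = 128, n_fibers = 40, seed = 12L)
  expect_false(identical(as.numeric(a),
                         as.numeric(make_fiber_texture(sp2))))
})

test_that("a zero-fiber spec yields a background-only image", {
  sp <- fiber_field_spec(width_px = 64, n_fibers = 0,
                         background_noise_sd = 0, seed = 1L)
  img <- make_fiber_texture(sp)
  expect_true(all(img == 0))
  expect_length(attr(img, "orientations_deg"), 0)
})

test_that("drawn orientations recover the programmed mean at high concentration", {
  for (s in 1:5) {
    sp <- fiber_field_spec(width_px = 128, mean_orientation_deg = 70,
                           concentration = 20, n_fibers = 200, seed = s)
    ang <- attr(make_fiber_texture(sp), "orientations_deg")
    # axial circular mean via doubled angles
    m <- (atan2(mean(sin(2 * ang * pi / 180)),
                mean(cos(2 * ang * pi / 180))) * 90 / pi) %% 180
    delta <- abs(((m - 70 + 90) %% 180) - 90)
    expect_lt(delta, 3)
  }
})

test_that("generator spec validation rejects invalid fields", {
  expect_error(fiber_field_spec(width_px = 32), class = "validation_error")
  expect_error(fiber_field_spec(concentration = -1),
               class = "validation_error")
  expect_error(cell_population_spec(eccentricity = 1),
               class = "validation_error")
  expect_error(cell_population_spec(orientation_deg = "sideways"),
               class = "validation_error")
})

test_that("cell masks are labeled 1..n without overlap and recover shape", {
  sp <- cell_population_spec(n_cells = 8, eccentricity = 0.961,
                             orientation_deg = 45, mean_area_px = 1257,
                             seed = 2L)
  m <- make_cell_masks(sp, 512)
  expect_setequal(unique(as.integer(m[m > 0])), 1:8)
  me <- mean_eccentricity(m)
  expect_true(all(me$cells$area_px >= 500))
  expect_true(all(abs(me$cells$eccentricity - 0.961) < 0.02))
  # circle case: moment eccentricity of ~1257-px binary circles carries
  # rasterization noise of order 0.1 at the mean-zero point
  sp0 <- cell_population_spec(n_cells = 5, eccentricity = 0,
                              orientation_deg = 0, mean_area_px = 1257,
                              seed = 3L)
  me0 <- mean_eccentricity(make_cell_masks(sp0, 512))
  expect_lt(me0$mean, 0.1)
  expect_true(all(me0$cells$eccentricity < 0.2))
})

test_that("a matched-fiber cell aligns its major axis with the fibers", {
  sp <- cell_population_spec(n_cells = 1, eccentricity = 0.866,
                             orientation_deg = "match_fibers", seed = 4L)
  m <- make_cell_masks(sp, 256, fiber_orientation_deg = 30)
  sh <- eccentricity(m, 1)
  delta <- abs(((sh$orientation_deg - 30 + 90) %% 180) - 90)
  expect_lt(delta, 3)
  expect_error(make_cell_masks(sp, 256), class = "validation_error")
})

test_that("tracks honor exact per-step displacement and determinism", {
  tr0 <- make_tracks(3, speed_um_min = 0, seed = 5L)
  for (id in 1:3) {
    t1 <- tr0[tr0$track_id == id, ]
    expect_equal(diff(range(t1$x_um)), 0)
    expect_equal(diff(range(t1$y_um)), 0)
  }
  tr <- make_tracks(1, speed_um_min = 0.5, step_min = 10, n_steps = 18,
                    turn_sd_deg = 0, seed = 6L)
  path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
  expect_equal(path, 0.5 * 10 * 18, tolerance = 1e-12)
  expect_identical(tr, make_tracks(1, 0.5, 10, 18, 0, seed = 6L))
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(steps, rep(5, 18), tolerance = 1e-12)
})

test_that("deforming masks span identical to disjoint as the level rises", {
  base <- square_mask(120, 20, 51, 51)
  p0 <- make_deforming_masks(base, 0, seed = 7L)
  expect_identical(p0$t0, p0$t1)
  expect_equal(cdi(p0$t0, p0$t1, 1)$cdi, 0)
  p1 <- make_deforming_masks(base, 1, seed = 7L)
  expect_equal(cdi(p1$t0, p1$t1, 1)$cdi, 1)
  pm <- make_deforming_masks(base, 0.5, seed = 7L)
  v <- cdi(pm$t0, pm$t1, 1)$cdi
  expect_gt(v, 0)
  expect_lt(v, 1)
})

test_that("scenario specs encode the early vs mature contrast", {
  s10 <- scenario_spec("day10like", seed = 1L)
  s21 <- scenario_spec("day21like", seed = 1L)
  expect_gt(s10$fiber$concentration, s21$fiber$concentration)
  expect_identical(s21$fiber$concentration, 0)
  expect_gt(s10$cells$eccentricity, s21$cells$eccentricity)
  expect_identical(s10$cells$orientation_deg, "match_fibers")
  expect_identical(s21$cells$orientation_deg, "random")
  expect_gt(s10$speed_um_min, s21$speed_um_min)
})
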