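test_that("caliber profiles evaluate baseline, pearls and Gaussian tails", {
  flat <- caliber_profile_spec(0.3)
  expect_equal(eval_caliber_profile(flat, c(0, 3.7, 9)), rep(0.3, 3))

  pearl <- caliber_profile_spec(0.3, data.frame(
    center_s_um = 5, amplitude_um = 0.4, width_s_um = 0.5))
  expect_equal(eval_caliber_profile(pearl, 5), 0.7)
  # 3 widths out the bump contributes exp(-4.5) ~ 1.1% of its amplitude
  tail_val <- eval_caliber_profile(pearl, 5 + 3 * 0.5)
  expect_equal(tail_val, 0.3 + 0.4 * exp(-4.5), tolerance = 1e-12)
  expect_lt((tail_val - 0.3) / 0.3, 0.015)

  # constrictions clamp at the floor
  deep <- caliber_profile_spec(0.3, data.frame(
    center_s_um = 2, amplitude_um = -0.3, width_s_um = 0.5), floor_um = 0.06)
  expect_equal(eval_caliber_profile(deep, 2), 0.06)
  expect_error(caliber_profile_spec(0.3, data.frame(
    center_s_um = 1, amplitude_um = -0.5, width_s_um = 0.5)))
})

test_that("rendering is seeded-deterministic and linear in label density", {
  sp <- straight_phantom(0.5, length_um = 8, seed = 42)
  a <- render_axon_image(sp)
  b <- render_axon_image(sp)
  expect_identical(a$stack$pixels, b$stack$pixels)

  sp2 <- straight_phantom(0.5, length_um = 8, seed = 43)
  expect_false(identical(render_axon_image(sp2)$stack$pixels,
                         a$stack$pixels))
  # distinct seeds differ only in noise: noise-off renders are identical
  expect_identical(render_axon_image(sp, noise = FALSE)$stack$pixels,
                   render_axon_image(sp2, noise = FALSE)$stack$pixels)

  lo <- render_axon_image(straight_phantom(0.5, length_um = 8, seed = 1),
                          noise = FALSE)
  hi_spec <- straight_phantom(0.5, length_um = 8, seed = 1,
                              photons_per_um_membrane = 400)
  hi <- render_axon_image(hi_spec, noise = FALSE)
  expect_equal(sum(hi$stack$pixels), 2 * sum(lo$stack$pixels),
               tolerance = 1e-9)
})

test_that("noise-off transverse profiles are bimodal at the true separation", {
  sp <- straight_phantom(0.6, length_um = 8, seed = 1)
  ph <- render_axon_image(sp, noise = FALSE)
  g <- interp_along(ph$centerline, 4)
  prof <- extract_profile(ph$stack, 1, g$position[1, ], g$normal[1, ],
                          1.5, 0.02)
  pk <- detect_membrane_peaks(prof)
  expect_true(pk$resolved)
  # mode separation within half a pixel of the true caliber
  expect_lt(abs((pk$right_um - pk$left_um) - 0.6), 0.02)
  # symmetry of construction
  expect_lt(abs(pk$right_um + pk$left_um), 0.02)
})

test_that("phantom margins reject calibers that cannot fit the field", {
  expect_error(phantom_spec(rbind(c(0, 1), c(8, 1)),
                            caliber_profile_spec(1.5),
                            field_um = c(8, 2)), "margin")
})

test_that("time lapses realize the four dynamics event classes exactly", {
  sp <- straight_phantom(0.3, length_um = 16, seed = 5)

  # no events: noise-off frames are pixel-identical
  still <- render_timelapse(sp, list(), n_frames = 3, noise = FALSE)
  expect_identical(still$stack$pixels[1, , , 1],
                   still$stack$pixels[3, , , 1])
  expect_equal(still$stack$frame_interval_min, 5)

  # traveling pearl: ground-truth argmax advances by the speed per frame
  tp <- render_timelapse(sp, list(dynamics_event(
    "traveling_pearl", center0_s_um = 4, amplitude_um = 0.3,
    width_s_um = 0.6, speed_um_per_frame = 1)), n_frames = 5, noise = FALSE)
  centers <- vapply(1:5, function(t) {
    g <- tp$truth[tp$truth$frame == t, ]
    g$s_um[which.max(g$c_um)]
  }, numeric(1))
  expect_equal(centers, 4:8, tolerance = 0.051)

  # widening by 1.5x raises the ground-truth mean caliber in the span by 50%
  wd <- render_timelapse(sp, list(dynamics_event(
    "segment_widening_narrowing", span_s_um = c(4, 12), factor = 1.5,
    start_frame = 2, rise_frames = 2, fall_frames = 2)),
    n_frames = 6, noise = FALSE)
  span_mean <- function(t) {
    g <- wd$truth[wd$truth$frame == t & wd$truth$s_um >= 4 &
                  wd$truth$s_um <= 12, ]
    mean(g$c_um)
  }
  expect_equal(span_mean(4) / span_mean(1), 1.5, tolerance = 1e-9)
  expect_equal(span_mean(6) / span_mean(1), 1.0, tolerance = 1e-9)

  # focal inflation/deflation ramps up then back down
  fo <- render_timelapse(sp, list(dynamics_event(
    "focal_inflation_deflation", center_s_um = 8, amplitude_um = 0.4,
    width_s_um = 0.8, start_frame = 1, rise_frames = 2, fall_frames = 2)),
    n_frames = 6, noise = FALSE)
  at8 <- vapply(1:6, function(t) {
    fo$truth$c_um[fo$truth$frame == t & abs(fo$truth$s_um - 8) < 0.01]
  }, numeric(1))
  expect_equal(at8[3], 0.7, tolerance = 1e-9)  # full amplitude
  expect_equal(at8[6], 0.3, tolerance = 1e-9)  # back to baseline
  expect_true(all(diff(at8[1:3]) > 0) && all(diff(at8[3:5]) < 0))

  # constriction point toggles
  cp <- render_timelapse(sp, list(dynamics_event(
    "constriction_point", center_s_um = 8, depth_um = 0.2,
    width_s_um = 0.4, active_frames = c(2, 4))), n_frames = 4, noise = FALSE)
  at8c <- vapply(1:4, function(t) {
    cp$truth$c_um[cp$truth$frame == t & abs(cp$truth$s_um - 8) < 0.01]
  }, numeric(1))
  expect_equal(at8c, c(0.3, 0.1, 0.3, 0.1), tolerance = 1e-9)

  expect_error(render_timelapse(sp, list(dynamics_event(
    "traveling_pearl", center0_s_um = 99, amplitude_um = 0.3,
    width_s_um = 0.6, speed_um_per_frame = 1)), n_frames = 2), "outside")
  expect_error(dynamics_event("traveling_pearl", center0_s_um = 4),
               "needs parameters")
})

test_that("dividing scenes export schedule, regions and caliber offsets", {
  spec <- dividing_scene_spec(rng_seed = 3)
  sc <- render_dividing_scene(spec, noise = FALSE)
  expect_equal(sc$truth_lengths$border_to_border_um, spec$schedule_um)

  # region labels split at the scheduled borders; ties go to the dividing cell
  st1 <- sc$truth_stations[sc$truth_stations$frame == 1, ]
  st1 <- st1[!is.na(st1$region), ]
  expect_setequal(unique(st1$region), c("neighbor1", "dividing", "neighbor2"))
  div_x <- st1$x_um[st1$region == "dividing"]
  expect_lte(max(div_x) - min(div_x), spec$schedule_um[1])

  # the dividing-cell caliber offset appears in the ground truth
  mid <- st1[st1$region == "dividing", ]
  far <- st1[st1$region == "neighbor1", ]
  expect_gt(max(mid$c_um), max(far$c_um) + 0.04)

  # a monotone schedule keeps ground-truth lengths monotone
  spec2 <- dividing_scene_spec(schedule_um = c(8, 9, 10, 11, 12),
                               rng_seed = 3)
  sc2 <- render_dividing_scene(spec2, noise = FALSE)
  expect_true(all(diff(sc2$truth_lengths$border_to_border_um) > 0))

  expect_error(dividing_scene_spec(schedule_um = c(5, 12)), "must lie")
  expect_error(dividing_scene_spec(l_round_um = 13), "l_round_um < l_flat_um")
})
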