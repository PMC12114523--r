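test_that("profiles interpolate the image and are stable under respacing", {
  uni <- calibrated_stack(matrix(7, 50, 50), pixel_size_um = 0.05)
  p <- extract_profile(uni, 1, c(1.2, 1.2), c(0, 1), 0.5, 0.025)
  expect_true(all(p$intensities == 7))
  expect_equal(p$offsets_um, -p$offsets_um[length(p$offsets_um):1])

  ph <- render_axon_image(straight_phantom(0.5, length_um = 8, seed = 2),
                          noise = FALSE)
  g <- interp_along(ph$centerline, 4)
  a <- extract_profile(ph$stack, 1, g$position[1, ], g$normal[1, ], 1, 0.02)
  b <- extract_profile(ph$stack, 1, g$position[1, ], g$normal[1, ], 1, 0.01)
  shared <- match(round(a$offsets_um, 9), round(b$offsets_um, 9))
  expect_equal(b$intensities[shared], a$intensities, tolerance = 1e-6)
  # profile symmetric about the centerline by construction
  expect_equal(a$intensities, rev(a$intensities), tolerance = 0.05)

  expect_error(extract_profile(uni, 1, c(0.1, 0.1), c(0, 1), 5, 0.025),
               "leaves the image")
  expect_error(extract_profile(uni, 1, c(1, 1), c(0, 1), 0.5, 0.2),
               "exceed the pixel size")
})

test_that("membrane peaks are localized to sub-sample precision", {
  x <- seq(-1, 1, by = 0.02)
  two <- 100 * (exp(-(x + 0.25)^2 / (2 * 0.07^2)) +
                exp(-(x - 0.25)^2 / (2 * 0.07^2)))
  pk <- detect_membrane_peaks(make_profile(x, two), smooth_sigma_um = 0)
  expect_true(pk$resolved)
  expect_equal(pk$left_um, -0.25, tolerance = 0.005)
  expect_equal(pk$right_um, 0.25, tolerance = 0.005)
  expect_equal(pk$right_um - pk$left_um, 0.5, tolerance = 0.005)

  one <- 100 * exp(-x^2 / (2 * 0.1^2))
  expect_false(detect_membrane_peaks(make_profile(x, one))$resolved)
  flat <- rep(5, length(x))
  expect_false(detect_membrane_peaks(make_profile(x, flat))$resolved)
})

test_that("pair selection matches an exhaustive grid-search oracle", {
  set.seed(21)
  n_checked <- 0
  for (rep in 1:40) {
    x <- seq(-1.5, 1.5, by = 0.02)
    sep <- runif(1, 0.2, 1.2)
    y <- 40 * (exp(-(x + sep / 2)^2 / (2 * 0.07^2)) +
               exp(-(x - sep / 2)^2 / (2 * 0.07^2))) +
      rpois(length(x), 10)
    prof <- make_profile(x, y)
    got <- detect_membrane_peaks(prof, refine = FALSE)
    ys <- caliberkit:::smooth_profile(y, 0.01 / 0.02)
    want <- oracle_peak_pair(x, ys, 0.15)
    if (is.null(want)) {
      expect_false(got$resolved)
    } else {
      expect_true(got$resolved)
      expect_equal(got$raw_left_um, x[want[1]])
      expect_equal(got$raw_right_um, x[want[2]])
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("station measurement recovers phantom calibers and is deterministic", {
  ph <- render_axon_image(straight_phantom(0.30, length_um = 8, seed = 9))
  m1 <- measure_at(ph$stack, ph$centerline, 1, 4)
  m2 <- measure_at(ph$stack, ph$centerline, 1, 4)
  expect_identical(m1, m2)
  expect_false(m1$below_limit)
  expect_lt(abs(m1$caliber_um - 0.30), 0.03)

  tiny <- render_axon_image(straight_phantom(0.08, length_um = 8, seed = 9))
  expect_true(measure_at(tiny$stack, tiny$centerline, 1, 4)$below_limit)
})

test_that("lengthwise series locate pearls and report noise-level pearling", {
  flat <- render_axon_image(straight_phantom(0.4, seed = 31))
  ser <- measure_lengthwise(flat$stack, flat$centerline, 1)
  expect_lt(summarize_series(ser)$sd_um, 0.02)

  pearls <- data.frame(center_s_um = c(6, 14), amplitude_um = c(0.35, 0.35),
                       width_s_um = c(1, 1))
  pp <- render_axon_image(straight_phantom(0.25, seed = 32, pearls = pearls))
  ser2 <- measure_lengthwise(pp$stack, pp$centerline, 1)
  m <- ser2$measurements[!ser2$measurements$below_limit, ]
  # the two series maxima sit at the pearl centers (within one station)
  top <- m$s_um[order(m$caliber_um, decreasing = TRUE)][1:2]
  expect_true(any(abs(top - 6) <= 1))
  expect_true(any(abs(top - 14) <= 1))

  # all-unresolved series reports an explicit all-flagged summary
  sub <- render_axon_image(straight_phantom(0.08, length_um = 8, seed = 33))
  ser3 <- measure_lengthwise(sub$stack, sub$centerline, 1)
  s3 <- summarize_series(ser3)
  expect_true(s3$all_flagged)
  expect_identical(s3$n_used, 0L)
})

test_that("time series track events and honour the exclusion rule", {
  sp <- straight_phantom(0.3, length_um = 10, seed = 41)
  tl <- render_timelapse(sp, list(dynamics_event(
    "segment_widening_narrowing", span_s_um = c(0, 10), factor = 1.5,
    start_frame = 2, rise_frames = 3, fall_frames = 3)), n_frames = 8)
  ser <- measure_timeseries(tl$stack, tl$centerline, 5)
  v <- ser$measurements$caliber_um
  expect_equal(max(v, na.rm = TRUE) / v[1], 1.5, tolerance = 0.1)

  static <- render_timelapse(straight_phantom(0.4, length_um = 8, seed = 42),
                             list(), n_frames = 10)
  sv <- measure_timeseries(static$stack, static$centerline, 4)
  expect_lt(summarize_series(sv)$sd_um, 0.02)

  # strict > 20% rule on the flagged fraction
  fake <- function(n_flag, n = 10) {
    m <- data.frame(frame = 1:n, s_um = 3, caliber_um = 0.3,
                    left_um = -0.15, right_um = 0.15,
                    below_limit = c(rep(TRUE, n_flag),
                                    rep(FALSE, n - n_flag)),
                    quality = 1)
    caliberkit:::new_caliber_series(m, "time")
  }
  expect_false(apply_series_exclusion(fake(2)))   # exactly 20%: keep
  expect_true(apply_series_exclusion(fake(3)))
  expect_false(apply_series_exclusion(fake(0)))
})
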