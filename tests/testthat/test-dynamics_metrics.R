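fake_series <- function(calibers, flags = rep(FALSE, length(calibers)),
                        mode = "time") {
  m <- data.frame(frame = seq_along(calibers), s_um = 3,
                  caliber_um = calibers, left_um = NA, right_um = NA,
                  below_limit = flags, quality = 1)
  if (mode == "lengthwise") m$s_um <- seq_along(calibers)
  caliberkit:::new_caliber_series(m, mode)
}

test_that("dynamicity summarizes mean, SD and %RSD over usable frames", {
  d <- dynamicity(fake_series(c(0.2, 0.3, 0.4)))
  expect_equal(d$mean_caliber_um, 0.3)
  expect_equal(d$sd_um, 0.1)
  expect_equal(d$rsd_percent, 100 / 3, tolerance = 1e-9)

  const <- dynamicity(fake_series(rep(0.3, 5)))
  expect_equal(const$sd_um, 0)
  expect_equal(const$rsd_percent, 0)

  # %RSD is scale invariant
  k <- dynamicity(fake_series(2 * c(0.2, 0.3, 0.4)))
  expect_equal(k$rsd_percent, d$rsd_percent, tolerance = 1e-12)

  expect_error(dynamicity(fake_series(c(0.3, 0.3, 0.3),
                                      flags = c(TRUE, FALSE, FALSE))),
               ">= 3")
  # > 20% flagged marks the series excluded
  ex <- dynamicity(fake_series(rep(0.3, 10),
                               flags = c(rep(TRUE, 3), rep(FALSE, 7))))
  expect_true(ex$excluded)
})

test_that("day pairing matches locations and counts decreases", {
  day1 <- data.frame(location = sprintf("L%02d", 1:11),
                     rsd_percent = rep(28, 11))
  day2 <- data.frame(location = sprintf("L%02d", 1:11),
                     rsd_percent = c(rep(20, 10), 35))
  suppressMessages(paired <- pair_days(day1, day2))
  expect_equal(nrow(paired), 11)
  expect_equal(sum(paired$delta < 0), 10)

  suppressMessages(same <- pair_days(day1, day1))
  expect_true(all(same$delta == 0))

  day2x <- day2
  day2x$excluded <- c(TRUE, rep(FALSE, 10))
  suppressMessages(drop1 <- pair_days(day1, day2x))
  expect_equal(nrow(drop1), 10)
  expect_equal(attr(drop1, "n_dropped"), 2)
  expect_error(suppressMessages(
    pair_days(day1, data.frame(location = "zz", rsd_percent = 1))),
    "no matched")
})

test_that("pearling index is the station SD, translation invariant", {
  expect_equal(pearling_index(fake_series(rep(0.25, 8), mode = "lengthwise")),
               0)
  v <- c(0.2, 0.35, 0.22, 0.4, 0.28)
  base <- pearling_index(fake_series(v, mode = "lengthwise"))
  expect_equal(base, sd(v), tolerance = 1e-12)
  expect_equal(pearling_index(fake_series(v + 0.1, mode = "lengthwise")),
               base, tolerance = 1e-12)
  expect_error(pearling_index(fake_series(c(0.2, 0.3), mode = "lengthwise")),
               ">= 3")
})

test_that("region grouping separates the three cell samples", {
  m <- data.frame(caliber_um = c(0.21, 0.22, 0.15, 0.16, 0.14, 0.13, 0.5),
                  below_limit = c(rep(FALSE, 6), TRUE),
                  region = c("dividing", "dividing", "neighbor1",
                             "neighbor1", "neighbor2", "neighbor2",
                             "dividing"))
  g <- group_by_region(m)
  expect_equal(g$dividing, c(0.21, 0.22))   # flagged station dropped
  expect_equal(g$neighbor2, c(0.14, 0.13))
  expect_message(group_by_region(m[m$region != "neighbor1", ]),
                 "empty region")
})

test_that("border-to-border length is exact and rigid-motion invariant", {
  rect <- rbind(c(4, 0), c(16, 0), c(16, 6), c(4, 6))
  ann <- annotation_set(
    centerlines = list(list(label = "axon", frame = 1,
                            xy = rbind(c(0, 3), c(20, 3)))),
    cell_borders = list(list(label = "dividing", frame = 1, xy = rect)))
  expect_equal(border_to_border(ann, 1), 12, tolerance = 1e-9)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- function(xy) sweep(xy %*% t(R), 2, c(3, 1), "+")
  ann2 <- annotation_set(
    centerlines = list(list(label = "axon", frame = 1,
                            xy = rot(rbind(c(0, 3), c(20, 3))))),
    cell_borders = list(list(label = "dividing", frame = 1, xy = rot(rect))))
  expect_equal(border_to_border(ann2, 1), 12, tolerance = 1e-9)

  ann3 <- annotation_set(
    centerlines = list(list(label = "axon", frame = 1,
                            xy = rbind(c(0, 3), c(2, 3)))),
    cell_borders = list(list(label = "dividing", frame = 1, xy = rect)))
  expect_error(border_to_border(ann3, 1), "need 2")
})

test_that("round/flat selection maximizes the length increase", {
  rf <- select_round_flat(c(8, 8.2, 11.5, 12))
  expect_equal(rf$round_frame, 2)   # largest jump 8.2 -> 11.5
  expect_equal(rf$flat_frame, 3)
  expect_equal(rf$delta_um, 3.3)
  expect_false(rf$tie_flag)

  tie <- select_round_flat(c(8, 9, 10, 11))
  expect_equal(tie$round_frame, 1)
  expect_true(tie$tie_flag)
  expect_warning(dec <- select_round_flat(c(12, 11, 9)), "never increases")
  expect_equal(dec$round_frame, 1)  # least-negative change

  # oracle: exhaustive scan over consecutive pairs on random sequences
  set.seed(77)
  for (rep in 1:25) {
    v <- runif(sample(3:12, 1), 8, 14)
    got <- suppressWarnings(select_round_flat(v))
    d <- vapply(seq_len(length(v) - 1), function(i) v[i + 1] - v[i],
                numeric(1))
    expect_equal(got$round_frame, which.max(d))
  }
})

test_that("round/flat pairing drops stations that leave the region", {
  m <- data.frame(frame = rep(c(1, 2), each = 4),
                  s_um = rep(1:4, 2),
                  caliber_um = c(0.30, 0.31, 0.29, 0.32,
                                 0.27, 0.28, 0.26, 0.35),
                  below_limit = c(rep(FALSE, 7), TRUE),
                  region = c("dividing", "dividing", "dividing", "dividing",
                             "dividing", "dividing", "neighbor1", "dividing"))
  suppressMessages(rp <- round_flat_pairing(m, 1, 2))
  expect_equal(nrow(rp$pairs), 2)      # s=3 left region, s=4 flagged
  expect_equal(rp$n_dropped, 2)
  expect_equal(rp$pairs$delta_um, c(-0.03, -0.03), tolerance = 1e-12)

  same <- m
  same$caliber_um[5:8] <- same$caliber_um[1:4]
  same$below_limit <- FALSE
  same$region <- "dividing"
  rp2 <- round_flat_pairing(same, 1, 2)
  expect_true(all(rp2$pairs$delta_um == 0))
  expect_equal(rp2$pearling_round_um, rp2$pearling_flat_um)
})

test_that("the circular-arc model matches closed forms and a dense oracle", {
  flat <- arc_path_ratio(10, 0, 10)
  expect_equal(flat$path_ratio, 1.0)
  expect_equal(flat$arc_length_um, 10)

  semi <- arc_path_ratio(10, 5, 10)
  expect_equal(semi$arc_length_um, 5 * pi, tolerance = 1e-12)
  expect_equal(semi$path_ratio, pi / 2, tolerance = 1e-12)

  # dense polyline oracle on the same circle (chord 7, sagitta 2)
  R <- (7^2 / 4 + 2^2) / (2 * 2)
  th <- asin(7 / (2 * R))
  tt <- seq(-th, th, length.out = 1e6 + 1)
  oracle <- sum(sqrt(diff(R * sin(tt))^2 + diff(R * cos(tt))^2))
  got <- arc_path_ratio(7, 2, 10)
  expect_equal(got$arc_length_um, oracle, tolerance = 1e-6)
  expect_equal(got$path_ratio, oracle / 10, tolerance = 1e-6)

  # continuity and monotonicity in the sagitta
  arcs <- vapply(c(1e-8, 0.5, 1, 2, 3.5, 5, 6),
                 function(h) arc_path_ratio(10, h, 10)$arc_length_um,
                 numeric(1))
  expect_equal(arcs[1], 10, tolerance = 1e-6)
  expect_true(all(diff(arcs) > 0))
  expect_true(all(arcs >= 10 - 1e-9))
  expect_error(arc_path_ratio(0, 1, 10), "> 0")
})

test_that("a null dividing scene yields uniform Mann-Whitney p-values", {
  # type-I control of the full render-measure-test pipeline: no caliber
  # offset, so region comparisons should be null over repeated seeds
  cfg <- run_config()
  ps <- vapply(1:200, function(seed) {
    # wide neighbor cells give ~15 stations per region, so the (tie-free)
    # Mann-Whitney p-values are nearly continuous and a KS check applies
    spec <- dividing_scene_spec(dividing_offset_um = 0,
                                flat_deflation_um = 0,
                                axon_baseline_um = 0.25,
                                l_flat_um = 12, neighbor_um = 14,
                                schedule_um = 8, rng_seed = seed)
    sc <- render_dividing_scene(spec)
    st <- sc$truth_stations[sc$truth_stations$frame == 1 &
                            !is.na(sc$truth_stations$region), ]
    rows <- lapply(st$s_um, function(s) {
      measure_at(sc$stack, sc$centerline, 1, s, cfg)
    })
    m <- do.call(rbind, rows)
    m$region <- st$region
    g <- group_by_region(m)
    mann_whitney_u(g$neighbor1, g$neighbor2)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
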