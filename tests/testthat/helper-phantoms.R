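# Shared fixture builders. Everything is generated in code at test time.

straight_phantom <- function(caliber_um, length_um = 21, seed = 1,
                             pearls = NULL, ...) {
  phantom_spec(rbind(c(0, 0), c(length_um, 0)),
               caliber_profile_spec(caliber_um, pearls),
               rng_seed = seed, ...)
}

# lengthwise recovery errors over interior stations of a straight phantom
recovery_errors <- function(caliber_um, seed, config = run_config()) {
  ph <- render_axon_image(straight_phantom(caliber_um, seed = seed))
  ser <- measure_lengthwise(ph$stack, ph$centerline, 1, config)
  m <- ser$measurements
  m <- m[m$s_um >= 1 & m$s_um <= 20, ]
  list(errors = m$caliber_um[!m$below_limit] - caliber_um,
       n_flagged = sum(m$below_limit), n = nrow(m))
}

# quarter circle of radius r as an n-vertex polyline
quarter_circle <- function(r, n) {
  th <- seq(0, pi / 2, length.out = n)
  cbind(r * cos(th), r * sin(th))
}

# a hand-built intensity profile object for peak-detection unit tests
make_profile <- function(offsets, intensities) {
  structure(list(offsets_um = offsets, intensities = intensities, frame = 1L),
            class = "intensity_profile")
}

# independent re-implementation of the peak-pair selection rule used as a
# grid-search oracle: scan every (negative, positive) pair of qualifying
# local maxima and take the pair minimising the distance of each member to
# the centreline (identical selection, different code path)
oracle_peak_pair <- function(offsets, y_smooth, min_prom_frac,
                             min_height_frac = 0.5) {
  n <- length(y_smooth)
  is_max <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    is_max[i] <- y_smooth[i] > y_smooth[i - 1] && y_smooth[i] >= y_smooth[i + 1]
  }
  rng <- max(y_smooth) - min(y_smooth)
  prom <- function(i) {
    lv <- Inf; j <- i - 1
    lmin <- y_smooth[i]
    while (j >= 1) {
      lmin <- min(lmin, y_smooth[j])
      if (y_smooth[j] > y_smooth[i]) break
      j <- j - 1
    }
    lb <- if (j >= 1 && y_smooth[j] > y_smooth[i]) lmin else min(y_smooth[1:i])
    rmin <- y_smooth[i]; j <- i + 1
    while (j <= n) {
      rmin <- min(rmin, y_smooth[j])
      if (y_smooth[j] > y_smooth[i]) break
      j <- j + 1
    }
    rb <- if (j <= n && y_smooth[j] > y_smooth[i]) rmin else min(y_smooth[i:n])
    y_smooth[i] - max(lb, rb)
  }
  qual <- which(is_max &
                vapply(seq_len(n), function(i) {
                  is_max[i] && prom(i) >= min_prom_frac * rng &&
                    y_smooth[i] >= min(y_smooth) + min_height_frac * rng
                }, logical(1)))
  best <- NULL; best_d <- Inf
  for (i in qual[offsets[qual] < 0]) {
    for (j in qual[offsets[qual] > 0]) {
      d <- abs(offsets[i]) + abs(offsets[j])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
  }
  best
}
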