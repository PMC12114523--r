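#' Extract a perpendicular intensity profile
#'
#' Samples the axon channel by bilinear interpolation along a line through
#' `center_um` in direction `normal`, at signed offsets
#' `-half_length..+half_length` (0 at the centerline).
#'
#' @param stack A `calibrated_stack`.
#' @param frame Frame index (1-based).
#' @param center_um Length-2 um position on the centerline.
#' @param normal Length-2 unit normal of the scan line.
#' @param half_length_um Scan half-length in um.
#' @param spacing_um Sample spacing (must be <= pixel size).
#' @param channel Channel role to sample (default `"axon"`).
#' @param tangent Optional length-2 unit tangent of the centerline; needed
#'   when `width_um > 0`.
#' @param width_um Scan-line width: pixel-spaced parallel lines within this
#'   width along `tangent` are averaged, as with a wide line-profile tool
#'   (reduces shot noise without affecting the peak separation of a locally
#'   straight axon). Default 0 (single line).
#' @return An object of class `intensity_profile`: list with `offsets_um`
#'   (strictly increasing, symmetric about 0), `intensities`, `frame`.
#' @export
extract_profile <- function(stack, frame, center_um, normal,
                            half_length_um, spacing_um, channel = "axon",
                            tangent = NULL, width_um = 0) {
  stopifnot(inherits(stack, "calibrated_stack"),
            spacing_um > 0, half_length_um > 0, width_um >= 0)
  if (spacing_um > stack$pixel_size_um + 1e-12) {
    stop("spacing_um must not exceed the pixel size")
  }
  normal <- normal / sqrt(sum(normal^2))
  k <- ceiling(half_length_um / spacing_um - 1e-9)
  offsets <- (-k:k) * spacing_um
  img <- frame_matrix(stack, frame, channel)
  lat <- 0
  if (width_um > 0) {
    if (is.null(tangent)) stop("width_um > 0 needs the centerline tangent")
    tangent <- tangent / sqrt(sum(tangent^2))
    nl <- floor(width_um / (2 * stack$pixel_size_um))
    lat <- (-nl:nl) * stack$pixel_size_um
  }
  acc <- 0
  for (l in lat) {
    ctr <- center_um + if (length(lat) > 1 || l != 0) l * tangent else 0
    pts <- cbind(ctr[1] + offsets * normal[1],
                 ctr[2] + offsets * normal[2])
    acc <- acc + bilinear(img, pts, stack$pixel_size_um)
  }
  structure(list(offsets_um = offsets, intensities = acc / length(lat),
                 frame = frame),
            class = "intensity_profile")
}

# bilinear interpolation of um-coordinate points on a (row, col) image
bilinear <- function(img, xy_um, pixel_size_um) {
  u <- xy_um[, 1] / pixel_size_um + 1
  v <- xy_um[, 2] / pixel_size_um + 1
  nr <- nrow(img); nc <- ncol(img)
  if (any(u < 1 - 1e-9 | u > nc + 1e-9 | v < 1 - 1e-9 | v > nr + 1e-9)) {
    stop("scan line leaves the image field")
  }
  u <- pmin(pmax(u, 1), nc); v <- pmin(pmax(v, 1), nr)
  c0 <- pmin(floor(u), nc - 1); r0 <- pmin(floor(v), nr - 1)
  fu <- u - c0; fv <- v - r0
  img[cbind(r0, c0)] * (1 - fu) * (1 - fv) +
    img[cbind(r0, c0 + 1)] * fu * (1 - fv) +
    img[cbind(r0 + 1, c0)] * (1 - fu) * fv +
    img[cbind(r0 + 1, c0 + 1)] * fu * fv
}

# topographic prominence of a local maximum at index i
peak_prominence <- function(y, i) {
  n <- length(y)
  left_base <- {
    j <- i; m <- y[i]
    while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; m <- min(m, y[j]) }
    if (j > 1) m else min(y[1:i])
  }
  right_base <- {
    j <- i; m <- y[i]
    while (j < n && y[j + 1] <= y[i]) { j <- j + 1; m <- min(m, y[j]) }
    if (j < n) m else min(y[i:n])
  }
  y[i] - max(left_base, right_base)
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# normalized Gaussian smoothing of profile samples (edge-renormalized so the
# ends are not pulled toward zero)
smooth_profile <- function(y, sigma_samples) {
  if (sigma_samples <= 0) return(y)
  r <- max(1L, ceiling(3 * sigma_samples))
  k <- exp(-((-r):r)^2 / (2 * sigma_samples^2))
  yp <- c(rep(0, r), y, rep(0, r))
  wp <- c(rep(0, r), rep(1, length(y)), rep(0, r))
  num <- stats::filter(yp, k, sides = 2)
  den <- stats::filter(wp, k, sides = 2)
  as.numeric(num / den)[(r + 1):(r + length(y))]
}

# sub-sample peak localization: least-squares quadratic vertex over up to
# 2h+1 samples. The window shrinks near the centreline so it never reaches
# into the opposite membrane peak of a barely-resolved pair; h = 1 is the
# classic 3-point parabola.
parabolic_refine <- function(x, y, i, h = 3L) {
  dx <- x[2] - x[1]
  h <- min(h, max(1L, floor(abs(x[i]) / dx / 2)))
  lo <- max(1L, i - h); hi <- min(length(y), i + h)
  if (hi - lo < 2) return(x[i])
  xs <- x[lo:hi] - x[i]
  ys <- y[lo:hi]
  X <- cbind(1, xs, xs^2)
  cf <- tryCatch(solve(crossprod(X), crossprod(X, ys)),
                 error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) {
    # degenerate curvature: fall back to the 3-point parabola
    if (i <= 1 || i >= length(y)) return(x[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(denom) < 1e-12) return(x[i])
    return(x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * dx)
  }
  x[i] - cf[2] / (2 * cf[3])
}

#' Detect the two membrane peaks of a line-scan profile
#'
#' Finds local maxima with topographic prominence at least
#' `min_prominence_frac` of the profile's intensity range, takes the
#' qualifying maxima nearest the centerline on the negative and on the
#' positive side (rejecting neighboring-axon crosstalk further out), and
#' refines each to sub-sample precision with a 3-point parabola. A profile
#' with no qualifying pair (e.g. unimodal, for an unresolved axon) returns
#' `resolved = FALSE` — that is a value, not an error.
#'
#' Two robustness guards against shot noise: the profile is first smoothed
#' with a small Gaussian (`smooth_sigma_um`, default 0.01 um — well below
#' the PSF width, so peak positions move negligibly), and a candidate must
#' also rise to at least `min_height_frac` of the intensity range (default
#' 0.5): the plasma-membrane peaks are the dominant structure of a scan
#' centred on the axon, while background noise ripples far from the
#' centerline are low even when locally prominent.
#'
#' @param profile An `intensity_profile` (>= 5 samples).
#' @param min_prominence_frac Prominence threshold as a fraction of
#'   `max - min` intensity (default 0.15).
#' @param refine Apply parabolic refinement (default `TRUE`).
#' @param smooth_sigma_um Pre-detection smoothing sd in um (0 disables).
#' @param min_height_frac Minimum peak height above the profile minimum,
#'   as a fraction of the intensity range.
#' @return List of class `membrane_peaks`: `resolved`, `left_um`,
#'   `right_um`, `raw_left_um`, `raw_right_um`, `quality` (smaller peak
#'   prominence / intensity range).
#' @export
detect_membrane_peaks <- function(profile, min_prominence_frac = 0.15,
                                  refine = TRUE, smooth_sigma_um = 0.01,
                                  min_height_frac = 0.5) {
  stopifnot(inherits(profile, "intensity_profile"))
  x <- profile$offsets_um
  if (length(profile$intensities) < 5) stop("profile needs >= 5 samples")
  y <- smooth_profile(profile$intensities, smooth_sigma_um / (x[2] - x[1]))
  rng <- max(y) - min(y)
  unresolved <- structure(list(resolved = FALSE, left_um = NA_real_,
                               right_um = NA_real_, raw_left_um = NA_real_,
                               raw_right_um = NA_real_, quality = 0),
                          class = "membrane_peaks")
  if (rng <= 0) return(unresolved)
  cand <- local_maxima(y)
  if (length(cand) == 0) return(unresolved)
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  qualify <- prom >= min_prominence_frac * rng &
    y[cand] >= min(y) + min_height_frac * rng
  ok <- cand[qualify]
  neg <- ok[x[ok] < 0]
  pos <- ok[x[ok] > 0]
  if (length(neg) == 0 || length(pos) == 0) return(unresolved)
  iL <- neg[which.max(x[neg])]   # nearest to centre on the left
  iR <- pos[which.min(x[pos])]   # nearest to centre on the right
  qual <- min(peak_prominence(y, iL), peak_prominence(y, iR)) / rng
  left <- if (refine) parabolic_refine(x, y, iL) else x[iL]
  right <- if (refine) parabolic_refine(x, y, iR) else x[iR]
  structure(list(resolved = TRUE, left_um = left, right_um = right,
                 raw_left_um = x[iL], raw_right_um = x[iR], quality = qual),
            class = "membrane_peaks")
}

#' Measure caliber at one centerline station
#'
#' Composes [extract_profile()] and [detect_membrane_peaks()]: the caliber is
#' the peak-to-peak distance. The measurement is flagged `below_limit` when
#' the peaks are unresolved or the caliber falls below
#' `config$resolution_limit_um`.
#'
#' @param stack A `calibrated_stack`.
#' @param cl A `centerline` in the stack's um coordinates.
#' @param frame Frame index.
#' @param s_um Arc-length coordinate of the station.
#' @param config A [run_config()].
#' @return One-row data frame: `frame`, `s_um`, `caliber_um`, `left_um`,
#'   `right_um`, `below_limit`, `quality`.
#' @export
measure_at <- function(stack, cl, frame, s_um, config = run_config()) {
  g <- interp_along(cl, s_um)
  prof <- extract_profile(stack, frame, g$position[1, ], g$normal[1, ],
                          half_length_um = config$scan_half_length_um,
                          spacing_um = scan_spacing(config, stack),
                          tangent = g$tangent[1, ],
                          width_um = config$scan_width_um)
  pk <- detect_membrane_peaks(prof, config$min_prominence_frac)
  caliber <- if (pk$resolved) pk$right_um - pk$left_um else NA_real_
  below <- !pk$resolved ||
    (is.finite(caliber) && caliber < config$resolution_limit_um)
  data.frame(frame = frame, s_um = s_um, caliber_um = caliber,
             left_um = pk$left_um, right_um = pk$right_um,
             below_limit = below, quality = pk$quality)
}

new_caliber_series <- function(measurements, mode) {
  structure(list(measurements = measurements, mode = mode),
            class = "caliber_series")
}

#' Summarize a caliber series
#'
#' Mean, sample SD (n - 1) and percent relative SD over the non-flagged
#' measurements. Flagged (below-limit) measurements are retained in the
#' table for transparency but excluded from every summary. In lengthwise
#' mode the SD across stations is the pearling index.
#'
#' @param series A `caliber_series`.
#' @return List: `mean_um`, `sd_um`, `rsd_percent`, `n_used`, `n_total`,
#'   `flagged_fraction`, `all_flagged`.
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "caliber_series"))
  m <- series$measurements
  use <- !m$below_limit & is.finite(m$caliber_um)
  v <- m$caliber_um[use]
  n_tot <- nrow(m)
  if (length(v) == 0) {
    return(list(mean_um = NA_real_, sd_um = NA_real_, rsd_percent = NA_real_,
                n_used = 0L, n_total = n_tot, flagged_fraction = 1,
                all_flagged = TRUE))
  }
  mu <- mean(v)
  sdv <- if (length(v) >= 2) stats::sd(v) else NA_real_
  list(mean_um = mu, sd_um = sdv,
       rsd_percent = if (is.na(sdv)) NA_real_ else 100 * sdv / mu,
       n_used = length(v), n_total = n_tot,
       flagged_fraction = mean(m$below_limit), all_flagged = FALSE)
}

#' @export
print.caliber_series <- function(x, ...) {
  s <- summarize_series(x)
  cat(sprintf("<caliber_series:%s> %d measurement(s), %d used; mean %.3f um, sd %.3f um\n",
              x$mode, s$n_total, s$n_used, s$mean_um, s$sd_um))
  invisible(x)
}

#' Lengthwise caliber profile of a segment
#'
#' Measures caliber at stations every `lengthwise_interval_um` along the
#' centerline, excluding stations closer than `branch_exclusion_um` to a
#' branch-point anchor.
#'
#' @param stack A `calibrated_stack`.
#' @param cl A `centerline` (its anchors are the branch points).
#' @param frame Frame index.
#' @param config A [run_config()].
#' @return A `caliber_series` ordered by `s_um` (mode `"lengthwise"`).
#' @export
measure_lengthwise <- function(stack, cl, frame = 1, config = run_config()) {
  st <- stations(cl, config$lengthwise_interval_um,
                 config$branch_exclusion_um)
  rows <- lapply(st$s_um, function(s) measure_at(stack, cl, frame, s, config))
  m <- if (length(rows) > 0) do.call(rbind, rows) else
    measure_at(stack, cl, frame, 0, config)[0, ]
  new_caliber_series(m[order(m$s_um), ], "lengthwise")
}

#' Caliber time series at a fixed station
#'
#' Measures one caliber per frame at arc-length `s_um`. A list of per-frame
#' centerlines re-anchors the station each frame (drifting annotations);
#' a single centerline reuses a fixed scan line.
#'
#' @param stack A multi-frame `calibrated_stack`.
#' @param cl A `centerline` or a list of one per frame.
#' @param s_um Station arc-length coordinate.
#' @param config A [run_config()].
#' @param frames Frames to measure (default all).
#' @return A `caliber_series` ordered by frame (mode `"time"`).
#' @export
measure_timeseries <- function(stack, cl, s_um, config = run_config(),
                               frames = seq_len(n_frames(stack))) {
  rows <- lapply(frames, function(f) {
    cli <- if (inherits(cl, "centerline")) cl else cl[[f]]
    measure_at(stack, cli, f, s_um, config)
  })
  new_caliber_series(do.call(rbind, rows), "time")
}

#' Below-resolution series exclusion rule
#'
#' A series is excluded when its flagged fraction is strictly greater than
#' `config$below_limit_series_fraction` (default 0.20): a series with
#' exactly 20 percent flagged is kept.
#'
#' @param series A `caliber_series`.
#' @param config A [run_config()].
#' @return `TRUE` if the series must be excluded.
#' @export
apply_series_exclusion <- function(series, config = run_config()) {
  stopifnot(inherits(series, "caliber_series"),
            nrow(series$measurements) > 0)
  mean(series$measurements$below_limit) >
    config$below_limit_series_fraction + 1e-12
}
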