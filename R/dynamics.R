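#' Caliber dynamicity of a time series
#'
#' Absolute dynamicity is the sample SD of caliber across frames at a fixed
#' location; relative dynamicity is `%RSD = 100 * SD / mean`. Flagged frames
#' are excluded; at least 3 usable frames are required.
#'
#' @param series A `caliber_series` in time mode.
#' @param config A [run_config()] (for the series exclusion rule).
#' @return List of class `dynamicity_summary`: `mean_caliber_um`, `sd_um`,
#'   `rsd_percent`, `n_frames_used`, `excluded`.
#' @export
#' @examples
#' # a constant series has SD 0 and %RSD 0
dynamicity <- function(series, config = run_config()) {
  stopifnot(inherits(series, "caliber_series"))
  s <- summarize_series(series)
  if (s$n_used < 3) {
    stop("dynamicity needs >= 3 non-flagged frames (have ", s$n_used, ")")
  }
  structure(list(mean_caliber_um = s$mean_um, sd_um = s$sd_um,
                 rsd_percent = s$rsd_percent, n_frames_used = s$n_used,
                 excluded = apply_series_exclusion(series, config)),
            class = "dynamicity_summary")
}

#' @export
print.dynamicity_summary <- function(x, ...) {
  cat(sprintf("<dynamicity> mean %.3f um, sd %.3f um, %%RSD %.1f (n = %d%s)\n",
              x$mean_caliber_um, x$sd_um, x$rsd_percent, x$n_frames_used,
              if (x$excluded) ", EXCLUDED" else ""))
  invisible(x)
}

#' Pair dynamicity across two developmental days
#'
#' Matches locations by key; locations missing or excluded on either day are
#' dropped (count recorded in the `n_dropped` attribute). The `delta` column
#' (day2 - day1) feeds the paired permutation test.
#'
#' @param day1,day2 Data frames with columns `location`, `rsd_percent` and
#'   optionally `excluded`.
#' @return Data frame `location`, `rsd_day1`, `rsd_day2`, `delta`, with
#'   attribute `n_dropped`.
#' @export
pair_days <- function(day1, day2) {
  stopifnot(all(c("location", "rsd_percent") %in% names(day1)),
            all(c("location", "rsd_percent") %in% names(day2)))
  keep <- function(df) {
    if ("excluded" %in% names(df)) df[!df$excluded, ] else df
  }
  d1 <- keep(day1); d2 <- keep(day2)
  m <- merge(d1[, c("location", "rsd_percent")],
             d2[, c("location", "rsd_percent")],
             by = "location", suffixes = c("_day1", "_day2"))
  if (nrow(m) == 0) stop("no matched locations between the two days")
  out <- data.frame(location = m$location,
                    rsd_day1 = m$rsd_percent_day1,
                    rsd_day2 = m$rsd_percent_day2)
  out$delta <- out$rsd_day2 - out$rsd_day1
  n_dropped <- (nrow(day1) - nrow(out)) + (nrow(day2) - nrow(out))
  attr(out, "n_dropped") <- n_dropped
  message(sprintf("pair_days: %d matched location(s), %d dropped",
                  nrow(out), n_dropped))
  out
}

#' Pearling index of a lengthwise profile
#'
#' Pearling is the sample SD of caliber across the lengthwise stations
#' (1 um interval set); below-limit stations are excluded.
#'
#' @param series A `caliber_series` in lengthwise mode (>= 3 usable
#'   stations).
#' @return Pearling SD in um.
#' @export
pearling_index <- function(series) {
  stopifnot(inherits(series, "caliber_series"))
  s <- summarize_series(series)
  if (s$n_used < 3) {
    stop("pearling index needs >= 3 non-flagged stations (have ",
         s$n_used, ")")
  }
  s$sd_um
}

#' Group dividing-scene measurements by cell region
#'
#' Splits station calibers into the three region samples
#' (dividing / neighbor1 / neighbor2) for the Mann-Whitney comparisons.
#' Flagged measurements are dropped; empty regions are reported with a
#' message and returned empty (the comparison is skipped downstream).
#'
#' @param measurements Data frame with `caliber_um`, `below_limit` and
#'   `region` columns (one frame of a dividing scene).
#' @return Named list of numeric vectors `dividing`, `neighbor1`,
#'   `neighbor2`.
#' @export
group_by_region <- function(measurements) {
  stopifnot(all(c("caliber_um", "below_limit", "region") %in%
                names(measurements)))
  m <- measurements[!measurements$below_limit &
                    is.finite(measurements$caliber_um) &
                    !is.na(measurements$region), ]
  out <- lapply(c(dividing = "dividing", neighbor1 = "neighbor1",
                  neighbor2 = "neighbor2"),
                function(r) m$caliber_um[m$region == r])
  empty <- names(out)[vapply(out, length, integer(1)) == 0]
  if (length(empty) > 0) {
    message("group_by_region: empty region sample(s): ",
            paste(empty, collapse = ", "))
  }
  out
}

# --- polygon / segment geometry -------------------------------------------

# crossing points of a polyline with a polygon boundary
polyline_polygon_crossings <- function(path_xy, poly_xy) {
  closed <- rbind(poly_xy, poly_xy[1, ])
  hits <- NULL
  for (i in seq_len(nrow(path_xy) - 1)) {
    p <- path_xy[i, ]; r <- path_xy[i + 1, ] - path_xy[i, ]
    for (j in seq_len(nrow(closed) - 1)) {
      q <- closed[j, ]; s <- closed[j + 1, ] - closed[j, ]
      denom <- r[1] * s[2] - r[2] * s[1]
      if (abs(denom) < 1e-12) next
      t <- ((q[1] - p[1]) * s[2] - (q[2] - p[2]) * s[1]) / denom
      u <- ((q[1] - p[1]) * r[2] - (q[2] - p[2]) * r[1]) / denom
      if (t >= -1e-9 && t <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) {
        hits <- rbind(hits, c(p[1] + t * r[1], p[2] + t * r[2]))
      }
    }
  }
  if (is.null(hits)) return(matrix(numeric(0), 0, 2))
  unique(round(hits, 9))
}

#' Border-to-border axon length across the dividing cell
#'
#' Straight-line distance between the two points where the axon path crosses
#' the border polygon of the dividing cell (or its daughters' combined
#' territory) in one frame.
#'
#' @param scene_annotations An `annotation_set` with per-frame `"dividing"`
#'   cell borders and an `"axon"` centerline.
#' @param frame Frame index.
#' @return Length in um.
#' @export
border_to_border <- function(scene_annotations, frame) {
  stopifnot(inherits(scene_annotations, "annotation_set"))
  poly <- NULL; path <- NULL
  for (e in scene_annotations$cell_borders) {
    if (e$frame == frame && e$label == "dividing") poly <- e$xy
  }
  for (e in scene_annotations$centerlines) {
    if (e$frame == frame && e$label == "axon") path <- e$xy
  }
  if (is.null(poly)) stop("no 'dividing' cell border in frame ", frame)
  if (is.null(path)) stop("no 'axon' centerline in frame ", frame)
  hits <- polyline_polygon_crossings(path, poly)
  if (nrow(hits) < 2) {
    stop("axon path crosses the dividing-cell border ", nrow(hits),
         " time(s); need 2")
  }
  # the two extreme crossings along the path direction
  dirv <- path[nrow(path), ] - path[1, ]
  proj <- hits %*% (dirv / sqrt(sum(dirv^2)))
  a <- hits[which.min(proj), ]; b <- hits[which.max(proj), ]
  sqrt(sum((b - a)^2))
}

#' Select the round and flat frames from border-to-border lengths
#'
#' The rounding-to-flattening transition is the consecutive frame pair with
#' the largest length increase. Ties take the earliest pair (`tie_flag`);
#' a never-increasing schedule returns the least-negative change with a
#' warning.
#'
#' @param lengths_um Border-to-border length per frame (>= 2 frames).
#' @return List: `round_frame`, `flat_frame` (= round + 1), `delta_um`,
#'   `tie_flag`.
#' @export
select_round_flat <- function(lengths_um) {
  stopifnot(length(lengths_um) >= 2)
  d <- diff(lengths_um)
  k <- which.max(d)                 # earliest index at the maximum
  tie <- sum(abs(d - d[k]) < 1e-12) > 1
  if (d[k] <= 0) {
    warning("border-to-border length never increases; degenerate schedule")
  }
  list(round_frame = k, flat_frame = k + 1L, delta_um = d[k],
       tie_flag = tie)
}

#' Pair calibers between the round and flat frames
#'
#' Builds per-station (round, flat) caliber pairs for the stations that
#' remained on the dividing cell or its daughters in both frames, plus the
#' per-axon pearling-index pair. Stations flagged in either frame or leaving
#' the region are dropped (counts messaged).
#'
#' @param measurements Data frame with `frame`, `s_um`, `caliber_um`,
#'   `below_limit`, `region` for at least the two selected frames.
#' @param round_frame,flat_frame Frame indices from [select_round_flat()].
#' @param region Region whose stations are paired (default `"dividing"`).
#' @return List: `pairs` (data frame `s_um`, `round_um`, `flat_um`,
#'   `delta_um`), `pearling_round_um`, `pearling_flat_um`, `n_dropped`.
#' @export
round_flat_pairing <- function(measurements, round_frame, flat_frame,
                               region = "dividing") {
  m <- measurements
  mr <- m[m$frame == round_frame, ]
  mf <- m[m$frame == flat_frame, ]
  j <- merge(mr, mf, by = "s_um", suffixes = c("_round", "_flat"))
  ok <- !j$below_limit_round & !j$below_limit_flat &
    !is.na(j$region_round) & !is.na(j$region_flat) &
    j$region_round == region & j$region_flat == region
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("round_flat_pairing: dropped ", n_dropped,
            " station(s) (flagged or left the region)")
  }
  jj <- j[ok, ]
  pairs <- data.frame(s_um = jj$s_um, round_um = jj$caliber_um_round,
                      flat_um = jj$caliber_um_flat)
  pairs$delta_um <- pairs$flat_um - pairs$round_um
  pr <- if (nrow(pairs) >= 3) stats::sd(pairs$round_um) else NA_real_
  pf <- if (nrow(pairs) >= 3) stats::sd(pairs$flat_um) else NA_real_
  list(pairs = pairs, pearling_round_um = pr, pearling_flat_um = pf,
       n_dropped = n_dropped)
}

#' Circular-arc model of the axon path over a rounded cell
#'
#' Models the axon path across a mitotically rounded basal cell as a
#' circular arc with chord `chord_um` (the rounded cell's planar extent) and
#' sagitta `sagitta_um` (its height above the flat reference):
#' `R = (chord^2/4 + sagitta^2) / (2 sagitta)`, `arc = 2 R asin(chord/(2R))`;
#' a zero sagitta gives `arc = chord`. The path ratio compares the arc to
#' the flat-state path (the flat cell's planar length, the axon assumed
#' straight and adherent at the borders).
#'
#' @param chord_um Chord length (> 0).
#' @param sagitta_um Arc height (>= 0).
#' @param flat_length_um Flat-state path length (>= chord).
#' @return List of class `arc_model`: `chord_um`, `sagitta_um`,
#'   `radius_um`, `arc_length_um`, `flat_length_um`, `path_ratio`.
#' @export
#' @examples
#' arc_path_ratio(10, 5, 10)$arc_length_um  # semicircle: 5 * pi
arc_path_ratio <- function(chord_um, sagitta_um, flat_length_um) {
  if (chord_um <= 0) stop("chord must be > 0")
  stopifnot(sagitta_um >= 0, flat_length_um >= chord_um)
  if (sagitta_um == 0) {
    R <- Inf
    arc <- chord_um
  } else {
    R <- (chord_um^2 / 4 + sagitta_um^2) / (2 * sagitta_um)
    half_angle <- asin(min(1, chord_um / (2 * R)))
    # sagitta beyond the semicircle (h > chord/2): major arc
    if (sagitta_um > chord_um / 2) half_angle <- pi - half_angle
    arc <- 2 * R * half_angle
  }
  structure(list(chord_um = chord_um, sagitta_um = sagitta_um,
                 radius_um = R, arc_length_um = arc,
                 flat_length_um = flat_length_um,
                 path_ratio = arc / flat_length_um),
            class = "arc_model")
}

#' @export
print.arc_model <- function(x, ...) {
  cat(sprintf("<arc_model> chord %.2f, sagitta %.2f -> arc %.3f um; path ratio %.3f\n",
              x$chord_um, x$sagitta_um, x$arc_length_um, x$path_ratio))
  invisible(x)
}
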