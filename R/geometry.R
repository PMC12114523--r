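#' Arc-length parameterized axon centerline
#'
#' Resamples an annotated polyline at a fixed arc-length step and attaches
#' unit tangents (central differences, boxcar-smoothed) and unit normals.
#' All coordinates are in micrometres; the normal is the tangent rotated by
#' +90 degrees (`(-ty, tx)`).
#'
#' @param polyline_xy Numeric matrix (n x 2) of vertices in um, n >= 2.
#' @param step_um Resampling step along arc length (default 0.05 um).
#' @param smooth_window_um Tangent smoothing window (default 0.5 um);
#'   suppresses annotation jitter at the resampling scale without erasing
#'   real curvature.
#' @param anchors_s Optional numeric vector of branch-point arc-length
#'   coordinates (um) on this centerline.
#'
#' @return An object of class `centerline`: list with `xy` (m x 2), `s`
#'   (strictly increasing arc length from 0), `tangent`, `normal` (m x 2 unit
#'   vectors), `anchors_s`, `step_um`, `length_um`.
#' @export
#' @examples
#' cl <- build_centerline(rbind(c(0, 0), c(10, 0)))
#' cl$length_um
build_centerline <- function(polyline_xy, step_um = 0.05,
                             smooth_window_um = 0.5, anchors_s = numeric(0)) {
  polyline_xy <- as.matrix(polyline_xy)
  stopifnot(ncol(polyline_xy) == 2, nrow(polyline_xy) >= 2,
            all(is.finite(polyline_xy)), step_um > 0)
  # drop consecutive duplicate vertices
  d <- sqrt(rowSums((polyline_xy[-1, , drop = FALSE] -
                     polyline_xy[-nrow(polyline_xy), , drop = FALSE])^2))
  keep <- c(TRUE, d > 1e-12)
  polyline_xy <- polyline_xy[keep, , drop = FALSE]
  if (nrow(polyline_xy) < 2) stop("polyline has zero length")
  d <- sqrt(rowSums((polyline_xy[-1, , drop = FALSE] -
                     polyline_xy[-nrow(polyline_xy), , drop = FALSE])^2))
  s_in <- c(0, cumsum(d))
  total <- s_in[length(s_in)]

  s <- seq(0, total, by = step_um)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  x <- stats::approx(s_in, polyline_xy[, 1], xout = s)$y
  y <- stats::approx(s_in, polyline_xy[, 2], xout = s)$y
  xy <- cbind(x, y)
  m <- nrow(xy)

  # central-difference tangents, one-sided at the endpoints
  tg <- matrix(0, m, 2)
  if (m >= 3) {
    tg[2:(m - 1), ] <- xy[3:m, , drop = FALSE] - xy[1:(m - 2), , drop = FALSE]
  }
  tg[1, ] <- xy[2, ] - xy[1, ]
  tg[m, ] <- xy[m, ] - xy[m - 1, ]

  w <- max(1L, round(smooth_window_um / step_um))
  if (w %% 2 == 0) w <- w + 1L
  if (w > 1 && m > w) {
    tg[, 1] <- boxcar(tg[, 1], w)
    tg[, 2] <- boxcar(tg[, 2], w)
  }
  nrm <- sqrt(rowSums(tg^2))
  nrm[nrm == 0] <- 1
  tg <- tg / nrm
  nm <- cbind(-tg[, 2], tg[, 1])

  structure(list(xy = xy, s = s, tangent = tg, normal = nm,
                 anchors_s = sort(as.numeric(anchors_s)),
                 step_um = step_um, length_um = total),
            class = "centerline")
}

# moving average with shrinking window at the edges (no phase shift)
boxcar <- function(v, w) {
  h <- (w - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %.3f um, %d vertices, step %.3g um, %d anchor(s)\n",
              x$length_um, nrow(x$xy), x$step_um, length(x$anchors_s)))
  invisible(x)
}

#' Interpolate position, tangent and normal at an arc-length coordinate
#'
#' @param cl A `centerline`.
#' @param s_um Arc-length coordinate(s), 0 <= s <= length.
#' @return List with `position`, `tangent`, `normal` (each length(s) x 2,
#'   tangent/normal renormalized after interpolation).
#' @export
interp_along <- function(cl, s_um) {
  stopifnot(inherits(cl, "centerline"))
  if (any(s_um < -1e-9 | s_um > cl$length_um + 1e-9)) {
    stop(sprintf("arc-length coordinate outside [0, %.4f] um", cl$length_um))
  }
  s_um <- pmin(pmax(s_um, 0), cl$length_um)
  comp <- function(mat) {
    cbind(stats::approx(cl$s, mat[, 1], xout = s_um)$y,
          stats::approx(cl$s, mat[, 2], xout = s_um)$y)
  }
  pos <- comp(cl$xy)
  tg <- comp(cl$tangent)
  nrm <- sqrt(rowSums(tg^2)); nrm[nrm == 0] <- 1
  tg <- tg / nrm
  list(position = pos, tangent = tg, normal = cbind(-tg[, 2], tg[, 1]))
}

#' Point at a geodesic distance from the branch-point anchor
#'
#' Walks the stated distance along the centerline (not straight-line) from
#' the first anchor, mirroring offset measurements taken "N um from the
#' branch point" along the axon's course.
#'
#' @param cl A `centerline` with at least one anchor.
#' @param from_anchor_um Distance along the path from the anchor, >= 0.
#' @param mode `"along_path"` (default) or `"straight_line"`; the latter
#'   returns the first centerline point whose Euclidean distance from the
#'   anchor equals `from_anchor_um`.
#' @return List with `position`, `tangent`, `normal` (1 x 2 each) and `s_um`.
#' @export
point_at_distance <- function(cl, from_anchor_um, mode = "along_path") {
  stopifnot(inherits(cl, "centerline"))
  if (length(cl$anchors_s) == 0) stop("centerline has no anchor")
  anchor <- cl$anchors_s[1]
  if (from_anchor_um < 0) stop("distance must be >= 0")
  if (mode == "along_path") {
    s <- anchor + from_anchor_um
    if (s > cl$length_um + 1e-9) {
      stop(sprintf("distance %.3f um exceeds available length %.3f um",
                   from_anchor_um, cl$length_um - anchor))
    }
  } else {
    a <- interp_along(cl, anchor)$position
    dd <- sqrt(rowSums((cl$xy - matrix(a, nrow(cl$xy), 2, byrow = TRUE))^2))
    ok <- which(cl$s >= anchor & dd >= from_anchor_um)
    if (length(ok) == 0) {
      stop(sprintf("no centerline point at straight-line distance %.3f um",
                   from_anchor_um))
    }
    i <- ok[1]
    if (i == 1) {
      s <- cl$s[1]
    } else {
      # linear interpolation of the crossing between vertices i-1 and i
      f <- (from_anchor_um - dd[i - 1]) / (dd[i] - dd[i - 1])
      s <- cl$s[i - 1] + f * (cl$s[i] - cl$s[i - 1])
    }
  }
  g <- interp_along(cl, s)
  list(position = g$position[1, ], tangent = g$tangent[1, ],
       normal = g$normal[1, ], s_um = s)
}

#' Measurement stations along a centerline
#'
#' Places stations every `interval_um` of arc length, omitting stations whose
#' along-path distance to any branch-point anchor is strictly less than
#' `exclusion_um` (a station at exactly the exclusion distance is kept).
#'
#' @param cl A `centerline`.
#' @param interval_um Station spacing (> 0).
#' @param exclusion_um Branch-point exclusion radius (default 0).
#' @param anchors_s Anchor coordinates; defaults to the centerline's own.
#' @return Data frame with `s_um`, `x_um`, `y_um`, `nx`, `ny` (unit normal).
#' @export
stations <- function(cl, interval_um, exclusion_um = 0,
                     anchors_s = cl$anchors_s) {
  stopifnot(inherits(cl, "centerline"), interval_um > 0, exclusion_um >= 0)
  s <- seq(0, cl$length_um + 1e-9, by = interval_um)
  s <- s[s <= cl$length_um + 1e-9]
  s <- pmin(s, cl$length_um)
  if (length(anchors_s) > 0 && exclusion_um > 0) {
    keep <- vapply(s, function(si) {
      min(abs(si - anchors_s)) >= exclusion_um - 1e-9
    }, logical(1))
    s <- s[keep]
  }
  if (length(s) == 0) {
    return(data.frame(s_um = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      nx = numeric(0), ny = numeric(0)))
  }
  g <- interp_along(cl, s)
  data.frame(s_um = s, x_um = g$position[, 1], y_um = g$position[, 2],
             nx = g$normal[, 1], ny = g$normal[, 2])
}
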