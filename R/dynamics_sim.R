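#' Time-lapse caliber dynamics event
#'
#' One of the four qualitative classes of short-timescale caliber dynamics:
#' a traveling pearl, focal inflation/deflation, segment-wide
#' widening/narrowing, or a transient constriction point.
#'
#' @param class One of `"traveling_pearl"`, `"focal_inflation_deflation"`,
#'   `"segment_widening_narrowing"`, `"constriction_point"`.
#' @param ... Class-specific parameters:
#'   \describe{
#'     \item{traveling_pearl}{`center0_s_um`, `amplitude_um`, `width_s_um`,
#'       `speed_um_per_frame`}
#'     \item{focal_inflation_deflation}{`center_s_um`, `amplitude_um`,
#'       `width_s_um`, `start_frame`, `rise_frames`, `fall_frames`}
#'     \item{segment_widening_narrowing}{`span_s_um` (length-2), `factor`,
#'       `start_frame`, `rise_frames`, `fall_frames`}
#'     \item{constriction_point}{`center_s_um`, `depth_um` (> 0),
#'       `width_s_um`, `active_frames` (integer vector)}
#'   }
#' @return An object of class `dynamics_event`.
#' @export
dynamics_event <- function(class = c("traveling_pearl",
                                     "focal_inflation_deflation",
                                     "segment_widening_narrowing",
                                     "constriction_point"), ...) {
  class <- match.arg(class)
  p <- list(...)
  need <- switch(class,
    traveling_pearl = c("center0_s_um", "amplitude_um", "width_s_um",
                        "speed_um_per_frame"),
    focal_inflation_deflation = c("center_s_um", "amplitude_um",
                                  "width_s_um", "start_frame",
                                  "rise_frames", "fall_frames"),
    segment_widening_narrowing = c("span_s_um", "factor", "start_frame",
                                   "rise_frames", "fall_frames"),
    constriction_point = c("center_s_um", "depth_um", "width_s_um",
                           "active_frames"))
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    stop("event '", class, "' needs parameters: ",
         paste(missing, collapse = ", "))
  }
  dims <- intersect(names(p), c("amplitude_um", "width_s_um", "depth_um"))
  for (nm in dims) if (any(p[[nm]] <= 0)) stop(nm, " must be > 0")
  structure(c(list(event_class = class), p), class = "dynamics_event")
}

# linear up-then-down ramp in [0, 1] used by transient events
event_ramp <- function(t, start, rise, fall) {
  if (t < start) return(0)
  if (t <= start + rise) return((t - start) / max(rise, 1))
  if (t <= start + rise + fall) {
    return(1 - (t - start - rise) / max(fall, 1))
  }
  0
}

# ground-truth caliber at arc positions s for frame t under the events
caliber_at_frame <- function(profile, events, s_um, t) {
  c_s <- rep(profile$baseline_um, length(s_um))
  scale <- rep(1, length(s_um))
  for (ev in events) {
    cls <- ev$event_class
    if (cls == "traveling_pearl") {
      ctr <- ev$center0_s_um + ev$speed_um_per_frame * (t - 1)
      c_s <- c_s + ev$amplitude_um *
        exp(-(s_um - ctr)^2 / (2 * ev$width_s_um^2))
    } else if (cls == "focal_inflation_deflation") {
      a <- ev$amplitude_um *
        event_ramp(t, ev$start_frame, ev$rise_frames, ev$fall_frames)
      c_s <- c_s + a * exp(-(s_um - ev$center_s_um)^2 / (2 * ev$width_s_um^2))
    } else if (cls == "segment_widening_narrowing") {
      m <- 1 + (ev$factor - 1) *
        event_ramp(t, ev$start_frame, ev$rise_frames, ev$fall_frames)
      inside <- s_um >= ev$span_s_um[1] & s_um <= ev$span_s_um[2]
      scale[inside] <- scale[inside] * m
    } else if (cls == "constriction_point") {
      if (t %in% ev$active_frames) {
        c_s <- c_s - ev$depth_um *
          exp(-(s_um - ev$center_s_um)^2 / (2 * ev$width_s_um^2))
      }
    }
  }
  # static pearls from the base profile ride on top of the events
  for (i in seq_len(nrow(profile$pearls))) {
    p <- profile$pearls[i, ]
    c_s <- c_s + p$amplitude_um *
      exp(-(s_um - p$center_s_um)^2 / (2 * p$width_s_um^2))
  }
  pmax(c_s * scale, profile$floor_um)
}

#' Render a time-lapse phantom with caliber dynamics events
#'
#' Each frame is rendered like [render_axon_image()] with the event-modified
#' caliber profile; the per-frame ground truth c(s, t) is exported at 0.1 um
#' steps.
#'
#' @param spec A `phantom_spec` (its caliber profile is the resting state).
#' @param events List of [dynamics_event()] objects.
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval_min Minutes between frames (default 5).
#' @param noise Apply the noise model (default `TRUE`).
#' @return List of class `axon_phantom` with a multi-frame `stack` and
#'   `truth` data frame (`frame`, `s_um`, `c_um`).
#' @export
render_timelapse <- function(spec, events = list(), n_frames,
                             frame_interval_min = 5, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), n_frames >= 1)
  cl <- build_centerline(spec$centerline_xy, anchors_s = spec$anchors_s)
  for (ev in events) {
    ctr <- switch(ev$event_class,
      traveling_pearl = ev$center0_s_um,
      segment_widening_narrowing = mean(ev$span_s_um),
      ev$center_s_um)
    if (ctr < 0 || ctr > cl$length_um) {
      stop(sprintf("event '%s' centered at %.2f um lies outside [0, %.2f]",
                   ev$event_class, ctr, cl$length_um))
    }
  }
  set.seed(spec$rng_seed)
  frames <- vector("list", n_frames)
  s_truth <- seq(0, cl$length_um, by = 0.1)
  truth <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    img <- render_frame(spec, function(s) {
      caliber_at_frame(spec$caliber_profile, events, s, t)
    })
    if (noise) img <- apply_noise(img, spec)
    frames[[t]] <- img
    truth[[t]] <- data.frame(
      frame = t, s_um = s_truth,
      c_um = caliber_at_frame(spec$caliber_profile, events, s_truth, t))
  }
  px <- array(0, c(n_frames, nrow(frames[[1]]), ncol(frames[[1]]), 1L))
  for (t in seq_len(n_frames)) px[t, , , 1] <- frames[[t]]
  structure(list(
    stack = calibrated_stack(px, spec$pixel_size_um,
                             frame_interval_min = frame_interval_min),
    truth = do.call(rbind, truth), centerline = cl, spec = spec),
    class = "axon_phantom")
}
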