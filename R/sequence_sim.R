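#' Render a time lapse with a prescribed per-frame baseline caliber
#'
#' Companion to [render_timelapse()] for controlled dynamicity experiments:
#' frame `t` is rendered with the spec's caliber profile whose baseline is
#' replaced by `baseline_um_per_frame[t]`, so the ground-truth mean, SD and
#' percent RSD of the series are known exactly.
#'
#' @param spec A `phantom_spec`.
#' @param baseline_um_per_frame Baseline caliber per frame (all > 0).
#' @param frame_interval_min Minutes between frames (default 5).
#' @param noise Apply the noise model (default `TRUE`).
#' @return An `axon_phantom` with a multi-frame stack and per-frame truth.
#' @export
render_caliber_sequence <- function(spec, baseline_um_per_frame,
                                    frame_interval_min = 5, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"),
            all(baseline_um_per_frame > 0))
  n_fr <- length(baseline_um_per_frame)
  cl <- build_centerline(spec$centerline_xy, anchors_s = spec$anchors_s)
  set.seed(spec$rng_seed)
  frames <- vector("list", n_fr)
  s_truth <- seq(0, cl$length_um, by = 0.1)
  truth <- vector("list", n_fr)
  base_prof <- spec$caliber_profile
  for (t in seq_len(n_fr)) {
    prof_t <- caliber_profile_spec(baseline_um_per_frame[t],
                                   base_prof$pearls, base_prof$floor_um)
    img <- render_frame(spec, function(s) eval_caliber_profile(prof_t, s))
    if (noise) img <- apply_noise(img, spec)
    frames[[t]] <- img
    truth[[t]] <- data.frame(frame = t, s_um = s_truth,
                             c_um = eval_caliber_profile(prof_t, s_truth))
  }
  px <- array(0, c(n_fr, nrow(frames[[1]]), ncol(frames[[1]]), 1L))
  for (t in seq_len(n_fr)) px[t, , , 1] <- frames[[t]]
  structure(list(
    stack = calibrated_stack(px, spec$pixel_size_um,
                             frame_interval_min = frame_interval_min),
    truth = do.call(rbind, truth), centerline = cl, spec = spec),
    class = "axon_phantom")
}
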