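#' Caliber profile specification
#'
#' Describes ground-truth caliber along an axon as a resting baseline plus
#' Gaussian "pearl" bumps (negative amplitudes model constrictions), clamped
#' from below at `floor_um`.
#'
#' @param baseline_um Resting caliber in um (> 0).
#' @param pearls Data frame with columns `center_s_um`, `amplitude_um`,
#'   `width_s_um` (Gaussian sd along arc length), or `NULL` for none.
#' @param floor_um Minimum caliber clamp (> 0).
#' @return An object of class `caliber_profile_spec`.
#' @export
#' @examples
#' sp <- caliber_profile_spec(0.3,
#'   data.frame(center_s_um = 5, amplitude_um = 0.4, width_s_um = 0.5))
#' eval_caliber_profile(sp, 5)  # 0.7 at the pearl peak
caliber_profile_spec <- function(baseline_um, pearls = NULL,
                                 floor_um = 0.05) {
  stopifnot(baseline_um > 0, floor_um > 0)
  if (is.null(pearls)) {
    pearls <- data.frame(center_s_um = numeric(0), amplitude_um = numeric(0),
                         width_s_um = numeric(0))
  }
  stopifnot(all(c("center_s_um", "amplitude_um", "width_s_um") %in%
                names(pearls)),
            all(pearls$width_s_um > 0),
            all(pearls$amplitude_um >= -baseline_um))
  structure(list(baseline_um = baseline_um, pearls = pearls,
                 floor_um = floor_um),
            class = "caliber_profile_spec")
}

#' Evaluate a caliber profile
#'
#' `c(s) = max(floor, baseline + sum(amp * exp(-(s - center)^2 / (2 width^2))))`
#'
#' @param spec A `caliber_profile_spec`.
#' @param s_um Arc-length positions (um).
#' @return Caliber in um at each position.
#' @export
eval_caliber_profile <- function(spec, s_um) {
  stopifnot(inherits(spec, "caliber_profile_spec"))
  c_s <- rep(spec$baseline_um, length(s_um))
  for (i in seq_len(nrow(spec$pearls))) {
    p <- spec$pearls[i, ]
    c_s <- c_s + p$amplitude_um *
      exp(-(s_um - p$center_s_um)^2 / (2 * p$width_s_um^2))
  }
  pmax(c_s, spec$floor_um)
}

#' Phantom specification for a membrane-labeled axon
#'
#' The membrane is modeled as an infinitely thin label sheet at +/- c(s)/2
#' along the centerline normal (two lines in 2-D), matching the double-peak
#' line scans of membrane-tagged axons.
#'
#' @param centerline_xy Control points (n x 2, um) of the axon path. If
#'   `field_um` is `NULL` the path is translated so that its bounding box
#'   sits `margin_um` inside an auto-sized field.
#' @param caliber_profile A `caliber_profile_spec`.
#' @param psf_sigma_um Isotropic Gaussian PSF sd (default 0.07 um, a
#'   super-resolution-class lateral width).
#' @param photons_per_um_membrane Label density: expected counts contributed
#'   by one um of membrane to its full transverse line spread.
#' @param background_level Mean background counts per pixel.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param pixel_size_um Pixel size (default 0.04 um).
#' @param field_um `c(width, height)` in um, or `NULL` for auto.
#' @param margin_um Margin used when auto-sizing (default 2 um, which keeps
#'   the default 1.5 um line scans inside the field).
#' @param anchors_s Branch-point arc-length coordinates carried onto the
#'   ground-truth centerline.
#' @param rng_seed Seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(centerline_xy, caliber_profile,
                         psf_sigma_um = 0.07,
                         photons_per_um_membrane = 200,
                         background_level = 10,
                         read_noise_sd = 2,
                         pixel_size_um = 0.04,
                         field_um = NULL,
                         margin_um = 2,
                         anchors_s = numeric(0),
                         rng_seed = 1L) {
  stopifnot(psf_sigma_um > 0, photons_per_um_membrane > 0,
            background_level >= 0, read_noise_sd >= 0, pixel_size_um > 0)
  centerline_xy <- as.matrix(centerline_xy)
  if (is.null(field_um)) {
    shift <- margin_um - apply(centerline_xy, 2, min)
    centerline_xy <- sweep(centerline_xy, 2, shift, "+")
    field_um <- apply(centerline_xy, 2, max) + margin_um
  }
  # margin check: caliber + 3 sigma must stay inside the field
  cmax <- max(eval_caliber_profile(caliber_profile,
                                   seq(0, poly_len(centerline_xy),
                                       length.out = 200)))
  need <- cmax / 2 + 3 * psf_sigma_um
  lo <- apply(centerline_xy, 2, min)
  hi <- field_um - apply(centerline_xy, 2, max)
  if (min(lo, hi) < need) {
    stop(sprintf("field margin %.3f um < caliber/2 + 3 sigma = %.3f um",
                 min(lo, hi), need))
  }
  structure(list(centerline_xy = centerline_xy,
                 caliber_profile = caliber_profile,
                 psf_sigma_um = psf_sigma_um,
                 photons_per_um_membrane = photons_per_um_membrane,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 pixel_size_um = pixel_size_um,
                 field_um = field_um,
                 anchors_s = anchors_s,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

poly_len <- function(xy) {
  sum(sqrt(rowSums((xy[-1, , drop = FALSE] -
                    xy[-nrow(xy), , drop = FALSE])^2)))
}

# --- rasterization helpers -------------------------------------------------

# bilinear splat of weighted points (um coords) into a (nr x nc) count image
splat <- function(img, xy_um, w, pixel_size_um) {
  u <- xy_um[, 1] / pixel_size_um + 1  # continuous col coordinate
  v <- xy_um[, 2] / pixel_size_um + 1  # continuous row coordinate
  c0 <- floor(u); r0 <- floor(v)
  fu <- u - c0; fv <- v - r0
  nr <- nrow(img); nc <- ncol(img)
  add <- function(r, cc, wt) {
    ok <- r >= 1 & r <= nr & cc >= 1 & cc <= nc & wt > 0
    if (!any(ok)) return()
    k <- (cc[ok] - 1) * nr + r[ok]
    agg <- rowsum(wt[ok], k)
    idx <- as.numeric(rownames(agg))
    img[idx] <<- img[idx] + agg[, 1]
  }
  add(r0,     c0,     w * (1 - fu) * (1 - fv))
  add(r0,     c0 + 1, w * fu       * (1 - fv))
  add(r0 + 1, c0,     w * (1 - fu) * fv)
  add(r0 + 1, c0 + 1, w * fu       * fv)
  img
}

# separable Gaussian blur; 1-D kernels normalized to unit peak so that
# photons_per_um_membrane equals the full transverse line-spread integral
# contributed per um of membrane
gauss_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / max(k)
}

conv_cols <- function(M, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(M)
  Mp <- rbind(matrix(0, r, ncol(M)), M, matrix(0, r, ncol(M)))
  F <- stats::filter(Mp, k, sides = 2)
  matrix(F[(r + 1):(r + nr), ], nr, ncol(M))
}

blur_psf <- function(img, sigma_px) {
  k <- gauss_kernel(sigma_px)
  t(conv_cols(t(conv_cols(img, k)), k))
}

# render one frame given a per-position caliber function c(s)
render_frame <- function(spec, caliber_fun) {
  fs <- min(spec$pixel_size_um / 4, 0.01)
  cl <- build_centerline(spec$centerline_xy, step_um = fs,
                         smooth_window_um = 0.25)
  c_s <- caliber_fun(cl$s)
  nr <- round(spec$field_um[2] / spec$pixel_size_um) + 1L
  nc <- round(spec$field_um[1] / spec$pixel_size_um) + 1L
  img <- matrix(0, nr, nc)
  w <- rep(spec$photons_per_um_membrane * fs, nrow(cl$xy))
  for (side in c(-0.5, 0.5)) {
    b <- cl$xy + cl$normal * (side * c_s)
    img <- splat(img, b, w, spec$pixel_size_um)
  }
  blur_psf(img, spec$psf_sigma_um / spec$pixel_size_um)
}

apply_noise <- function(img, spec) {
  n <- length(img)
  noisy <- stats::rpois(n, lambda = as.vector(img) + spec$background_level) +
    stats::rnorm(n, sd = spec$read_noise_sd)
  matrix(pmax(noisy, 0), nrow(img), ncol(img))
}

#' Render a single-frame membrane-labeled axon phantom
#'
#' Boundary curves at +/- c(s)/2 along the centerline normal are finely
#' sampled, bilinearly splatted with line-integrated label density, blurred
#' with the Gaussian PSF, and (optionally) degraded with Poisson shot noise
#' on signal + background plus Gaussian read noise. Reproducible for a fixed
#' `rng_seed`.
#'
#' @param spec A `phantom_spec`.
#' @param noise Apply the noise model (default `TRUE`).
#' @return List of class `axon_phantom`: `stack` (a `calibrated_stack`),
#'   `truth` (data frame `s_um`, `c_um` at 0.1 um steps), `centerline`
#'   (ground-truth `centerline` with the spec's anchors), `spec`.
#' @export
render_axon_image <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- render_frame(spec,
                      function(s) eval_caliber_profile(spec$caliber_profile, s))
  if (noise) {
    set.seed(spec$rng_seed)
    img <- apply_noise(img, spec)
  }
  cl <- build_centerline(spec$centerline_xy, anchors_s = spec$anchors_s)
  s_truth <- seq(0, cl$length_um, by = 0.1)
  truth <- data.frame(
    s_um = s_truth,
    c_um = eval_caliber_profile(spec$caliber_profile, s_truth))
  structure(list(stack = calibrated_stack(img, spec$pixel_size_um),
                 truth = truth, centerline = cl, spec = spec),
            class = "axon_phantom")
}

#' @export
print.axon_phantom <- function(x, ...) {
  cat(sprintf("<axon_phantom> %.1f um axon, %d frame(s)\n",
              x$centerline$length_um, n_frames(x$stack)))
  invisible(x)
}
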