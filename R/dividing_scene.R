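#' Dividing-skin-cell scene specification
#'
#' A dual-channel scene: an axon crossing three basal skin cells — a central
#' cell that is rounded for mitosis and re-flattens, flanked by two
#' non-dividing neighbors. The central cell's border-to-border extent follows
#' a per-frame schedule from the rounded length to the flat length; the axon
#' caliber carries a configurable offset on the dividing cell and deflates as
#' the cell flattens.
#'
#' @param l_flat_um Planar (flat) length of the basal cell.
#' @param h_flat_um Flat-state height (>= 0).
#' @param l_round_um Chord length when rounded (< `l_flat_um`).
#' @param h_round_um Rounded-state height (> `h_flat_um`).
#' @param schedule_um Border-to-border length per frame; defaults to three
#'   rounded frames, a large flattening jump, then flat frames. Values must
#'   lie in `[l_round_um, l_flat_um]`.
#' @param neighbor_um Planar length of each neighbor cell.
#' @param cell_height_um Rendered (in-plane) cell depth in the image.
#' @param axon_baseline_um Resting axon caliber on the neighbor cells
#'   (default 0.22 um, so the dividing-cell caliber sits at 0.28 um when
#'   rounded and 0.25 um when flattened — thin skin-embedded axon territory
#'   that stays above the default optical resolution limit).
#' @param dividing_offset_um Caliber offset added while over the dividing
#'   cell (0 gives a null scene).
#' @param flat_deflation_um Caliber drop on the dividing cell at full
#'   flattening, ramped with the schedule progress.
#' @param border_transition_um Smoothing width of the caliber transition at
#'   the cell borders.
#' @param cell_photons_per_um Label density of the cell-border membrane.
#' @param psf_sigma_um,photons_per_um_membrane,background_level,read_noise_sd,pixel_size_um,rng_seed
#'   As in [phantom_spec()].
#' @return An object of class `dividing_scene_spec`.
#' @export
dividing_scene_spec <- function(l_flat_um = 12, h_flat_um = 1,
                                l_round_um = 8, h_round_um = 5,
                                schedule_um = NULL,
                                neighbor_um = 9,
                                cell_height_um = 6,
                                axon_baseline_um = 0.22,
                                dividing_offset_um = 0.06,
                                flat_deflation_um = 0.03,
                                border_transition_um = 0.3,
                                cell_photons_per_um = 300,
                                psf_sigma_um = 0.07,
                                photons_per_um_membrane = 200,
                                background_level = 10,
                                read_noise_sd = 2,
                                pixel_size_um = 0.04,
                                rng_seed = 1L) {
  stopifnot(l_round_um < l_flat_um, h_round_um > h_flat_um, h_flat_um >= 0,
            neighbor_um > 0, axon_baseline_um > 0)
  if (is.null(schedule_um)) {
    d <- l_flat_um - l_round_um
    schedule_um <- c(l_round_um, l_round_um, l_round_um + 0.15 * d,
                     l_round_um + 0.85 * d, l_flat_um, l_flat_um)
  }
  if (any(schedule_um < l_round_um - 1e-9 | schedule_um > l_flat_um + 1e-9)) {
    stop("schedule lengths must lie in [l_round_um, l_flat_um]")
  }
  structure(list(l_flat_um = l_flat_um, h_flat_um = h_flat_um,
                 l_round_um = l_round_um, h_round_um = h_round_um,
                 schedule_um = schedule_um, neighbor_um = neighbor_um,
                 cell_height_um = cell_height_um,
                 axon_baseline_um = axon_baseline_um,
                 dividing_offset_um = dividing_offset_um,
                 flat_deflation_um = flat_deflation_um,
                 border_transition_um = border_transition_um,
                 cell_photons_per_um = cell_photons_per_um,
                 psf_sigma_um = psf_sigma_um,
                 photons_per_um_membrane = photons_per_um_membrane,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 pixel_size_um = pixel_size_um,
                 rng_seed = as.integer(rng_seed)),
            class = "dividing_scene_spec")
}

# smooth 0..1 step over width w centred at 0
smoothstep <- function(x, w) {
  u <- pmin(pmax(x / w + 0.5, 0), 1)
  u * u * (3 - 2 * u)
}

#' Render a dividing-cell scene
#'
#' Channel `"axon"` shows the membrane-labeled axon; channel `"cell"` shows
#' the bright border polygons of the three cells. Ground truth is exported
#' per 1 um axon station per frame (region label and caliber) together with
#' the border-to-border length schedule.
#'
#' @param spec A `dividing_scene_spec`.
#' @param noise Apply the noise model (default `TRUE`).
#' @return List of class `dividing_scene`: `stack` (2-channel), `centerline`
#'   (axon), `truth_stations` (frame, s_um, x_um, region, c_um),
#'   `truth_lengths` (frame, border_to_border_um), `annotations`
#'   (per-frame cell polygons + axon path), `spec`.
#' @export
render_dividing_scene <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "dividing_scene_spec"))
  margin <- 2
  span <- 2 * spec$neighbor_um + spec$l_flat_um
  field_w <- span + 2 * margin
  field_h <- spec$cell_height_um + 2 * margin
  ya <- margin + spec$cell_height_um / 2   # axon row
  x0 <- margin                             # axon s = x - x0
  xc <- field_w / 2
  outer_l <- xc - spec$l_flat_um / 2 - spec$neighbor_um
  outer_r <- xc + spec$l_flat_um / 2 + spec$neighbor_um
  n_fr <- length(spec$schedule_um)
  d_range <- spec$l_flat_um - spec$l_round_um

  axon_xy <- rbind(c(x0, ya), c(field_w - margin, ya))
  axon_len <- field_w - 2 * margin
  if (!(outer_l >= x0 - 1e-9 && outer_r <= field_w - margin + 1e-9)) {
    stop("axon path does not cross all three cell regions")
  }

  caliber_xt <- function(x, t) {
    L <- spec$schedule_um[t]
    xl <- xc - L / 2; xr <- xc + L / 2
    inreg <- smoothstep(x - xl, spec$border_transition_um) *
      smoothstep(xr - x, spec$border_transition_um)
    prog <- (L - spec$l_round_um) / d_range
    pmax(spec$axon_baseline_um +
           (spec$dividing_offset_um - spec$flat_deflation_um * prog) * inreg,
         0.05)
  }

  prof <- caliber_profile_spec(spec$axon_baseline_um)
  ph_axon <- phantom_spec(axon_xy, prof,
                          psf_sigma_um = spec$psf_sigma_um,
                          photons_per_um_membrane = spec$photons_per_um_membrane,
                          background_level = spec$background_level,
                          read_noise_sd = spec$read_noise_sd,
                          pixel_size_um = spec$pixel_size_um,
                          field_um = c(field_w, field_h),
                          rng_seed = spec$rng_seed)

  cell_rect <- function(xl, xr) {
    yb <- margin; yt <- margin + spec$cell_height_um
    rbind(c(xl, yb), c(xr, yb), c(xr, yt), c(xl, yt))
  }
  deposit_polygon <- function(img, poly) {
    closed <- rbind(poly, poly[1, ])
    fs <- min(spec$pixel_size_um / 4, 0.01)
    for (i in seq_len(nrow(poly))) {
      a <- closed[i, ]; b <- closed[i + 1, ]
      len <- sqrt(sum((b - a)^2))
      n <- max(2L, ceiling(len / fs))
      tt <- seq(0, 1, length.out = n)
      pts <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
      img <- splat(img, pts, rep(spec$cell_photons_per_um * len / n, n),
                   spec$pixel_size_um)
    }
    img
  }

  set.seed(spec$rng_seed)
  nr <- round(field_h / spec$pixel_size_um) + 1L
  nc <- round(field_w / spec$pixel_size_um) + 1L
  px <- array(0, c(n_fr, nr, nc, 2L))
  centerlines <- list(); borders <- list()
  st_s <- seq(0, axon_len, by = 1)
  truth_st <- vector("list", n_fr)
  for (t in seq_len(n_fr)) {
    L <- spec$schedule_um[t]
    xl <- xc - L / 2; xr <- xc + L / 2
    ax_img <- render_frame(ph_axon, function(s) caliber_xt(s + x0, t))
    cell_img <- matrix(0, nr, nc)
    cell_img <- deposit_polygon(cell_img, cell_rect(outer_l, xl))
    cell_img <- deposit_polygon(cell_img, cell_rect(xl, xr))
    cell_img <- deposit_polygon(cell_img, cell_rect(xr, outer_r))
    cell_img <- blur_psf(cell_img, spec$psf_sigma_um / spec$pixel_size_um)
    if (noise) {
      ax_img <- apply_noise(ax_img, ph_axon)
      cell_img <- apply_noise(cell_img, ph_axon)
    }
    px[t, , , 1] <- ax_img
    px[t, , , 2] <- cell_img
    x_st <- st_s + x0
    region <- ifelse(x_st < xl - 1e-9, "neighbor1",
                     ifelse(x_st > xr + 1e-9, "neighbor2", "dividing"))
    region[x_st < outer_l - 1e-9 | x_st > outer_r + 1e-9] <- NA
    truth_st[[t]] <- data.frame(frame = t, s_um = st_s, x_um = x_st,
                                region = region,
                                c_um = caliber_xt(x_st, t))
    centerlines[[t]] <- list(label = "axon", frame = t, xy = axon_xy)
    borders <- c(borders,
                 list(list(label = "neighbor1", frame = t,
                           xy = cell_rect(outer_l, xl)),
                      list(label = "dividing", frame = t,
                           xy = cell_rect(xl, xr)),
                      list(label = "neighbor2", frame = t,
                           xy = cell_rect(xr, outer_r))))
  }
  stack <- calibrated_stack(px, spec$pixel_size_um, frame_interval_min = 5,
                            channel_roles = c(axon = 1L, cell = 2L))
  ann <- annotation_set(centerlines,
                        data.frame(frame = integer(0), x_um = numeric(0),
                                   y_um = numeric(0)),
                        borders, bounds_um = c(field_w, field_h))
  structure(list(stack = stack,
                 centerline = build_centerline(axon_xy),
                 truth_stations = do.call(rbind, truth_st),
                 truth_lengths = data.frame(
                   frame = seq_len(n_fr),
                   border_to_border_um = spec$schedule_um),
                 annotations = ann, spec = spec),
            class = "dividing_scene")
}

#' @export
print.dividing_scene <- function(x, ...) {
  cat(sprintf("<dividing_scene> %d frame(s), schedule %.1f -> %.1f um\n",
              nrow(x$truth_lengths), min(x$truth_lengths$border_to_border_um),
              max(x$truth_lengths$border_to_border_um)))
  invisible(x)
}
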