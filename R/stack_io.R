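#' Calibrated image stack
#'
#' In-memory container for a fluorescence image stack with physical
#' calibration. Pixels are stored as a 4-d array indexed
#' `(frame, row, col, channel)`; intensities are arbitrary-unit, finite and
#' nonnegative. Image coordinates are `(x, y)` in um with the origin at the
#' centre of pixel `(row 1, col 1)`: `x = (col - 1) * pixel_size_um`,
#' `y = (row - 1) * pixel_size_um`.
#'
#' @param pixels Numeric array: `(row, col)`, `(frame, row, col)` or
#'   `(frame, row, col, channel)`.
#' @param pixel_size_um Isotropic in-plane pixel size in um (> 0).
#' @param frame_interval_min Minutes per frame; 0 for a single frame.
#' @param channel_roles Named integer vector mapping role -> channel index;
#'   must contain `"axon"`.
#' @return An object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(pixels, pixel_size_um, frame_interval_min = 0,
                             channel_roles = c(axon = 1L)) {
  if (is.matrix(pixels)) {
    dim(pixels) <- c(1L, dim(pixels), 1L)
  } else if (length(dim(pixels)) == 3) {
    dim(pixels) <- c(dim(pixels), 1L)
  }
  stopifnot(length(dim(pixels)) == 4)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and >= 0")
  }
  if (!("axon" %in% names(channel_roles))) {
    stop("channel_roles must contain an 'axon' channel")
  }
  if (any(channel_roles < 1 | channel_roles > dim(pixels)[4])) {
    stop("channel_roles index outside the channel range")
  }
  structure(list(pixels = pixels,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 channel_roles = channel_roles),
            class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_stack> %d frame(s), %d x %d px, %d channel(s), %.4g um/px, %.3g min/frame\n",
    d[1], d[2], d[3], d[4], x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[1]

# frame image for a channel role, as a (row, col) matrix
frame_matrix <- function(stack, frame, role = "axon") {
  ch <- stack$channel_roles[[role]]
  if (is.null(ch)) stop("stack has no channel with role '", role, "'")
  stack$pixels[frame, , , ch]
}

# physical field extent in um: c(width_x, height_y)
field_extent_um <- function(stack) {
  d <- dim(stack$pixels)
  c((d[3] - 1) * stack$pixel_size_um, (d[2] - 1) * stack$pixel_size_um)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are written frame-major, channels consecutive within a frame, with
#' 32-bit samples (intensities are scaled by a recorded power of two into
#' the TIFF range, giving a relative quantization of 2^-32; a second
#' write/read round trip is bit-identical). Calibration and axis layout go
#' to a JSON sidecar (`<path>.json`); TIFF tags are never relied on for
#' units.
#'
#' @param stack A `calibrated_stack`.
#' @param path Destination `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$pixels)
  # TIFF pages hold [0, 1] at 32-bit depth; scale by a power of two (exact
  # in binary floating point) recorded in the sidecar. The TIFF writer
  # stores floor(v * (2^32 - 1)) while the reader returns k / 2^32, so we
  # pick the stored integer k = round(v / scale * 2^32) ourselves and write
  # the midpoint of its bin: round trips after the first write are then
  # bit-identical.
  mx <- max(stack$pixels)
  scale <- if (mx <= 0) 1 else 2^(floor(log2(mx)) + 1)
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (f in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      kk <- round(stack$pixels[f, , , ch] / scale * 2^32)
      pages[[k]] <- matrix(pmin((kk + 0.5) / (2^32 - 1), 1), d[2], d[3])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               n_frames = d[1], n_channels = d[4],
               intensity_scale = scale,
               channel_roles = as.list(stack$channel_roles))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' Calibration must be supplied explicitly: either a JSON sidecar written by
#' [write_stack()] sits next to the file, or `calibration` carries
#' `pixel_size_um` (plus optionally `frame_interval_min`, `n_channels`,
#' `channel_roles`). Pixel sizes are never guessed from TIFF tags; if both a
#' sidecar and `calibration` state a pixel size they must agree.
#'
#' @param path A single- or multi-page TIFF.
#' @param calibration Optional named list overriding/supplying calibration.
#' @return A `calibrated_stack`.
#' @export
read_stack <- function(path, calibration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) {
    stop("not a TIFF file: ", path)
  }
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::fromJSON(sidecar_path(path), simplifyVector = TRUE)
  }
  if (!is.null(calibration)) {
    if (!is.null(meta) && !is.null(calibration$pixel_size_um) &&
        !is.null(meta$pixel_size_um) &&
        abs(meta$pixel_size_um - calibration$pixel_size_um) > 1e-12) {
      stop(sprintf(
        "calibration mismatch: sidecar says %.6g um/px, config says %.6g um/px",
        meta$pixel_size_um, calibration$pixel_size_um))
    }
    meta <- utils::modifyList(if (is.null(meta)) list() else meta,
                              calibration)
  }
  if (is.null(meta) || is.null(meta$pixel_size_um)) {
    stop("missing calibration: supply a sidecar or a pixel_size_um ",
         "(pixel sizes are never guessed)")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # flatten any RGB pages
  })
  n_channels <- if (!is.null(meta$n_channels)) meta$n_channels else 1L
  n_fr <- length(pages) / n_channels
  if (n_fr != round(n_fr)) {
    stop("page count ", length(pages), " not divisible by ", n_channels,
         " channels")
  }
  n_fr <- as.integer(n_fr)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  d <- dim(pages[[1]])
  px <- array(0, c(n_fr, d[1], d[2], n_channels))
  k <- 1L
  for (f in seq_len(n_fr)) {
    for (ch in seq_len(n_channels)) {
      px[f, , , ch] <- pages[[k]] * scale
      k <- k + 1L
    }
  }
  roles <- if (!is.null(meta$channel_roles)) {
    unlist(meta$channel_roles)
  } else {
    c(axon = 1L)
  }
  calibrated_stack(px, meta$pixel_size_um,
                   frame_interval_min =
                     if (is.null(meta$frame_interval_min)) 0
                     else meta$frame_interval_min,
                   channel_roles = roles)
}
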