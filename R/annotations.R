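#' Annotation set: centerlines, branch points, cell borders
#'
#' Holds axon centerline polylines, branch-point coordinates and optional
#' cell-border polygons, all in um image coordinates. Labels must be unique
#' per frame within each category; polylines need at least 2 vertices.
#'
#' @param centerlines List of entries `list(label, frame, xy)` where `xy` is
#'   an n x 2 um coordinate matrix (n >= 2).
#' @param branch_points Data frame with columns `frame`, `x_um`, `y_um` and
#'   optionally `label` (may have zero rows).
#' @param cell_borders Optional list of entries `list(label, frame, xy)`
#'   with `xy` a closed-or-open polygon (n >= 3); labels such as
#'   `"dividing"`, `"neighbor1"`, `"neighbor2"`.
#' @param bounds_um Optional `c(width, height)` field extent; when given,
#'   every coordinate is checked against it.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(centerlines = list(),
                           branch_points = data.frame(frame = integer(0),
                                                      x_um = numeric(0),
                                                      y_um = numeric(0)),
                           cell_borders = list(),
                           bounds_um = NULL) {
  check_poly <- function(e, min_n, what) {
    if (is.null(e$label) || is.null(e$frame) || is.null(e$xy)) {
      stop(what, " entries need fields label, frame, xy")
    }
    e$xy <- as.matrix(e$xy)
    if (nrow(e$xy) < min_n) {
      stop(sprintf("%s '%s' (frame %d) has %d vertices; need >= %d",
                   what, e$label, e$frame, nrow(e$xy), min_n))
    }
    if (!all(is.finite(e$xy))) stop(what, " '", e$label, "' has non-finite coordinates")
    if (!is.null(bounds_um)) {
      bad <- which(e$xy[, 1] < 0 | e$xy[, 1] > bounds_um[1] |
                   e$xy[, 2] < 0 | e$xy[, 2] > bounds_um[2])
      if (length(bad) > 0) {
        stop(sprintf("%s '%s' (frame %d): vertex %d at (%.3f, %.3f) outside field",
                     what, e$label, e$frame, bad[1],
                     e$xy[bad[1], 1], e$xy[bad[1], 2]))
      }
    }
    e
  }
  centerlines <- lapply(centerlines, check_poly, min_n = 2, what = "centerline")
  cell_borders <- lapply(cell_borders, check_poly, min_n = 3, what = "cell border")
  for (group in list(centerlines, cell_borders)) {
    if (length(group) > 0) {
      key <- vapply(group, function(e) paste(e$frame, e$label), character(1))
      if (anyDuplicated(key)) {
        stop("duplicate label within a frame: ", key[duplicated(key)][1])
      }
    }
  }
  stopifnot(is.data.frame(branch_points),
            all(c("frame", "x_um", "y_um") %in% names(branch_points)))
  structure(list(centerlines = centerlines, branch_points = branch_points,
                 cell_borders = cell_borders, bounds_um = bounds_um),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d centerline(s), %d branch point(s), %d cell border(s)\n",
              length(x$centerlines), nrow(x$branch_points),
              length(x$cell_borders)))
  invisible(x)
}

poly_to_df <- function(entries, kind) {
  if (length(entries) == 0) {
    return(data.frame(kind = character(0), label = character(0),
                      frame = integer(0), vertex = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  }
  do.call(rbind, lapply(entries, function(e) {
    data.frame(kind = kind, label = e$label, frame = e$frame,
               vertex = seq_len(nrow(e$xy)),
               x_um = e$xy[, 1], y_um = e$xy[, 2])
  }))
}

df_to_poly <- function(df) {
  if (nrow(df) == 0) return(list())
  sp <- split(df, paste(df$frame, df$label, sep = "\r"))
  unname(lapply(sp, function(g) {
    g <- g[order(g$vertex), ]
    list(label = g$label[1], frame = g$frame[1],
         xy = cbind(g$x_um, g$y_um))
  }))
}

#' Write annotations to JSON or flat CSV
#'
#' JSON is the primary format (full structure); CSV is a flat long table
#' with columns `kind, label, frame, vertex, x_um, y_um` (`kind` one of
#' `centerline`, `branch_point`, `cell_border`). Coordinates are always um
#' (`units: "um"` recorded in JSON).
#'
#' @param ann An `annotation_set`.
#' @param path Destination `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(
      units = "um",
      centerlines = lapply(ann$centerlines, function(e) {
        list(label = e$label, frame = e$frame,
             x_um = e$xy[, 1], y_um = e$xy[, 2])
      }),
      branch_points = ann$branch_points,
      cell_borders = lapply(ann$cell_borders, function(e) {
        list(label = e$label, frame = e$frame,
             x_um = e$xy[, 1], y_um = e$xy[, 2])
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    bp <- ann$branch_points
    bp_df <- data.frame(kind = rep("branch_point", nrow(bp)),
                        label = if (!is.null(bp$label)) bp$label
                                else rep("", nrow(bp)),
                        frame = bp$frame, vertex = seq_len(nrow(bp)),
                        x_um = bp$x_um, y_um = bp$y_um)
    df <- rbind(poly_to_df(ann$centerlines, "centerline"), bp_df,
                poly_to_df(ann$cell_borders, "cell_border"))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported annotation format: '.", ext, "'")
  }
  invisible(path)
}

#' Read annotations from JSON or CSV
#'
#' @param path A `.json` or `.csv` file written by [write_annotations()] (or
#'   following the same schema). Coordinates given in pixels must be flagged
#'   with `units: "px"` and a `pixel_size_um` field (JSON only); they are
#'   converted to um on read.
#' @param bounds_um Optional field extent for validation.
#' @return An `annotation_set`.
#' @export
read_annotations <- function(path, bounds_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
    fac <- 1
    if (!is.null(obj$units) && obj$units == "px") {
      if (is.null(obj$pixel_size_um)) {
        stop("annotations in pixel units need a pixel_size_um field")
      }
      fac <- obj$pixel_size_um
    }
    grab <- function(lst) {
      if (is.null(lst) || length(lst) == 0) return(list())
      if (is.data.frame(lst)) {
        lst <- lapply(seq_len(nrow(lst)), function(i) as.list(lst[i, ]))
      }
      lapply(lst, function(e) {
        list(label = e$label, frame = e$frame,
             xy = cbind(unlist(e$x_um), unlist(e$y_um)) * fac)
      })
    }
    bp <- obj$branch_points
    if (is.null(bp) || length(bp) == 0) {
      bp <- data.frame(frame = integer(0), x_um = numeric(0),
                       y_um = numeric(0))
    } else {
      bp <- as.data.frame(bp)
      bp$x_um <- bp$x_um * fac
      bp$y_um <- bp$y_um * fac
    }
    annotation_set(grab(obj$centerlines), bp, grab(obj$cell_borders),
                   bounds_um = bounds_um)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("kind", "label", "frame", "vertex", "x_um", "y_um")
    if (!all(need %in% names(df))) {
      stop("annotation CSV needs columns: ", paste(need, collapse = ", "))
    }
    bp <- df[df$kind == "branch_point", ]
    bp_df <- data.frame(frame = bp$frame, x_um = bp$x_um, y_um = bp$y_um)
    if (any(nzchar(bp$label))) bp_df$label <- bp$label
    annotation_set(df_to_poly(df[df$kind == "centerline", ]), bp_df,
                   df_to_poly(df[df$kind == "cell_border", ]),
                   bounds_um = bounds_um)
  } else {
    stop("unsupported annotation format: '.", ext, "'")
  }
}

#' Write a measurement table as CSV
#'
#' Deterministic output: stable column order as given, `.` decimal
#' separator, UTF-8, 15 significant digits (round-trips doubles to 1e-9 or
#' better at these magnitudes).
#'
#' @param records A data frame of measurements (may have zero rows).
#' @param path Destination `.csv` path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  fmt <- records
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), "", sprintf("%.15g", fmt[[j]]))
    }
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measurement table written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
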