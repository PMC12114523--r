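#' Analysis run configuration
#'
#' Collects every tunable parameter of the measurement pipeline in one
#' validated object. All lengths are in micrometres, times in minutes.
#'
#' @param resolution_limit_um Smallest caliber trusted by the optical system.
#'   Measurements below this (or with unresolvable membrane peaks) are
#'   flagged `below_limit` and excluded from summaries.
#' @param scan_half_length_um Half-length of the perpendicular line scan.
#' @param scan_width_um Width of the scan line: parallel pixel-spaced lines
#'   within this width (along the local axon axis) are averaged, like a
#'   wide line-profile tool; 0 uses a single line.
#' @param scan_sample_spacing_um Sample spacing along the scan; `NULL` means
#'   half the pixel size of the stack being measured.
#' @param branch_offsets_um Distances from a branch point at which segment
#'   caliber is measured and averaged.
#' @param lengthwise_interval_um Station interval for lengthwise profiling.
#' @param branch_exclusion_um Stations closer than this to a branch point are
#'   omitted from lengthwise profiling (strictly-less-than rule; a station at
#'   exactly the exclusion distance is kept).
#' @param below_limit_series_fraction A time series with a below-limit
#'   fraction strictly greater than this is excluded from comparisons.
#' @param min_prominence_frac Minimum peak prominence, as a fraction of the
#'   profile's intensity range, for a membrane peak to qualify.
#' @param offset_mode How branch offsets are walked: `"along_path"`
#'   (geodesic, default) or `"straight_line"`.
#' @param rng_seed Seed for stochastic steps (bootstrap, Monte Carlo).
#' @param bootstrap_reps Bootstrap resamples for confidence intervals.
#' @param permutation_reps Monte Carlo resamples when exact enumeration of
#'   sign flips is infeasible.
#'
#' @return An object of class `run_config` (a validated named list).
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$branch_offsets_um
run_config <- function(resolution_limit_um = 0.14,
                       scan_half_length_um = 1.5,
                       scan_width_um = 0.2,
                       scan_sample_spacing_um = NULL,
                       branch_offsets_um = c(3, 4, 5),
                       lengthwise_interval_um = 1,
                       branch_exclusion_um = 3,
                       below_limit_series_fraction = 0.20,
                       min_prominence_frac = 0.15,
                       offset_mode = c("along_path", "straight_line"),
                       rng_seed = 1L,
                       bootstrap_reps = 5000L,
                       permutation_reps = 10000L) {
  offset_mode <- match.arg(offset_mode)
  stopifnot(
    is.numeric(resolution_limit_um), resolution_limit_um > 0,
    scan_half_length_um > 0, scan_width_um >= 0,
    is.null(scan_sample_spacing_um) || scan_sample_spacing_um > 0,
    all(branch_offsets_um > 0),
    lengthwise_interval_um > 0,
    branch_exclusion_um >= 0,
    below_limit_series_fraction >= 0, below_limit_series_fraction <= 1,
    min_prominence_frac >= 0, min_prominence_frac <= 1,
    bootstrap_reps >= 1, permutation_reps >= 1
  )
  structure(list(
    resolution_limit_um = resolution_limit_um,
    scan_half_length_um = scan_half_length_um,
    scan_width_um = scan_width_um,
    scan_sample_spacing_um = scan_sample_spacing_um,
    branch_offsets_um = branch_offsets_um,
    lengthwise_interval_um = lengthwise_interval_um,
    branch_exclusion_um = branch_exclusion_um,
    below_limit_series_fraction = below_limit_series_fraction,
    min_prominence_frac = min_prominence_frac,
    offset_mode = offset_mode,
    rng_seed = as.integer(rng_seed),
    bootstrap_reps = as.integer(bootstrap_reps),
    permutation_reps = as.integer(permutation_reps)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected so that typos never silently fall back to
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   arguments of [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: '.", ext, "' (use YAML or JSON)")
  )
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Write a run configuration
#'
#' @param config A `run_config` object.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: '.", ext, "'")
  )
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(v)) "auto" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# Effective scan spacing for a given stack (default: half the pixel).
scan_spacing <- function(config, stack) {
  if (!is.null(config$scan_sample_spacing_um)) {
    return(config$scan_sample_spacing_um)
  }
  stack$pixel_size_um / 2
}
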