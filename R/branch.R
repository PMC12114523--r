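#' Mean segment caliber from branch-offset measurements
#'
#' The caliber of a segment is the arithmetic mean of the non-flagged
#' measurements taken at the configured offsets from the branch point
#' (default 3, 4 and 5 um). Individual flagged offsets are dropped rather
#' than discarding the whole segment; if every offset is flagged the segment
#' is unmeasurable and `NA` is returned (propagating to triplet exclusion).
#'
#' @param measurements Data frame of `measure_at()` rows.
#' @return Mean caliber in um, or `NA_real_` if all offsets are flagged.
#' @export
segment_mean_caliber <- function(measurements) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1)
  v <- measurements$caliber_um[!measurements$below_limit &
                               is.finite(measurements$caliber_um)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Assign a P/S1/S2 branch triplet and derive its metrics
#'
#' S1 is the thicker and S2 the thinner secondary branch. Derived fields:
#' normalized calibers `norm_s1 = s1/p`, `norm_s2 = s2/p`; `symmetry =
#' s2/s1` (equal to `norm_s2/norm_s1`); cross-sectional areas
#' `pi * (c/2)^2`; `taper_area_ratio = (area_s1 + area_s2) / area_p`
#' (equal to `(s1^2 + s2^2) / p^2`); radius scaling ratios `s1/p`, `s2/p`.
#'
#' @param primary_um Primary caliber (um, > 0, not below-limit — triplets
#'   whose primary is unresolvable are excluded upstream).
#' @param secondary_a_um,secondary_b_um Secondary calibers in annotation
#'   order; exact ties keep annotation order for the S1 label and set
#'   `tie_flag`.
#' @return An object of class `branch_triplet`.
#' @export
#' @examples
#' tr <- assign_triplet(0.4, 0.2, 0.3)
#' tr$symmetry       # 0.6667
#' tr$taper_area_ratio
assign_triplet <- function(primary_um, secondary_a_um, secondary_b_um) {
  vals <- c(primary_um, secondary_a_um, secondary_b_um)
  if (any(!is.finite(vals))) stop("unmeasurable segment in triplet")
  if (any(vals <= 0)) stop("calibers must be > 0")
  tie <- secondary_a_um == secondary_b_um
  if (secondary_a_um >= secondary_b_um) {
    s1 <- secondary_a_um; s2 <- secondary_b_um
  } else {
    s1 <- secondary_b_um; s2 <- secondary_a_um
  }
  area <- function(c_um) pi * (c_um / 2)^2
  structure(list(
    p_um = primary_um, s1_um = s1, s2_um = s2,
    norm_s1 = s1 / primary_um, norm_s2 = s2 / primary_um,
    symmetry = s2 / s1,
    area_p = area(primary_um), area_s1 = area(s1), area_s2 = area(s2),
    taper_area_ratio = (area(s1) + area(s2)) / area(primary_um),
    r_ratio_s1 = s1 / primary_um, r_ratio_s2 = s2 / primary_um,
    tie_flag = tie), class = "branch_triplet")
}

#' @export
print.branch_triplet <- function(x, ...) {
  cat(sprintf("<branch_triplet> P %.3f, S1 %.3f, S2 %.3f um | symmetry %.3f, area ratio %.3f\n",
              x$p_um, x$s1_um, x$s2_um, x$symmetry, x$taper_area_ratio))
  invisible(x)
}

#' Convert branch triplets to a table
#'
#' @param triplets List of `branch_triplet` objects.
#' @return Data frame, one row per branch point.
#' @export
triplets_to_df <- function(triplets) {
  do.call(rbind, lapply(triplets, function(tr) {
    as.data.frame(unclass(tr))
  }))
}

#' Cohort summaries of branch triplets
#'
#' Means and SEMs (sample sd / sqrt(n)) of the tapering area ratio and the
#' radius scaling ratios; the pooled S/P sample puts both secondaries of
#' every triplet into one sample. Regression inputs (S1 vs S2, symmetry vs
#' normalized calibers) are forwarded for [linregress_r2()].
#'
#' @param triplets List of `branch_triplet` objects (>= 2).
#' @return List: `summary` data frame (metric, mean, sem, n), `pooled_sp`
#'   numeric vector, `regressions` named list of x/y data frames.
#' @export
cohort_summaries <- function(triplets) {
  stopifnot(length(triplets) >= 2)
  df <- triplets_to_df(triplets)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  pooled <- c(df$r_ratio_s1, df$r_ratio_s2)
  metrics <- list(
    mean_p_um = df$p_um, mean_s1_um = df$s1_um, mean_s2_um = df$s2_um,
    taper_area_ratio = df$taper_area_ratio,
    r_ratio_s1 = df$r_ratio_s1, r_ratio_s2 = df$r_ratio_s2,
    symmetry = df$symmetry, pooled_s_over_p = pooled)
  summary <- data.frame(
    metric = names(metrics),
    mean = vapply(metrics, mean, numeric(1)),
    sem = vapply(metrics, sem, numeric(1)),
    n = vapply(metrics, length, integer(1)),
    row.names = NULL)
  list(summary = summary,
       pooled_sp = pooled,
       triplet_table = df,
       regressions = list(
         s1_vs_s2 = data.frame(x = df$s1_um, y = df$s2_um),
         symmetry_vs_norm_s1 = data.frame(x = df$norm_s1, y = df$symmetry),
         symmetry_vs_norm_s2 = data.frame(x = df$norm_s2, y = df$symmetry)))
}

#' Measure a branch triplet from annotated segment centerlines
#'
#' Each segment centerline must be anchored at the branch point (anchor at
#' its start); caliber is measured at the configured offsets (3/4/5 um by
#' default) along each segment and averaged.
#'
#' @param stack A `calibrated_stack`.
#' @param cl_p,cl_a,cl_b Anchored `centerline`s for the primary and the two
#'   secondary segments.
#' @param frame Frame index.
#' @param config A [run_config()].
#' @return A `branch_triplet`, or `NULL` when the primary (or both offsets
#'   of a secondary) is below the resolution limit.
#' @export
measure_branch_triplet <- function(stack, cl_p, cl_a, cl_b, frame = 1,
                                   config = run_config()) {
  seg_mean <- function(cl) {
    rows <- lapply(config$branch_offsets_um, function(d) {
      p <- point_at_distance(cl, d, mode = config$offset_mode)
      measure_at(stack, cl, frame, p$s_um, config)
    })
    segment_mean_caliber(do.call(rbind, rows))
  }
  p <- seg_mean(cl_p); a <- seg_mean(cl_a); b <- seg_mean(cl_b)
  if (!is.finite(p) || !is.finite(a) || !is.finite(b)) return(NULL)
  assign_triplet(p, a, b)
}
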