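#' Run the full phantom-to-statistics pipeline
#'
#' One-command end-to-end run on seeded synthetic scenes with known ground
#' truth: (1) branch scenes — straight P/S1/S2 segments with known calibers,
#' measured at the branch offsets and reduced to triplet metrics and cohort
#' summaries; (2) a caliber-dynamics time lapse with known per-frame
#' baselines, reduced to dynamicity summaries; (3) a dividing-cell scene,
#' reduced to region comparisons, border-to-border lengths, round/flat
#' pairing and the arc path model; (4) the statistical table over the
#' comparisons. All result tables are written as CSV under `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stochastic stage derives from it.
#' @param config A [run_config()].
#' @param n_triplets Number of branch scenes (default 5).
#' @param n_dyn_frames Frames in the dynamics time lapse (default 10).
#' @param verbose Log per-stage timing to stderr (default TRUE).
#' @return List with `branch` (truth, triplets, cohort), `dynamics`
#'   (truth and measured summaries), `divide` (region samples, tests,
#'   round/flat pairing, arc model), `stats` (the combined table), and
#'   `files` (paths written).
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = run_config(),
                         n_triplets = 5L, n_dyn_frames = 10L,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[caliberkit] ", fmt), ...))
  }
  t_all <- proc.time()["elapsed"]
  set.seed(seed)

  ## --- branch scenes -------------------------------------------------------
  t0 <- proc.time()["elapsed"]
  seg_len <- max(config$branch_offsets_um) + 2
  truth_tr <- data.frame(
    p_um = stats::runif(n_triplets, 0.38, 0.50),
    s1_um = stats::runif(n_triplets, 0.28, 0.38),
    s2_um = stats::runif(n_triplets, 0.18, 0.26))
  triplets <- list()
  kept <- integer(0)
  for (i in seq_len(n_triplets)) {
    mk <- function(c_um, sd) {
      sp <- phantom_spec(rbind(c(0, 0), c(seg_len, 0)),
                         caliber_profile_spec(c_um),
                         anchors_s = 0, rng_seed = sd)
      ph <- render_axon_image(sp)
      list(stack = ph$stack, cl = ph$centerline)
    }
    p <- mk(truth_tr$p_um[i], seed + 100 + i)
    a <- mk(truth_tr$s1_um[i], seed + 200 + i)
    b <- mk(truth_tr$s2_um[i], seed + 300 + i)
    seg_mean <- function(seg) {
      rows <- lapply(config$branch_offsets_um, function(d) {
        pt <- point_at_distance(seg$cl, d, mode = config$offset_mode)
        measure_at(seg$stack, seg$cl, 1, pt$s_um, config)
      })
      segment_mean_caliber(do.call(rbind, rows))
    }
    pm <- seg_mean(p); am <- seg_mean(a); bm <- seg_mean(b)
    if (anyNA(c(pm, am, bm))) {
      # a segment below the resolution limit at every offset excludes the
      # whole branch point, mirroring the exclusion rules of the protocol
      say("branch: triplet %d excluded (unmeasurable segment)", i)
      next
    }
    triplets <- c(triplets, list(assign_triplet(pm, am, bm)))
    kept <- c(kept, i)
  }
  if (length(kept) < 2) stop("fewer than 2 measurable branch triplets")
  cohort <- cohort_summaries(triplets)
  truth_cohort <- cohort_summaries(lapply(kept, function(i) {
    assign_triplet(truth_tr$p_um[i], truth_tr$s1_um[i], truth_tr$s2_um[i])
  }))
  say("branch: %d/%d triplets measured in %.1f s", length(kept), n_triplets,
      proc.time()["elapsed"] - t0)

  ## --- dynamics time lapse -------------------------------------------------
  t0 <- proc.time()["elapsed"]
  base_mean <- 0.40
  target_rsd <- 25
  baselines <- base_mean *
    (1 + target_rsd / 100 * sin(2 * pi * seq_len(n_dyn_frames) / 6.5))
  dyn_spec <- phantom_spec(rbind(c(0, 0), c(12, 0)),
                           caliber_profile_spec(base_mean),
                           anchors_s = 0, rng_seed = seed + 400)
  dyn <- render_caliber_sequence(dyn_spec, baselines)
  station_s <- 3  # measured 3 um from the branch-point anchor each frame
  dser <- measure_timeseries(dyn$stack, dyn$centerline, station_s, config)
  dsum <- dynamicity(dser, config)
  truth_dyn <- list(mean_um = mean(baselines), sd_um = stats::sd(baselines),
                    rsd_percent = 100 * stats::sd(baselines) / mean(baselines))
  say("dynamics: %d frames in %.1f s", n_dyn_frames,
      proc.time()["elapsed"] - t0)

  ## --- dividing-cell scene -------------------------------------------------
  t0 <- proc.time()["elapsed"]
  dspec <- dividing_scene_spec(rng_seed = seed + 500)
  scene <- render_dividing_scene(dspec)
  n_fr <- nrow(scene$truth_lengths)
  st <- scene$truth_stations
  meas <- do.call(rbind, lapply(seq_len(n_fr), function(f) {
    sf <- st[st$frame == f & !is.na(st$region), ]
    rows <- lapply(sf$s_um, function(s) {
      measure_at(scene$stack, scene$centerline, f, s, config)
    })
    out <- do.call(rbind, rows)
    out$region <- sf$region
    out
  }))
  lengths <- vapply(seq_len(n_fr), function(f) {
    border_to_border(scene$annotations, f)
  }, numeric(1))
  rf <- select_round_flat(lengths)
  groups <- group_by_region(meas[meas$frame == rf$round_frame, ])
  mw <- list(
    dividing_vs_neighbor1 = mann_whitney_u(groups$dividing,
                                           groups$neighbor1),
    dividing_vs_neighbor2 = mann_whitney_u(groups$dividing,
                                           groups$neighbor2),
    neighbor1_vs_neighbor2 = mann_whitney_u(groups$neighbor1,
                                            groups$neighbor2))
  pairing <- round_flat_pairing(meas, rf$round_frame, rf$flat_frame)
  perm_round_flat <- paired_permutation_test(pairing$pairs$delta_um,
                                             reps = config$permutation_reps,
                                             seed = config$rng_seed)
  ci_round_flat <- paired_mean_difference_ci(pairing$pairs$delta_um,
                                             reps = config$bootstrap_reps,
                                             seed = config$rng_seed)
  arc <- arc_path_ratio(dspec$l_round_um,
                        dspec$h_round_um - dspec$h_flat_um,
                        dspec$l_flat_um)
  say("divide: %d frames in %.1f s", n_fr, proc.time()["elapsed"] - t0)

  ## --- statistics table ----------------------------------------------------
  stats_tab <- stats_table(c(mw, list(
    round_vs_flat_perm = perm_round_flat,
    round_vs_flat_ci = ci_round_flat)))

  files <- c(
    branch_triplets = file.path(out_dir, "branch_triplets.csv"),
    branch_summary = file.path(out_dir, "branch_summary.csv"),
    dynamics_series = file.path(out_dir, "dynamics_series.csv"),
    dividing_stations = file.path(out_dir, "dividing_stations.csv"),
    border_lengths = file.path(out_dir, "border_lengths.csv"),
    stats = file.path(out_dir, "stats_table.csv"))
  write_results(cohort$triplet_table, files[["branch_triplets"]])
  write_results(cohort$summary, files[["branch_summary"]])
  write_results(dser$measurements, files[["dynamics_series"]])
  write_results(meas, files[["dividing_stations"]])
  write_results(data.frame(frame = seq_len(n_fr),
                           border_to_border_um = lengths),
                files[["border_lengths"]])
  write_results(stats_tab, files[["stats"]])
  say("pipeline done in %.1f s", proc.time()["elapsed"] - t_all)

  list(branch = list(truth = truth_cohort, measured = cohort,
                     truth_calibers = truth_tr, kept_triplets = kept),
       dynamics = list(truth = truth_dyn, summary = dsum, series = dser),
       divide = list(measurements = meas, groups = groups, tests = mw,
                     lengths = lengths, truth_lengths = scene$truth_lengths,
                     round_flat = rf, pairing = pairing,
                     perm = perm_round_flat, ci = ci_round_flat,
                     arc = arc, scene_spec = dspec),
       stats = stats_tab, files = files)
}
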