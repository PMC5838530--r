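# derive a reproducible sub-seed (kept below 2^31) from a base seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483629 + 1)
}

#' Configuration of a full synthetic study replay
#'
#' Bundles every knob of the end-to-end replay: cohort generation, per-visit
#' localizer + ROI selection, neurofeedback runs through the real-time
#' engine, offline contrasts, visit-trend and PPI models, behaviour
#' regression, and composite scoring. The defaults are deliberately
#' desk-scale (small grid, 5 participants) so a replay completes in seconds;
#' block timing, thresholds and the feedback rule itself are at study scale.
#'
#' @param n_participants Cohort size (default 5).
#' @param visits Training visits per participant (3 or 4).
#' @param runs Neurofeedback runs per visit (3 or 4).
#' @param grid [acquisition_grid()] for all simulated runs.
#' @param roi_half_extent Half-extent of the planted active box ROI.
#' @param base_amplitude,learning_slope,ar_coefficient,noise_sd Ground-truth
#'   parameters of the planted upregulation signal (PSC %, PSC %/visit,
#'   unitless, signal units).
#' @param localizer_amplitude Planted amplitude (PSC %) of the localizer
#'   activation.
#' @param localizer_cycles,localizer_block_s Localizer design shape.
#' @param engine [engine_config()].
#' @param hrf [hrf_params()].
#' @param t_threshold,spike_mm,run_exclusion_mm,voxel_p Analysis thresholds.
#' @param stages Character subset of c("trend", "ppi", "behavior",
#'   "composite") to run after the feedback stage.
#' @param seed Global seed, expanded into per-stage sub-seeds.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 5, visits = 3, runs = 3,
                         grid = acquisition_grid(c(8, 8, 6)),
                         roi_half_extent = c(1, 1, 1),
                         base_amplitude = 0.6, learning_slope = 0.5,
                         ar_coefficient = 0.3, noise_sd = 1,
                         localizer_amplitude = 2,
                         localizer_cycles = 4, localizer_block_s = 15,
                         engine = engine_config(), hrf = hrf_params(),
                         t_threshold = 3, spike_mm = 1,
                         run_exclusion_mm = 2, voxel_p = 0.001,
                         stages = c("trend", "ppi", "behavior", "composite"),
                         seed = 1) {
  if (!visits %in% 3:4) stop("`visits` must be 3 or 4")
  if (!runs %in% 3:4) stop("`runs` must be 3 or 4")
  stopifnot(inherits(grid, "acquisition_grid"),
            inherits(engine, "engine_config"),
            inherits(hrf, "hrf_params"),
            all(stages %in% c("trend", "ppi", "behavior", "composite")))
  structure(as.list(environment()), class = "study_config")
}

#' Replay a full neurofeedback study on synthetic data
#'
#' Simulates a cohort, then for every participant and visit: a functional
#' localizer run, GLM-based target-ROI selection (t > threshold), the
#' neurofeedback runs through the closed-loop engine, and offline
#' upregulation-versus-baseline contrasts on the group (union) mask with
#' motion and spike nuisance regressors. Downstream stages fit the
#' visit-trend mixed model, the PPI connectivity-change model, the voxelwise
#' behaviour regression on activation change, and composite-score change.
#' Deterministic for a fixed (config, seed) pair.
#'
#' @param cfg A [study_config()].
#' @return An object of class `study_report`: list with `config`, `cohort`,
#'   `roi` (per-visit ROI sizes + group mask), `feedback` (per-block
#'   summaries), `estimates` (subject/visit/run ROI contrasts), and one
#'   element per requested stage (`trend`, `ppi`, `behavior`, `composite`).
#' @export
replay_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- simulate_cohort(cohort_spec(
    n_participants = cfg$n_participants, seed = derive_seed(cfg$seed, 1)))
  truth_mask <- central_roi(cfg$grid, cfg$roi_half_extent)
  loc_design <- alternating_design("clench", n_cycles = cfg$localizer_cycles,
                                   block_s = cfg$localizer_block_s,
                                   tr = cfg$grid$tr)
  nf_design <- nf_block_design(tr = cfg$grid$tr)

  masks <- list()
  roi_sizes <- NULL
  feedback_blocks <- NULL
  records <- list()   # one entry per retained run: run + subject/visit/run
  ctr <- 0L

  for (s in seq_len(cfg$n_participants)) {
    subj_truth <- simulation_truth(
      truth_mask, base_amplitude = cfg$base_amplitude,
      learning_slope = cfg$learning_slope,
      ar_coefficient = cfg$ar_coefficient, noise_sd = cfg$noise_sd)
    loc_truth <- simulation_truth(
      truth_mask, base_amplitude = cfg$localizer_amplitude,
      learning_slope = 0, ar_coefficient = cfg$ar_coefficient,
      noise_sd = cfg$noise_sd)
    for (v in seq_len(cfg$visits)) {
      ctr <- ctr + 1L
      loc_run <- simulate_run(loc_truth, loc_design, cfg$grid, cfg$hrf,
                              visit = v, signal_kind = "clench",
                              seed = derive_seed(cfg$seed, 100 + ctr))
      loc <- localize_roi(loc_run, "clench", cfg$hrf, cfg$t_threshold)
      visit_mask <- if (any(loc$mask)) loc$mask else truth_mask
      masks[[length(masks) + 1L]] <- visit_mask
      roi_sizes <- rbind(roi_sizes, data.frame(
        subject = s, visit = v, n_voxels = sum(visit_mask)))
      for (r in seq_len(cfg$runs)) {
        ctr <- ctr + 1L
        run <- simulate_run(subj_truth, nf_design, cfg$grid, cfg$hrf,
                            visit = v,
                            seed = derive_seed(cfg$seed, 100 + ctr))
        if (exclude_run(run$motion, cfg$run_exclusion_mm)) next
        fb <- run_feedback(run, visit_mask, cfg$engine, cfg$hrf)
        feedback_blocks <- rbind(feedback_blocks, cbind(
          data.frame(subject = s, visit = v, run = r), fb$blocks))
        records[[length(records) + 1L]] <-
          list(run = run, subject = s, visit = v, run_no = r)
      }
    }
  }

  group_mask <- union_mask(masks, group_threshold = 1)
  estimates <- NULL
  maps <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    spikes <- spike_regressors(rec$run$motion, cfg$spike_mm)
    bc <- block_contrast(rec$run, group_mask, cfg$hrf,
                         nuisance = cbind(rec$run$motion, spikes$columns))
    maps[[i]] <- bc$map
    estimates <- rbind(estimates, data.frame(
      subject = rec$subject, visit = rec$visit, run = rec$run_no,
      roi_contrast = bc$roi,
      age = cohort$age[rec$subject],
      caudate_pct_icv = cohort$caudate_pct_icv[rec$subject]))
  }

  report <- list(config = cfg, cohort = cohort,
                 roi = list(sizes = roi_sizes, group_mask = group_mask),
                 feedback = feedback_blocks, estimates = estimates)

  if ("trend" %in% cfg$stages)
    report$trend <- visit_trend(estimates)

  if ("ppi" %in% cfg$stages) {
    mean_map <- Reduce(`+`, maps) / length(maps)
    mean_map[!group_mask] <- -Inf
    peak <- as.integer(arrayInd(which.max(mean_map), cfg$grid$dim))
    seed_mask <- sphere_seed(peak, 6, group_mask, cfg$grid$vox_mm)
    cond <- design_boxcar(nf_design, "upregulate")
    betas <- NULL
    for (rec in records) {
      bold_mat <- matrix(rec$run$bold, ncol = rec$run$design$n_volumes)
      seed_ts <- colMeans(bold_mat[as.vector(seed_mask), , drop = FALSE])
      targ_ts <- colMeans(bold_mat[as.vector(group_mask), , drop = FALSE])
      pp <- ppi_terms(seed_ts, cond, cfg$hrf, rec$run$tr)
      betas <- rbind(betas, data.frame(
        subject = rec$subject, visit = rec$visit, run = rec$run_no,
        beta = fit_ppi(targ_ts, pp)$beta,
        age = cohort$age[rec$subject],
        caudate_pct_icv = cohort$caudate_pct_icv[rec$subject]))
    }
    report$ppi <- list(seed_mask = seed_mask, betas = betas,
                       trend = connectivity_change(betas))
  }

  if (any(c("composite", "behavior") %in% cfg$stages)) {
    norms <- example_norms()
    base_comp <- vapply(seq_len(cfg$n_participants), function(s)
      composite_score(cohort[s, ], norms), numeric(1))
    # realized activation gain: mean last-visit minus first-visit contrast
    gain <- vapply(seq_len(cfg$n_participants), function(s) {
      es <- estimates[estimates$subject == s, ]
      mean(es$roi_contrast[es$visit == max(es$visit)]) -
        mean(es$roi_contrast[es$visit == 1])
    }, numeric(1))
    scaled_gain <- if (stats::sd(gain) > 0) as.numeric(scale(gain)) else
      rep(0, length(gain))
    comp_change <- with_seed(derive_seed(cfg$seed, 2),
      0.05 + 0.1 * scaled_gain +
        stats::rnorm(cfg$n_participants, 0, 0.1))
    report$composite <- data.frame(
      subject = seq_len(cfg$n_participants), baseline = base_comp,
      post = base_comp + comp_change, change = comp_change)
  }

  if ("behavior" %in% cfg$stages && cfg$n_participants < 5) {
    # the voxelwise regression carries an intercept + 3 covariates; with
    # fewer than 5 subjects there are no residual degrees of freedom
    report$behavior <- list(skipped = "fewer than 5 participants")
  } else if ("behavior" %in% cfg$stages) {
    nvox <- prod(cfg$grid$dim)
    change_maps <- matrix(0, nvox, cfg$n_participants)
    for (s in seq_len(cfg$n_participants)) {
      idx <- which(vapply(records, function(rec) rec$subject == s,
                          logical(1)))
      visits_s <- vapply(records[idx], function(rec) rec$visit, numeric(1))
      first <- maps[idx[visits_s == min(visits_s)]]
      last <- maps[idx[visits_s == max(visits_s)]]
      change_maps[, s] <-
        as.vector(Reduce(`+`, last) / length(last) -
                  Reduce(`+`, first) / length(first))
    }
    report$behavior <- behavior_regression(
      change_maps, report$composite$change,
      cohort[, c("age", "caudate_pct_icv")], cfg$grid$dim,
      p_threshold = cfg$voxel_p)
  }

  structure(report, class = "study_report")
}

#' Write a miniature canned dataset for fast pipeline tests
#'
#' One participant, 2 visits x 2 runs on a 12 x 12 x 8 grid: NIfTI volumes,
#' BIDS-style events TSV, motion TSV, a cohort CSV and a ground-truth JSON.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- acquisition_grid(c(12, 12, 8))
  truth <- simulation_truth(central_roi(grid, c(1, 1, 1)),
                            base_amplitude = 1, learning_slope = 0.5,
                            spike_times = 40L)
  design <- nf_block_design(tr = grid$tr)
  cohort <- simulate_cohort(cohort_spec(n_participants = 3,
                                        seed = derive_seed(seed, 1)))
  files <- character(0)
  for (v in 1:2) for (r in 1:2) {
    run <- simulate_run(truth, design, grid,
                        visit = v, seed = derive_seed(seed, 10 * v + r))
    stem <- file.path(out_dir, sprintf("sub-01_visit-%d_run-%d", v, r))
    files <- c(files,
               write_run_nifti(run, paste0(stem, "_bold.nii.gz")),
               write_events_tsv(design, paste0(stem, "_events.tsv")),
               write_motion_tsv(run$motion, paste0(stem, "_motion.tsv")))
  }
  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)
  truth_path <- write_truth_json(truth, file.path(out_dir, "truth.json"))
  invisible(c(files, cohort_path, truth_path))
}
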