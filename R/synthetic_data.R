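# run `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# default per-measure slopes on caudate %ICV: healthier (larger) caudate ->
# better performance, i.e. higher counts, longer annulus, faster/steadier taps
default_measure_effects <- c(
  stroop_word_correct = 60, sdmt_correct = 40, circle_trace_annulus = 600,
  emotion_recog_correct = 25, iti = -0.3, sd_ioi = -0.08, sd_dmti = -0.1)

measure_noise_sd <- c(
  stroop_word_correct = 6, sdmt_correct = 4, circle_trace_annulus = 60,
  emotion_recog_correct = 2.5, iti = 0.03, sd_ioi = 0.012, sd_dmti = 0.015)

measure_baselines <- c(
  stroop_word_correct = 60, sdmt_correct = 20, circle_trace_annulus = 150,
  emotion_recog_correct = 10, iti = 0.40, sd_ioi = 0.08, sd_dmti = 0.10)

#' Specification of a synthetic study cohort
#'
#' Describes a cohort of premanifest/early Huntington's disease gene carriers:
#' ages and CAG repeat lengths are sampled uniformly, the CAP disease-burden
#' score is computed from them, caudate volume (as % of intracranial volume)
#' is generated with a target negative rank correlation with CAP via a
#' Gaussian copula, and the seven cognitive/motor measures depend linearly on
#' caudate %ICV.
#'
#' @param n_participants Cohort size (at least 3; default 10).
#' @param age_range Age range in years.
#' @param cag_range Integer CAG repeat range; minimum must exceed 30 so the
#'   CAP formula is defined.
#' @param caudate_cap_rho Target Spearman correlation between caudate %ICV
#'   and CAP (negative: more disease burden, more atrophy).
#' @param measure_effect Either a scalar multiplier of the default
#'   per-measure slopes on caudate %ICV (0 gives measures unrelated to
#'   disease), or a full named vector of slopes.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 10, age_range = c(39, 68),
                        cag_range = c(39, 46), caudate_cap_rho = -0.8,
                        measure_effect = 1, seed = 1) {
  if (n_participants < 3) stop("`n_participants` must be at least 3")
  if (min(cag_range) <= 30)
    stop("`cag_range` minimum must exceed 30 (CAP requires CAG - 30 > 0)")
  stopifnot(length(age_range) == 2, diff(age_range) >= 0,
            caudate_cap_rho >= -1, caudate_cap_rho <= 1)
  eff <- if (length(measure_effect) == 1 && is.null(names(measure_effect))) {
    measure_effect * default_measure_effects
  } else {
    stopifnot(all(names(default_measure_effects) %in% names(measure_effect)))
    measure_effect[names(default_measure_effects)]
  }
  structure(list(n_participants = as.integer(n_participants),
                 age_range = age_range, cag_range = cag_range,
                 caudate_cap_rho = caudate_cap_rho, measure_effect = eff,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a study cohort with Table-1-like covariates and measure panel
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per participant: `id`, `sex`, `age`,
#'   `cag`, `cap`, `caudate_pct_icv`, `moca`, `tms`, `dcs`, `tfc`, and the
#'   seven raw measure columns (`stroop_word_correct`, `sdmt_correct`,
#'   `circle_trace_annulus`, `emotion_recog_correct`, `iti`, `sd_ioi`,
#'   `sd_dmti`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_participants
    age <- round(stats::runif(n, spec$age_range[1], spec$age_range[2]), 1)
    cag <- sample(seq(spec$cag_range[1], spec$cag_range[2]), n, replace = TRUE)
    cap <- cap_score(age, cag)
    # Gaussian copula: Pearson correlation on the latent normals that yields
    # the requested Spearman correlation for a bivariate normal
    r <- 2 * sin(pi * spec$caudate_cap_rho / 6)
    z_cap <- stats::qnorm(rank(cap, ties.method = "random") / (n + 1))
    z_caud <- r * z_cap + sqrt(1 - r^2) * stats::rnorm(n)
    caudate <- pmax(0.42 + 0.07 * z_caud, 0.05)
    df <- data.frame(
      id = seq_len(n),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4)),
      age = age, cag = cag, cap = cap, caudate_pct_icv = caudate,
      moca = round(clip(26 + 2 * z_caud + stats::rnorm(n, 0, 1.5), 15, 30)),
      tms = round(clip(10 - 5 * z_caud + stats::rnorm(n, 0, 3), 0, 20)),
      dcs = round(clip(3 - z_caud + stats::rnorm(n, 0, 1), 0, 4)),
      tfc = round(clip(12.3 + 0.5 * z_caud + stats::rnorm(n, 0, 0.7), 7, 13)))
    for (m in names(default_measure_effects)) {
      val <- measure_baselines[[m]] +
        spec$measure_effect[[m]] * (caudate - 0.42) +
        stats::rnorm(n, 0, measure_noise_sd[[m]])
      df[[m]] <- pmax(val, 0.01 * measure_baselines[[m]])
    }
    df
  })
}

#' Acquisition grid of a simulated run
#'
#' @param dim Integer grid dimensions (default 24 x 24 x 16, a deliberately
#'   small desk-scale grid).
#' @param vox_mm Voxel size in mm along each axis.
#' @param tr Repetition time in seconds.
#' @return An object of class `acquisition_grid`.
#' @export
acquisition_grid <- function(dim = c(24, 24, 16), vox_mm = c(3, 3, 3),
                             tr = 1) {
  stopifnot(length(dim) == 3, all(dim >= 1), all(vox_mm > 0), tr > 0)
  structure(list(dim = as.integer(dim), vox_mm = vox_mm, tr = tr),
            class = "acquisition_grid")
}

#' Central box ROI mask on a grid
#'
#' @param grid An [acquisition_grid()].
#' @param half_extent Half-width of the box in voxels along each axis.
#' @return Logical 3-D array.
#' @export
central_roi <- function(grid, half_extent = c(2, 2, 1)) {
  d <- grid$dim
  mask <- array(FALSE, d)
  c0 <- ceiling(d / 2)
  lo <- pmax(c0 - half_extent, 1)
  hi <- pmin(c0 + half_extent, d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask
}

#' Ground truth for one simulated BOLD run
#'
#' @param roi_mask Logical 3-D array marking the planted active voxels.
#' @param base_amplitude Upregulation amplitude at visit 1, in PSC %.
#' @param learning_slope Amplitude increase per visit, in PSC % per visit.
#' @param ar_coefficient AR(1) coefficient of the voxel noise, |phi| < 1.
#' @param noise_sd Innovation standard deviation of the noise, signal units.
#' @param drift_slope Linear drift in signal units per second.
#' @param spike_times Volume indices at which motion spikes are planted.
#' @param spike_magnitude Spike size in mm (planted on the first translation).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(roi_mask, base_amplitude = 0.5,
                             learning_slope = 0.4, ar_coefficient = 0.3,
                             noise_sd = 1, drift_slope = 0.002,
                             spike_times = integer(0),
                             spike_magnitude = 1.2) {
  if (!any(roi_mask)) stop("empty ROI voxel set")
  stopifnot(base_amplitude >= 0, abs(ar_coefficient) < 1, noise_sd >= 0)
  structure(list(roi_mask = roi_mask, base_amplitude = base_amplitude,
                 learning_slope = learning_slope,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 spike_times = as.integer(spike_times),
                 spike_magnitude = spike_magnitude),
            class = "simulation_truth")
}

#' Simulate a 4-D BOLD run with known ground truth
#'
#' Every voxel carries a flat baseline of 100 signal units (so percent signal
#' change is directly interpretable) plus linear drift and AR(1) noise;
#' planted ROI voxels additionally carry
#' `100 * amplitude/100 * (boxcar x HRF)` where the regressor is
#' plateau-normalized, and the amplitude at `visit` v is
#' `base_amplitude + learning_slope * (v - 1)` (floored at 0). A motion table
#' (3 translations mm, 3 rotations rad) with small fluctuations and planted
#' step spikes on the first translation accompanies the run.
#'
#' @param truth A [simulation_truth()].
#' @param design A [block_design()]; defaults to [nf_block_design()].
#' @param grid An [acquisition_grid()] consistent with `truth$roi_mask`.
#' @param hrf [hrf_params()].
#' @param visit Visit number (1-based) driving the learning amplitude.
#' @param signal_kind Block kind carrying the planted signal.
#' @param seed Integer seed; fixed seed gives identical volumes.
#' @return An object of class `nf_run`: list with `bold` (4-D array), `design`,
#'   `tr`, `grid`, `motion` (volumes x 6), `truth`, `visit`, `amplitude`.
#' @export
simulate_run <- function(truth, design = nf_block_design(),
                         grid = acquisition_grid(), hrf = hrf_params(),
                         visit = 1, signal_kind = "upregulate", seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(design, "block_design"),
            inherits(grid, "acquisition_grid"))
  if (!isTRUE(all(dim(truth$roi_mask) == grid$dim)))
    stop("truth ROI mask does not match the acquisition grid")
  if (abs(design$tr - grid$tr) > 1e-9)
    stop("design and grid disagree on TR")
  with_seed(seed, {
    nvol <- design$n_volumes
    nvox <- prod(grid$dim)
    amp <- max(truth$base_amplitude + truth$learning_slope * (visit - 1), 0)
    reg <- convolve_design(design, signal_kind, hrf, normalize = "plateau")
    times <- (seq_len(nvol) - 1) * design$tr

    noise <- matrix(stats::rnorm(nvol * nvox, 0, truth$noise_sd), nvol, nvox)
    if (truth$ar_coefficient != 0)
      noise <- as.matrix(stats::filter(noise, truth$ar_coefficient,
                                       method = "recursive"))
    signal <- matrix(100, nvol, nvox)
    roi_idx <- which(as.vector(truth$roi_mask))
    signal[, roi_idx] <- 100 * (1 + amp / 100 * reg)
    y <- signal + noise + truth$drift_slope * times
    bold <- array(t(y), dim = c(grid$dim, nvol))

    motion <- cbind(matrix(stats::rnorm(nvol * 3, 0, 0.02), nvol, 3),
                    matrix(stats::rnorm(nvol * 3, 0, 2e-4), nvol, 3))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    for (v in truth$spike_times)
      motion[v:nvol, 1] <- motion[v:nvol, 1] + truth$spike_magnitude

    structure(list(bold = bold, design = design, tr = design$tr, grid = grid,
                   motion = motion, truth = truth, visit = visit,
                   amplitude = amp),
              class = "nf_run")
  })
}

#' Simulate a paced-tapping onset sequence
#'
#' Onsets are the target-rhythm grid `k * target_period` plus independent
#' Gaussian jitter, emulating paced tapping at 1.8 Hz.
#'
#' @param n_taps Number of taps (at least 2).
#' @param target_period Target inter-tap period in seconds (default 1/1.8).
#' @param jitter_sd Standard deviation of the Gaussian onset jitter, seconds.
#' @param seed Integer seed.
#' @return An object of class `tap_sequence`: list with strictly increasing
#'   `onsets` (seconds), `target_period`, `jitter_sd`.
#' @export
simulate_taps <- function(n_taps, target_period = 1 / 1.8, jitter_sd = 0.02,
                          seed = NULL) {
  if (n_taps < 2) stop("`n_taps` must be at least 2")
  if (jitter_sd < 0) stop("`jitter_sd` must be nonnegative")
  if (target_period <= 0) stop("`target_period` must be positive")
  with_seed(seed, {
    onsets <- (seq_len(n_taps) - 1) * target_period +
      stats::rnorm(n_taps, 0, jitter_sd)
    if (any(diff(onsets) <= 0))
      stop("jitter too large: onsets are not strictly increasing")
    structure(list(onsets = onsets, target_period = target_period,
                   jitter_sd = jitter_sd),
              class = "tap_sequence")
  })
}
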