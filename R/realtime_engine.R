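#' Feedback engine configuration
#'
#' @param update_interval Average spacing of thermometer updates in seconds
#'   (default 1.5 s; with TR = 1 s this is realized as alternating 1 s / 2 s
#'   gaps, matching the average exactly on an integer-TR grid).
#' @param line_fraction Height of the target line on the thermometer as a
#'   fraction of its full height (default 3/5).
#' @param initial_scale Thermometer scale (max displayable PSC, in %) for the
#'   first upregulation block, before any shaping history exists.
#' @param scale_floor Smallest admissible scale in PSC %; shaping never sets
#'   the scale below this, so a displayable positive scale always exists.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(update_interval = 1.5, line_fraction = 3 / 5,
                          initial_scale = 1.0, scale_floor = 0.1) {
  stopifnot(update_interval > 0, line_fraction > 0, line_fraction < 1,
            initial_scale > 0, scale_floor > 0)
  structure(list(update_interval = update_interval,
                 line_fraction = line_fraction,
                 initial_scale = initial_scale,
                 scale_floor = scale_floor),
            class = "engine_config")
}

#' Mean ROI signal of one volume
#'
#' @param volume 3-D numeric array.
#' @param mask Logical array of the same dimensions with at least one voxel.
#' @return Arithmetic mean over masked voxels, in signal units.
#' @export
roi_mean <- function(volume, mask) {
  if (!isTRUE(all(dim(volume) == dim(mask))))
    stop("`volume` and `mask` must share a grid")
  if (!any(mask)) stop("empty ROI mask")
  mean(volume[mask])
}

#' HRF-weighted baseline estimate
#'
#' Inner product of the ROI samples from the preceding baseline block with
#' the normalized baseline weights; response-block samples are never included.
#'
#' @param samples ROI means over the baseline block, one per volume.
#' @param weights Weights from [baseline_weights()] (same length).
#' @return Baseline estimate in signal units.
#' @export
weighted_baseline <- function(samples, weights) {
  if (length(samples) != length(weights))
    stop("`samples` and `weights` must have equal length")
  sum(samples * weights)
}

#' Percent signal change against a baseline
#'
#' @param current Current ROI signal.
#' @param baseline Baseline ROI signal; must be positive.
#' @return 100 * (current - baseline) / baseline, in %.
#' @export
compute_psc <- function(current, baseline) {
  if (any(baseline <= 0)) stop("`baseline` must be positive")
  100 * (current - baseline) / baseline
}

#' Operant shaping update of the thermometer scale
#'
#' After each upregulation block the thermometer maximum for the next block is
#' set to the maximum PSC achieved in the completed block (floored at the
#' configured minimum scale, since only increases are displayed): a weak block
#' makes the next bar easier to fill, a strong block demands a yet higher PSC
#' for the same bar height.
#'
#' @param state List with elements `scale` and `prev_block_max_psc`.
#' @param completed_block_max_psc Maximum PSC (in %) of the completed block.
#' @param scale_floor Minimum admissible scale in %.
#' @return Updated state list.
#' @export
shaping_update <- function(state, completed_block_max_psc, scale_floor = 0.1) {
  list(scale = max(completed_block_max_psc, scale_floor),
       prev_block_max_psc = completed_block_max_psc)
}

#' Displayed bar height as a fraction of the thermometer
#'
#' Decreases are not shown (negative PSC maps to 0) and the bar saturates at
#' the current scale.
#'
#' @param psc Percent signal change.
#' @param scale Current thermometer scale in % (positive).
#' @return Fraction in [0, 1].
#' @export
bar_fraction <- function(psc, scale) {
  stopifnot(all(scale > 0))
  pmin(pmax(psc, 0), scale) / scale
}

# volume offsets (1-based within a block of m volumes) displayed at an
# average spacing of `interval` seconds: sample at times (j-1)*interval
display_offsets <- function(m, tr, interval) {
  t <- seq(0, m * tr - 1e-9, by = interval)
  unique(floor(t / tr) + 1L)
}

#' Run the closed-loop feedback computation over a simulated run
#'
#' Iterates volumes in acquisition order, recomputes the HRF-weighted baseline
#' at the end of every baseline block (response blocks are excluded from the
#' baseline), and during every upregulation block emits thermometer display
#' samples thinned to the configured average update interval. At the end of
#' each upregulation block the scale is updated by [shaping_update()] from the
#' maximum PSC over the emitted (participant-visible) samples; the first
#' upregulation block uses the configured initial scale.
#'
#' @param run An `nf_run` from [simulate_run()], or any list with elements
#'   `bold` (4-D array), `design` (a [block_design()]) and `tr`.
#' @param mask Logical 3-D array, the target ROI.
#' @param cfg [engine_config()].
#' @param hrf [hrf_params()] used for the baseline weighting.
#' @return A list of class `feedback_trace`: `trace`, a data frame with one
#'   row per emitted display sample (time, roi_mean, baseline, psc, scale,
#'   bar_fraction, block); and `blocks`, one row per upregulation block
#'   (block, scale_used, max_psc, baseline).
#' @export
run_feedback <- function(run, mask, cfg = engine_config(),
                         hrf = hrf_params()) {
  design <- run$design
  tr <- design$tr
  stopifnot(inherits(design, "block_design"), cfg$update_interval >= tr)
  blocks <- design$blocks
  first_up <- match("upregulate", blocks$kind)
  first_base <- match("baseline", blocks$kind)
  if (is.na(first_base) || (!is.na(first_up) && first_up < first_base))
    stop("an upregulation block precedes any baseline block")

  nvol <- design$n_volumes
  if (!any(mask)) stop("empty ROI mask")
  if (!isTRUE(all(dim(run$bold)[1:3] == dim(mask))))
    stop("run and mask must share a grid")
  # per-volume ROI means, computed in one pass over the masked voxels
  roi <- colMeans(matrix(run$bold, ncol = nvol)[as.vector(mask), ,
                                                drop = FALSE])
  times <- (seq_len(nvol) - 1) * tr

  baseline <- NA_real_
  scale <- cfg$initial_scale
  state <- list(scale = scale, prev_block_max_psc = NA_real_)
  trace <- list()
  block_rows <- list()

  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    vols <- which(times >= b$onset - 1e-9 & times < b$onset + b$duration - 1e-9)
    if (b$kind == "baseline") {
      w <- baseline_weights(b$duration, tr, hrf)
      baseline <- weighted_baseline(roi[vols], w)
    } else if (b$kind == "upregulate") {
      if (is.na(baseline))
        stop("an upregulation block precedes any completed baseline block")
      offs <- display_offsets(length(vols), tr, cfg$update_interval)
      emit <- vols[offs]
      psc <- compute_psc(roi[emit], baseline)
      trace[[length(trace) + 1L]] <- data.frame(
        time = times[emit], roi_mean = roi[emit], baseline = baseline,
        psc = psc, scale = state$scale,
        bar_fraction = bar_fraction(psc, state$scale), block = i)
      block_rows[[length(block_rows) + 1L]] <- data.frame(
        block = i, scale_used = state$scale, max_psc = max(psc),
        baseline = baseline)
      state <- shaping_update(state, max(psc), cfg$scale_floor)
    }
    # response blocks: acquired but never used for baseline or display
  }
  structure(list(trace = do.call(rbind, trace),
                 blocks = do.call(rbind, block_rows),
                 config = cfg),
            class = "feedback_trace")
}
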