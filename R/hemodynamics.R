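#' Canonical double-gamma HRF parameters
#'
#' The hemodynamic response is modelled as a mixture (difference) of two gamma
#' densities: a positive peak component minus a scaled undershoot component.
#' Defaults follow the community-standard canonical form: peak around 5 s,
#' undershoot around 15 s, undershoot ratio 1/6. All parameters are in the
#' shape/rate parameterization of the gamma density with time in seconds.
#'
#' @param peak_shape,peak_rate Shape and rate of the peak gamma component.
#' @param under_shape,under_rate Shape and rate of the undershoot component.
#' @param under_ratio Nonnegative weight of the undershoot component.
#' @return An object of class `hrf_params`.
#' @export
#' @examples
#' p <- hrf_params()
#' hrf_value(5, p) > hrf_value(1, p)
hrf_params <- function(peak_shape = 6, peak_rate = 1,
                       under_shape = 16, under_rate = 1,
                       under_ratio = 1 / 6) {
  stopifnot(peak_shape > 0, peak_rate > 0, under_shape > 0, under_rate > 0)
  if (under_ratio < 0) stop("`under_ratio` must be nonnegative")
  structure(list(peak_shape = peak_shape, peak_rate = peak_rate,
                 under_shape = under_shape, under_rate = under_rate,
                 under_ratio = under_ratio),
            class = "hrf_params")
}

#' Evaluate the double-gamma HRF
#'
#' @param t Time in seconds since stimulus onset; must be nonnegative.
#' @param params An [hrf_params()] object.
#' @return Unitless response values, one per element of `t`.
#' @export
hrf_value <- function(t, params = hrf_params()) {
  if (any(t < 0)) stop("`t` must be nonnegative")
  stats::dgamma(t, shape = params$peak_shape, rate = params$peak_rate) -
    params$under_ratio *
      stats::dgamma(t, shape = params$under_shape, rate = params$under_rate)
}

# HRF sampled on the TR grid over its support (32 s covers peak + undershoot)
hrf_kernel <- function(tr, params, support = 32) {
  hrf_value(seq(0, support, by = tr), params)
}

#' Block design for an fMRI run
#'
#' A block design is an ordered table of non-overlapping blocks, each with a
#' kind (e.g. "baseline", "response", "upregulate", "tap", "rest", "clench"),
#' an onset and a duration in seconds, plus the repetition time TR.
#'
#' @param blocks A data frame with columns `kind`, `onset`, `duration`.
#' @param tr Repetition time in seconds.
#' @return An object of class `block_design`.
#' @export
block_design <- function(blocks, tr = 1) {
  stopifnot(is.data.frame(blocks),
            all(c("kind", "onset", "duration") %in% names(blocks)),
            tr > 0)
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  ends <- blocks$onset + blocks$duration
  if (nrow(blocks) > 1 && any(blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9))
    stop("blocks overlap")
  total <- max(ends)
  if (abs(total / tr - round(total / tr)) > 1e-9)
    stop("total design duration must be divisible by TR")
  structure(list(blocks = blocks, tr = tr,
                 n_volumes = as.integer(round(total / tr))),
            class = "block_design")
}

#' Standard neurofeedback training run design
#'
#' Builds the canonical training-run design: a repeating triplet of a 30 s
#' baseline block, a 16 s response block (which lets the hemodynamic response
#' return to baseline before upregulation) and a 30 s upregulation block,
#' repeated five times, closed by a final baseline + response pair — 6
#' baseline, 6 response and 5 upregulation blocks, 426 s in total.
#'
#' @param tr Repetition time in seconds (default 1).
#' @param baseline_s,response_s,upregulate_s Block durations in seconds.
#' @return A `block_design` with 426 volumes at the defaults.
#' @export
nf_block_design <- function(tr = 1, baseline_s = 30, response_s = 16,
                            upregulate_s = 30) {
  kinds <- c(rep(c("baseline", "response", "upregulate"), 5),
             "baseline", "response")
  durs <- c(baseline = baseline_s, response = response_s,
            upregulate = upregulate_s)[kinds]
  onsets <- cumsum(c(0, durs[-length(durs)]))
  block_design(data.frame(kind = kinds, onset = unname(onsets),
                          duration = unname(durs)), tr = tr)
}

#' Alternating two-condition design (localizer / paced tapping)
#'
#' @param active_kind Kind label of the active blocks (e.g. "clench", "tap").
#' @param n_cycles Number of rest+active cycles.
#' @param block_s Duration of every block in seconds.
#' @param tr Repetition time in seconds.
#' @return A `block_design` alternating "rest" and `active_kind`.
#' @export
alternating_design <- function(active_kind = "clench", n_cycles = 6,
                               block_s = 20, tr = 1) {
  kinds <- rep(c("rest", active_kind), n_cycles)
  onsets <- seq_along(kinds) * block_s - block_s
  block_design(data.frame(kind = kinds, onset = onsets, duration = block_s),
               tr = tr)
}

# 0/1 indicator per volume for blocks of the given kind
design_boxcar <- function(design, kind) {
  stopifnot(inherits(design, "block_design"))
  times <- (seq_len(design$n_volumes) - 1) * design$tr
  box <- numeric(design$n_volumes)
  for (i in which(design$blocks$kind == kind)) {
    b <- design$blocks[i, ]
    box[times >= b$onset - 1e-9 & times < b$onset + b$duration - 1e-9] <- 1
  }
  box
}

#' Convolve a block design with the HRF
#'
#' Forms the 0/1 boxcar of the requested block kind sampled at TR resolution
#' and convolves it with the HRF (discrete convolution, scaled by TR so that a
#' long block plateaus at the HRF time-integral), truncated to the run length.
#' With `normalize = "plateau"` the regressor is rescaled so a sustained block
#' plateaus at exactly 1, making a planted amplitude directly interpretable as
#' percent signal change.
#'
#' @param design A [block_design()].
#' @param kind Block kind to convolve; must appear in the design (an all-zero
#'   regressor for a declared-but-absent kind is allowed via `allow_empty`).
#' @param params [hrf_params()].
#' @param normalize `"none"` (raw HRF-integral scale) or `"plateau"`.
#' @param allow_empty Permit a kind absent from the design (returns zeros).
#' @return Numeric regressor, one value per volume.
#' @export
convolve_design <- function(design, kind, params = hrf_params(),
                            normalize = c("none", "plateau"),
                            allow_empty = FALSE) {
  normalize <- match.arg(normalize)
  if (!allow_empty && !kind %in% design$blocks$kind)
    stop("unknown block kind: ", kind)
  box <- design_boxcar(design, kind)
  h <- hrf_kernel(design$tr, params)
  out <- design$tr * stats::convolve(box, rev(h), type = "open")
  out <- out[seq_len(design$n_volumes)]
  if (normalize == "plateau") {
    plateau <- design$tr * sum(h)
    if (abs(plateau) < 1e-12) stop("HRF integrates to zero; cannot normalize")
    out <- out / plateau
  }
  out
}

#' Hemodynamically weighted baseline-block weights
#'
#' The real-time baseline is a weighted average of the ROI signal over the
#' preceding baseline block, weighted by the HRF evaluated at the time since
#' block onset. Negative HRF lobes are floored at zero so the baseline stays a
#' convex combination of observed samples; the weights are normalized to sum
#' to one. `method = "convolved"` instead weights by the block-convolved
#' response (boxcar x HRF) over the block.
#'
#' @param duration Baseline-block duration in seconds (divisible by `tr`).
#' @param tr Repetition time in seconds.
#' @param params [hrf_params()].
#' @param method `"hrf"` (default) or `"convolved"`.
#' @return Numeric vector of `duration/tr` nonnegative weights summing to 1.
#' @export
#' @examples
#' w <- baseline_weights(30, 1)
#' sum(w)  # 1
baseline_weights <- function(duration, tr = 1, params = hrf_params(),
                             method = c("hrf", "convolved")) {
  method <- match.arg(method)
  n <- duration / tr
  if (abs(n - round(n)) > 1e-9) stop("`duration` must be divisible by `tr`")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1) * tr
  raw <- if (method == "hrf") {
    hrf_value(t, params)
  } else {
    h <- hrf_kernel(tr, params)
    (tr * stats::convolve(rep(1, n), rev(h), type = "open"))[seq_len(n)]
  }
  raw <- pmax(raw, 0)
  s <- sum(raw)
  if (s <= 0) stop("all baseline weights are zero before normalization")
  raw / s
}
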