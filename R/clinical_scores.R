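#' CAG-Age Product (CAP) disease-burden score
#'
#' `100 * age * (CAG - 30) / 627`, normalized so that the score is about 100
#' at a gene-carrier's expected age of onset. The exact (unrounded) value is
#' returned; round to the nearest integer for tabular display.
#'
#' @param age Age in years (positive).
#' @param cag CAG repeat length; must exceed 30.
#' @return Unitless CAP score (vectorized).
#' @export
#' @examples
#' round(cap_score(43, 46))  # 110
cap_score <- function(age, cag) {
  if (any(cag <= 30)) stop("`cag` must exceed 30 for the CAP score")
  if (any(age <= 0)) stop("`age` must be positive")
  100 * age * (cag - 30) / 627
}

# canonical measure order of the cognitive/Q-Motor panel
measure_names <- function() names(default_measure_effects)

#' Direction-harmonized measure panel
#'
#' Transforms the seven raw cognitive and quantitative-motor measures so that
#' larger always means better: Stroop word reading, SDMT and negative emotion
#' recognition counts and the (log-transformed) indirect-circle-tracing
#' annulus length enter as is, while the speeded-tapping inter-tap interval
#' and the log-transformed tapping variability measures (SD of inter-onset
#' interval, SD of mid-tap interval deviation) are negated.
#'
#' @param panel Named list or one-row data frame with raw values for
#'   `stroop_word_correct`, `sdmt_correct`, `circle_trace_annulus`,
#'   `emotion_recog_correct`, `iti`, `sd_ioi`, `sd_dmti`.
#' @return Named numeric vector of 7 harmonized values, in canonical order.
#' @export
harmonize_measures <- function(panel) {
  need <- measure_names()
  if (!all(need %in% names(panel))) {
    stop("panel is missing measures: ",
         paste(setdiff(need, names(panel)), collapse = ", "))
  }
  p <- lapply(panel[need], as.numeric)
  for (m in c("circle_trace_annulus", "sd_ioi", "sd_dmti"))
    if (p[[m]] <= 0) stop("`", m, "` must be positive before log transform")
  c(stroop_word_correct = p$stroop_word_correct,
    sdmt_correct = p$sdmt_correct,
    circle_trace_annulus = log(p$circle_trace_annulus),
    emotion_recog_correct = p$emotion_recog_correct,
    iti = -p$iti,
    sd_ioi = -log(p$sd_ioi),
    sd_dmti = -log(p$sd_dmti))
}

#' Reference norms for measure standardization
#'
#' Means and standard deviations of the harmonized measures in an external
#' reference cohort, used for z-standardization.
#'
#' @param mean,sd Named numeric vectors covering all seven measures (on the
#'   harmonized scale); all SDs must be positive.
#' @return An object of class `reference_norms`.
#' @export
reference_norms <- function(mean, sd) {
  need <- measure_names()
  if (!all(need %in% names(mean)) || !all(need %in% names(sd)))
    stop("norms must cover all seven measures")
  if (any(sd[need] <= 0)) stop("reference SDs must be positive")
  structure(list(mean = mean[need], sd = sd[need]),
            class = "reference_norms")
}

#' Synthetic example reference norms
#'
#' A synthetic stand-in for norms from an independent early-HD reference
#' sample, with means/SDs on the harmonized scale matched to the synthetic
#' cohort generator's typical output; suitable for examples and tests.
#'
#' @return A [reference_norms()] object.
#' @export
example_norms <- function() {
  reference_norms(
    mean = c(stroop_word_correct = 60, sdmt_correct = 20,
             circle_trace_annulus = log(150), emotion_recog_correct = 10,
             iti = -0.40, sd_ioi = -log(0.08), sd_dmti = -log(0.10)),
    sd = c(stroop_word_correct = 8, sdmt_correct = 5,
           circle_trace_annulus = 0.4, emotion_recog_correct = 3,
           iti = 0.05, sd_ioi = 0.25, sd_dmti = 0.25))
}

#' Composite cognitive/motor score
#'
#' Mean over the seven measures of the direction-harmonized value,
#' z-standardized against the reference norms.
#'
#' @param panel Raw measure panel (see [harmonize_measures()]).
#' @param norms A [reference_norms()] object.
#' @return Unitless composite score.
#' @export
composite_score <- function(panel, norms) {
  stopifnot(inherits(norms, "reference_norms"))
  h <- harmonize_measures(panel)
  mean((h - norms$mean[names(h)]) / norms$sd[names(h)])
}

#' Quantitative-motor tapping measures from an onset sequence
#'
#' Inter-tap interval (mean inter-onset interval), log SD of the inter-onset
#' intervals, and log SD of the mid-tap interval deviation from the target
#' rhythm. The mid-tap deviation of each pair of consecutive taps is the
#' offset of their midpoint from the nearest target-grid midpoint
#' (grid anchored at the first onset), wrapped to half a period either side.
#'
#' @param taps A `tap_sequence` from [simulate_taps()], or a list with
#'   `onsets` and `target_period`.
#' @return Named list: `iti` (s), `sd_ioi` (s), `sd_dmti` (s), `log_sd_ioi`,
#'   `log_sd_dmti`.
#' @export
tapping_measures <- function(taps) {
  onsets <- taps$onsets
  period <- taps$target_period
  if (length(onsets) < 3) stop("at least 3 taps are required")
  ioi <- diff(onsets)
  if (stats::sd(ioi) == 0)
    stop("zero inter-onset variance: log SD undefined")
  mid <- (onsets[-length(onsets)] + onsets[-1]) / 2
  rel <- mid - (onsets[1] + period / 2)
  dev <- rel - round(rel / period) * period
  if (stats::sd(dev) == 0)
    stop("zero mid-tap deviation variance: log SD undefined")
  list(iti = mean(ioi), sd_ioi = stats::sd(ioi), sd_dmti = stats::sd(dev),
       log_sd_ioi = log(stats::sd(ioi)), log_sd_dmti = log(stats::sd(dev)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average) ranks; errors on constant input rather
#' than returning NA.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Rank correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  stats::cor(rank(x), rank(y))
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three variables, residualizes the x- and y-ranks on
#' the control ranks by OLS, and correlates the residuals. A constant control
#' reduces to the plain Spearman correlation.
#'
#' @param x,y Numeric vectors (length at least 4).
#' @param control Numeric control variable of the same length.
#' @return Adjusted rank correlation.
#' @export
partial_spearman <- function(x, y, control) {
  n <- length(x)
  if (length(y) != n || length(control) != n)
    stop("all inputs must have equal length")
  if (n < 4) stop("at least 4 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  if (stats::sd(control) == 0) return(spearman_rho(x, y))
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  ex <- stats::residuals(stats::lm(rx ~ rc))
  ey <- stats::residuals(stats::lm(ry ~ rc))
  if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12)
    stop("degenerate after adjustment: correlation undefined")
  stats::cor(ex, ey)
}

#' The 10-participant study cohort table
#'
#' Characteristics of the ten Huntington's disease gene carriers used in the
#' worked examples: sex, age, CAG repeat length, CAP score, caudate volume as
#' % of intracranial volume, MOCA, and UHDRS total motor score (TMS),
#' diagnostic confidence score (DCS) and total functional capacity (TFC).
#'
#' @return Data frame with 10 rows, read from the packaged cohort CSV.
#' @export
hd_cohort <- function() {
  path <- system.file("extdata", "hd_cohort.csv", package = "rtnf",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
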