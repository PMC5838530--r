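#' Scan-to-scan displacement from realignment parameters
#'
#' Displacement at volume v is the maximum over the six parameters of the
#' absolute frame-to-frame difference, with rotations (radians) converted to
#' mm of arc on a 50 mm head radius. The first volume has displacement 0.
#'
#' @param motion Numeric matrix, one row per volume: 3 translations (mm) then
#'   3 rotations (rad).
#' @param head_radius_mm Rotation-to-mm conversion radius (default 50).
#' @return Numeric vector of displacements, one per volume.
#' @export
scan_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("at least 2 volumes are required")
  if (ncol(motion) != 6) stop("`motion` must have 6 columns")
  scaled <- motion
  scaled[, 4:6] <- scaled[, 4:6] * head_radius_mm
  d <- abs(diff(scaled))
  c(0, apply(d, 1, max))
}

#' Motion-spike indicator regressors
#'
#' Flags volumes whose scan-to-scan displacement strictly exceeds the
#' threshold and builds one one-hot indicator column per flagged volume, for
#' inclusion as nuisance regressors in first-level models.
#'
#' @param motion Motion-parameter matrix (see [scan_displacement()]).
#' @param threshold_mm Displacement threshold in mm (default 1; strict).
#' @param head_radius_mm Rotation conversion radius in mm.
#' @return List with `columns` (volumes x n_spikes indicator matrix, possibly
#'   0 columns), `flagged` (volume indices) and `displacement`.
#' @export
spike_regressors <- function(motion, threshold_mm = 1, head_radius_mm = 50) {
  disp <- scan_displacement(motion, head_radius_mm)
  flagged <- which(disp > threshold_mm)
  cols <- matrix(0, length(disp), length(flagged))
  for (j in seq_along(flagged)) cols[flagged[j], j] <- 1
  if (length(flagged))
    colnames(cols) <- paste0("spike_", flagged)
  list(columns = cols, flagged = flagged, displacement = disp)
}

#' Run-level motion exclusion
#'
#' A run is excluded when any scan-to-scan displacement strictly exceeds the
#' run-exclusion threshold (default 2 mm).
#'
#' @param motion Motion-parameter matrix.
#' @param threshold_mm Exclusion threshold in mm (default 2; strict).
#' @param head_radius_mm Rotation conversion radius in mm.
#' @return Logical: `TRUE` if the run should be excluded.
#' @export
exclude_run <- function(motion, threshold_mm = 2, head_radius_mm = 50) {
  any(scan_displacement(motion, head_radius_mm) > threshold_mm)
}

#' Upregulation-versus-baseline block contrast for one run
#'
#' First-level GLM with HRF-convolved regressors for the active block kinds
#' (baseline/rest blocks form the implicit baseline), an intercept, a linear
#' drift term, and any nuisance columns (motion parameters, spike
#' indicators). The contrast puts weight +1 on the requested active kind.
#'
#' @param run An `nf_run`.
#' @param mask Logical array; the ROI over which the mean contrast is taken.
#' @param hrf [hrf_params()].
#' @param active_kind Contrasted block kind (default "upregulate").
#' @param nuisance Optional matrix of nuisance regressors (volumes x q).
#' @return List with `map` (3-D contrast-estimate array), `tmap`, `roi`
#'   (mean contrast over the mask), `roi_t`, and `fit` (the `nf_glm`).
#' @export
block_contrast <- function(run, mask, hrf = hrf_params(),
                           active_kind = "upregulate", nuisance = NULL) {
  design <- run$design
  kinds <- unique(design$blocks$kind)
  base_kinds <- intersect(kinds, c("baseline", "rest"))
  if (!active_kind %in% kinds)
    stop("design has no '", active_kind, "' blocks")
  if (!length(base_kinds))
    stop("design has no baseline/rest blocks")
  task_kinds <- setdiff(kinds, base_kinds)
  regs <- sapply(task_kinds, function(k) convolve_design(design, k, hrf))
  times <- (seq_len(design$n_volumes) - 1) * run$tr
  X <- cbind(intercept = 1, regs, drift = drop(scale(times, scale = FALSE)))
  if (!is.null(nuisance) && NCOL(nuisance) > 0)
    X <- cbind(X, as.matrix(nuisance))
  contrast <- as.numeric(colnames(X) == active_kind)
  names(contrast) <- colnames(X)
  Y <- t(matrix(run$bold, ncol = design$n_volumes))
  fit <- fit_glm(Y, X)
  con <- glm_contrast(fit, contrast)
  map <- array(con$estimate, dim = run$grid$dim)
  tmap <- array(con$t, dim = run$grid$dim)
  list(map = map, tmap = tmap, roi = mean(map[mask]),
       roi_t = mean(tmap[mask]), fit = fit)
}

#' Linear mixed-effects trend of ROI activation across visits
#'
#' Fits `response ~ visit + run (+ age + caudate_pct_icv) + (1 | subject)` by
#' REML with Satterthwaite degrees of freedom for the Wald test on the visit
#' slope. Covariate columns are used when present in `data`.
#'
#' @param data Data frame with columns `subject`, `visit`, `run`, the
#'   response, and optionally `age` and `caudate_pct_icv`.
#' @param response Name of the response column (default "roi_contrast").
#' @param random Fit the random intercept (default `TRUE`); with `FALSE` an
#'   ordinary least-squares fit of the same fixed effects is returned, which
#'   the mixed fit reduces to when the intercept variance is zero.
#' @return An object of class `trend_result`: data frame `fixed` (term,
#'   estimate, se, df, t, p), `ranef_var`, `resid_var`, `singular`, `model`.
#' @export
visit_trend <- function(data, response = "roi_contrast", random = TRUE) {
  stopifnot(all(c("subject", "visit", "run", response) %in% names(data)))
  if (length(unique(data$subject)) < 2) stop("at least 2 subjects required")
  if (length(unique(data$visit)) < 2) stop("at least 2 visits required")
  covs <- intersect(c("age", "caudate_pct_icv"), names(data))
  rhs <- paste(c("visit", "run", covs), collapse = " + ")
  # a degenerate constant response cannot support a variance decomposition;
  # fall back to the fixed-effects fit (slope exactly 0)
  if (stats::sd(data[[response]]) == 0) random <- FALSE
  if (random) {
    fml <- stats::as.formula(
      paste(response, "~", rhs, "+ (1 | subject)"))
    fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
    sm <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    structure(list(
      fixed = data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                         se = sm[, "Std. Error"], df = sm[, "df"],
                         t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                         row.names = NULL),
      ranef_var = vc$vcov[vc$grp == "subject"],
      resid_var = vc$vcov[vc$grp == "Residual"],
      singular = lme4::isSingular(fit), model = fit),
      class = "trend_result")
  } else {
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(fml, data = data)
    sm <- summary(fit)$coefficients
    structure(list(
      fixed = data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                         se = sm[, "Std. Error"], df = fit$df.residual,
                         t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                         row.names = NULL),
      ranef_var = 0, resid_var = summary(fit)$sigma^2,
      singular = FALSE, model = fit),
      class = "trend_result")
  }
}

#' Extract one fixed effect from a trend fit
#'
#' @param trend A `trend_result`.
#' @param term Term name (default "visit").
#' @return One-row data frame with estimate, se, df, t, p.
#' @export
trend_effect <- function(trend, term = "visit") {
  row <- trend$fixed[trend$fixed$term == term, ]
  if (!nrow(row)) stop("no such term: ", term)
  row
}

#' Psychophysiological-interaction design terms
#'
#' The condition regressor is the HRF-convolved condition boxcar, mean
#' centered; the seed series is mean centered; the PPI interaction is their
#' elementwise product (no deconvolution).
#'
#' @param seed_series Seed-ROI time series, one value per volume.
#' @param condition_boxcar 0/1 condition indicator per volume (e.g.
#'   upregulate vs baseline).
#' @param hrf [hrf_params()].
#' @param tr Repetition time in seconds.
#' @return List of class `ppi_design`: `seed` (centered), `condition`
#'   (convolved, centered), `interaction`.
#' @export
ppi_terms <- function(seed_series, condition_boxcar, hrf = hrf_params(),
                      tr = 1) {
  if (length(seed_series) != length(condition_boxcar))
    stop("`seed_series` and `condition_boxcar` must have equal length")
  h <- hrf_kernel(tr, hrf)
  conv <- (tr * stats::convolve(condition_boxcar, rev(h),
                                type = "open"))[seq_along(condition_boxcar)]
  cond <- conv - mean(conv)
  seed <- seed_series - mean(seed_series)
  structure(list(seed = seed, condition = cond,
                 interaction = cond * seed),
            class = "ppi_design")
}

#' Fit a PPI model to a target time series
#'
#' OLS regression of the target series on the seed series, the condition
#' regressor and the PPI interaction, plus intercept and optional nuisance
#' columns; returns the interaction (PPI) coefficient.
#'
#' @param target Target time series.
#' @param ppi A `ppi_design` from [ppi_terms()].
#' @param nuisance Optional nuisance matrix.
#' @return List with `beta` (PPI coefficient), `t`, `p`, `fit`.
#' @export
fit_ppi <- function(target, ppi, nuisance = NULL) {
  stopifnot(inherits(ppi, "ppi_design"),
            length(target) == length(ppi$seed))
  X <- cbind(intercept = 1, seed = ppi$seed, condition = ppi$condition,
             ppi = ppi$interaction)
  if (!is.null(nuisance) && NCOL(nuisance) > 0)
    X <- cbind(X, as.matrix(nuisance))
  fit <- fit_glm(matrix(target, ncol = 1), X)
  con <- glm_contrast(fit, as.numeric(colnames(X) == "ppi"))
  list(beta = con$estimate, t = con$t,
       p = 2 * stats::pt(-abs(con$t), con$dof), fit = fit)
}

#' Across-visit change in PPI coupling
#'
#' Second-level mixed model on first-level PPI coefficients, identical in
#' structure to [visit_trend()].
#'
#' @param data Data frame with `subject`, `visit`, `run`, `beta` and optional
#'   covariates `age`, `caudate_pct_icv`.
#' @return A `trend_result`.
#' @export
connectivity_change <- function(data) {
  visit_trend(data, response = "beta")
}

#' Label 26-connected clusters in a 3-D mask
#'
#' @param mask Logical 3-D array.
#' @return List with `labels` (integer array, 0 = background) and `sizes`
#'   (cluster sizes, decreasing).
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  current <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      cv <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(cv), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & labels[lin] == 0L]
      labels[new] <- current
      queue <- c(queue, new)
    }
  }
  sizes <- if (current > 0) sort(tabulate(labels[labels > 0L]),
                                 decreasing = TRUE) else integer(0)
  list(labels = labels, sizes = sizes)
}

#' Voxelwise regression of activation change on behavioural change
#'
#' Per-voxel OLS of the activation-change maps on the composite-score change
#' with age and caudate %ICV as confounds; voxels significant at the
#' uncorrected voxel threshold are grouped into 26-connected clusters.
#' Family-wise inference is not performed; cluster sizes are reported, with an
#' optional max-cluster-size permutation null available via `n_perm`.
#'
#' @param change_maps Numeric matrix, one column per subject, one row per
#'   voxel (in grid order).
#' @param composite_change Per-subject behavioural change scores.
#' @param covariates Data frame with per-subject `age` and `caudate_pct_icv`.
#' @param dim_grid Integer grid dimensions of the maps.
#' @param p_threshold Uncorrected voxel threshold (default 0.001).
#' @param n_perm Optional number of permutations of `composite_change` for a
#'   max-cluster-size null (0 = skip).
#' @param seed Seed for the permutation null.
#' @return List with `tmap` (array), `pmap`, `sig` (logical array),
#'   `clusters` (from [label_clusters()]), `dof`, and `perm_max_sizes`.
#' @export
behavior_regression <- function(change_maps, composite_change, covariates,
                                dim_grid, p_threshold = 0.001, n_perm = 0,
                                seed = NULL) {
  change_maps <- as.matrix(change_maps)
  n <- ncol(change_maps)
  stopifnot(length(composite_change) == n, nrow(covariates) == n)
  X <- cbind(intercept = 1, composite = composite_change,
             age = covariates$age, caudate = covariates$caudate_pct_icv)
  if (n - qr(X)$rank <= 0)
    stop("no residual degrees of freedom: too few subjects")
  run_once <- function(comp) {
    X[, "composite"] <- comp
    fit <- fit_glm(t(change_maps), X)
    glm_contrast(fit, c(0, 1, 0, 0))
  }
  con <- run_once(composite_change)
  pmap <- 2 * stats::pt(-abs(con$t), con$dof)
  sig <- array(pmap < p_threshold, dim_grid)
  # constant maps yield 0/0 t-statistics; treat as nonsignificant
  sig[is.na(sig)] <- FALSE
  cl <- label_clusters(sig)
  perm_max <- NULL
  if (n_perm > 0) {
    perm_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      ci <- run_once(sample(composite_change))
      pi <- 2 * stats::pt(-abs(ci$t), ci$dof)
      si <- array(pi < p_threshold, dim_grid)
      si[is.na(si)] <- FALSE
      szs <- label_clusters(si)$sizes
      if (length(szs)) max(szs) else 0L
    }, integer(1)))
  }
  list(tmap = array(con$t, dim_grid), pmap = array(pmap, dim_grid),
       sig = sig, clusters = cl, dof = con$dof, perm_max_sizes = perm_max)
}

#' Compare tapping-task ROI contrasts across session types
#'
#' Computes the tapping-versus-rest ROI contrast per subject for each of the
#' three session types (pretraining, post-training without upregulation,
#' post-training with upregulation), tests for differences among session
#' types with a repeated-measures ANOVA, and compares with- versus
#' without-upregulation with a paired t-test.
#'
#' @param runs_pre,runs_post_without,runs_post_with Named lists of `nf_run`
#'   objects, one per subject; names must match across conditions.
#' @param mask ROI mask for contrast extraction.
#' @param hrf [hrf_params()].
#' @param active_kind Tapping block kind (default "tap").
#' @return List with `contrasts` (subject x condition data frame), `anova`
#'   (repeated-measures ANOVA table), `paired` (htest for with - without).
#' @export
tapping_contrast_comparison <- function(runs_pre, runs_post_without,
                                        runs_post_with, mask,
                                        hrf = hrf_params(),
                                        active_kind = "tap") {
  conds <- list(pre = runs_pre, post_without = runs_post_without,
                post_with = runs_post_with)
  if (any(vapply(conds, length, 1L) == 0)) stop("missing condition")
  ids <- names(conds$pre)
  if (is.null(ids) ||
      !all(vapply(conds, function(x) identical(sort(names(x)), sort(ids)),
                  logical(1))))
    stop("subjects are not matched across conditions")
  est <- sapply(conds, function(runs) {
    vapply(ids, function(s)
      block_contrast(runs[[s]], mask, hrf, active_kind = active_kind)$roi,
      numeric(1))
  })
  long <- data.frame(subject = factor(rep(ids, 3)),
                     condition = factor(rep(colnames(est),
                                            each = length(ids))),
                     contrast = as.vector(est))
  aov_fit <- stats::aov(contrast ~ condition + Error(subject / condition),
                        data = long)
  paired <- stats::t.test(est[, "post_with"], est[, "post_without"],
                          paired = TRUE)
  list(contrasts = data.frame(subject = ids, est, row.names = NULL),
       anova = summary(aov_fit), paired = paired)
}
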