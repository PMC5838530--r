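#' Fit a massively univariate GLM by ordinary least squares
#'
#' Fits `Y = X B + E` independently per voxel (column of `Y`) and computes
#' contrast t-statistics `t = c'b / sqrt(s2 * c'(X'X)^-1 c)`.
#'
#' @param Y Numeric matrix, one row per volume, one column per voxel.
#' @param X Design matrix (volumes x regressors), full column rank.
#' @return An object of class `nf_glm`: `betas` (regressors x voxels),
#'   `sigma2` (residual variance per voxel), `dof`, `xtx_inv`, `dim_grid`
#'   (carried through by [block_contrast()] when known).
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("time dimensions of `Y` and `X` differ")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  dof <- nrow(X) - qx$rank
  if (dof <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / dof
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 colnames = colnames(X)),
            class = "nf_glm")
}

#' Contrast estimates and t-map from a fitted GLM
#'
#' @param fit An [fit_glm()] result.
#' @param contrast Numeric contrast vector, one weight per regressor.
#' @return List with `estimate` and `t` (one value per voxel) and `dof`.
#' @export
glm_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "nf_glm"),
            length(contrast) == nrow(fit$betas))
  est <- drop(crossprod(contrast, fit$betas))
  varc <- drop(crossprod(contrast, fit$xtx_inv %*% contrast))
  list(estimate = est, t = est / sqrt(fit$sigma2 * varc), dof = fit$dof)
}

#' Select a target ROI by thresholding a t-map
#'
#' Voxels with t strictly greater than the threshold, intersected with an
#' anatomical mask. An empty result is returned with a warning (per-visit
#' redrawing naturally yields variable, occasionally empty selections).
#'
#' @param tmap Numeric 3-D array of t-values.
#' @param t_threshold Threshold (default 3); strictly exceeded.
#' @param anatomical_mask Optional logical array restricting the search.
#' @return Logical array, the selected ROI.
#' @export
select_roi <- function(tmap, t_threshold = 3, anatomical_mask = NULL) {
  stopifnot(t_threshold > 0)
  sel <- tmap > t_threshold
  if (!is.null(anatomical_mask)) {
    if (!isTRUE(all(dim(tmap) == dim(anatomical_mask))))
      stop("t-map and anatomical mask must share a grid")
    sel <- sel & anatomical_mask
  }
  if (!any(sel)) warning("no voxels exceed the t threshold; empty ROI")
  sel
}

#' Combine individual ROI masks into a group mask
#'
#' A voxel enters the group mask if it appears in at least `group_threshold`
#' of the individual masks; the default 1 is the inclusive-OR union.
#'
#' @param masks List of logical arrays on a shared grid.
#' @param group_threshold Minimum number of masks a voxel must appear in.
#' @return Logical array.
#' @export
union_mask <- function(masks, group_threshold = 1) {
  stopifnot(length(masks) >= 1, group_threshold >= 1)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!isTRUE(all(dim(m) == d))) stop("masks are not on a shared grid")
  counts <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  counts >= group_threshold
}

#' Spherical seed mask around a peak voxel
#'
#' All voxels whose center-to-center Euclidean distance from the peak voxel is
#' at most `radius_mm`, intersected with a constraint mask (e.g. the target
#' ROI or an atlas region).
#'
#' @param peak Integer voxel coordinate (i, j, k), 1-based.
#' @param radius_mm Sphere radius in mm (default 6).
#' @param constraint Logical array; the peak must lie inside it.
#' @param vox_mm Voxel size in mm per axis.
#' @return Logical array.
#' @export
sphere_seed <- function(peak, radius_mm = 6, constraint,
                        vox_mm = c(3, 3, 3)) {
  stopifnot(length(peak) == 3, radius_mm > 0)
  d <- dim(constraint)
  if (any(peak < 1) || any(peak > d)) stop("peak outside the grid")
  if (!constraint[peak[1], peak[2], peak[3]])
    stop("peak voxel lies outside the constraint mask")
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  dist2 <- ((idx[, 1] - peak[1]) * vox_mm[1])^2 +
           ((idx[, 2] - peak[2]) * vox_mm[2])^2 +
           ((idx[, 3] - peak[3]) * vox_mm[3])^2
  sph <- array(dist2 <= radius_mm^2 + 1e-9, d)
  sph & constraint
}

#' Isotropic Gaussian smoothing of a 3-D volume
#'
#' Separable Gaussian filter with the kernel width given as full width at
#' half maximum in mm; used before group-level GLMs, never in the real-time
#' path.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Full width at half maximum in mm.
#' @param vox_mm Voxel size in mm per axis.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm = 8, vox_mm = c(3, 3, 3)) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox_mm
  out <- volume
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-6) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    out <- apply_along(out, axis, function(x) {
      n <- length(x)
      xp <- c(rep(x[1], half), x, rep(x[n], half))
      stats::convolve(xp, rev(k), type = "filter")
    })
  }
  out
}

# apply a length-preserving function along one axis of a 3-D array
apply_along <- function(arr, axis, f) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  m <- apply(m, 2, f)
  aperm(array(m, d[perm]), order(perm))
}

#' Functional-localizer ROI selection from a run
#'
#' Convenience wrapper: fits the localizer GLM (active-versus-rest contrast
#' with intercept and linear drift) over all voxels of a run and thresholds
#' the contrast t-map.
#'
#' @param run An `nf_run` whose design alternates rest and an active kind.
#' @param active_kind Active block kind (default "clench").
#' @param hrf [hrf_params()].
#' @param t_threshold,anatomical_mask Passed to [select_roi()].
#' @return List with `mask` (logical array), `tmap` (array) and `fit`.
#' @export
localize_roi <- function(run, active_kind = "clench", hrf = hrf_params(),
                         t_threshold = 3, anatomical_mask = NULL) {
  Y <- t(matrix(run$bold, ncol = run$design$n_volumes))
  reg <- convolve_design(run$design, active_kind, hrf)
  times <- (seq_len(run$design$n_volumes) - 1) * run$tr
  X <- cbind(intercept = 1, active = reg, drift = scale(times, scale = FALSE))
  fit <- fit_glm(Y, X)
  con <- glm_contrast(fit, c(0, 1, 0))
  tmap <- array(con$t, dim = run$grid$dim)
  mask <- suppressWarnings(select_roi(tmap, t_threshold, anatomical_mask))
  list(mask = mask, tmap = tmap, fit = fit)
}
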