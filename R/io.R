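#' Write / read a block design as a BIDS-style events table
#'
#' Tab-separated file with columns `onset`, `duration`, `trial_type`.
#'
#' @param design A [block_design()].
#' @param path Output path (.tsv).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "block_design"))
  df <- data.frame(onset = design$blocks$onset,
                   duration = design$blocks$duration,
                   trial_type = design$blocks$kind)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param tr Repetition time of the reconstructed design.
#' @export
read_events_tsv <- function(path, tr = 1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  block_design(data.frame(kind = df$trial_type, onset = df$onset,
                          duration = df$duration), tr = tr)
}

#' Write / read a motion-parameter table
#'
#' Tab-separated, six columns per volume: three translations in mm, three
#' rotations in radians.
#'
#' @param motion Volumes x 6 matrix.
#' @param path Output path (.tsv).
#' @return `path` invisibly; the reader returns the matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(as.data.frame(motion), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Write a simulated run's volumes as NIfTI-1
#'
#' @param run An `nf_run`.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_run_nifti <- function(run, path) {
  img <- RNifti::asNifti(run$bold, pixdim = c(run$grid$vox_mm, run$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D or 4-D NIfTI image as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_nifti_array <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a binary mask as NIfTI-1
#'
#' @param mask Logical 3-D array.
#' @param path Output path.
#' @param vox_mm Voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path, vox_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                         pixdim = vox_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' The ROI is stored as 1-based linear voxel indices plus the grid
#' dimensions, so the truth file is plain text and self-describing.
#'
#' @param truth A [simulation_truth()].
#' @param path Output path (.json).
#' @return `path` invisibly; the reader returns a `simulation_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  obj <- list(dim = dim(truth$roi_mask),
              roi_voxels = which(truth$roi_mask),
              base_amplitude = truth$base_amplitude,
              learning_slope = truth$learning_slope,
              ar_coefficient = truth$ar_coefficient,
              noise_sd = truth$noise_sd, drift_slope = truth$drift_slope,
              spike_times = truth$spike_times,
              spike_magnitude = truth$spike_magnitude)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- array(FALSE, obj$dim)
  mask[obj$roi_voxels] <- TRUE
  simulation_truth(mask, base_amplitude = obj$base_amplitude,
                   learning_slope = obj$learning_slope,
                   ar_coefficient = obj$ar_coefficient,
                   noise_sd = obj$noise_sd, drift_slope = obj$drift_slope,
                   spike_times = obj$spike_times,
                   spike_magnitude = obj$spike_magnitude)
}

#' Write a feedback trace and its per-block summary as CSV
#'
#' @param trace A `feedback_trace` from [run_feedback()].
#' @param trace_path,blocks_path Output CSV paths (blocks optional).
#' @return `trace_path`, invisibly.
#' @export
write_trace_csv <- function(trace, trace_path, blocks_path = NULL) {
  stopifnot(inherits(trace, "feedback_trace"))
  utils::write.csv(trace$trace, trace_path, row.names = FALSE)
  if (!is.null(blocks_path))
    utils::write.csv(trace$blocks, blocks_path, row.names = FALSE)
  invisible(trace_path)
}
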