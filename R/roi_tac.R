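#' Region label dictionary
#'
#' Integer labels of the single label volume used throughout the
#' pipeline: 0 background, 1 WMH (white matter hyperintensity), 2 NAWM
#' (normal-appearing white matter), 3 striatum, 4 infarct, 5 segmented
#' white matter.
#'
#' @return Named integer vector.
#' @export
roi_labels <- function() {
  c(background = 0L, WMH = 1L, NAWM = 2L, striatum = 3L, infarct = 4L,
    WM_segmentation = 5L)
}

check_same_grid <- function(a, b) {
  stop_if_not(identical(dim(a), dim(b)), "grid mismatch between volumes")
}

#' Derive the NAWM mask
#'
#' Normal-appearing white matter is defined by subtracting WMH voxels
#' from the segmented white matter: \eqn{NAWM = WM \wedge \neg WMH}.
#' Optionally infarct voxels are removed as well (default), so that
#' infarcted tissue contaminates neither lesion nor normal tissue.
#' The result is always disjoint from the WMH mask.
#'
#' @param wm_mask,wmh_mask Logical/0-1 arrays on a common grid.
#' @param infarct_mask Optional mask to subtract too.
#' @return Logical array: the NAWM mask.
#' @export
derive_nawm <- function(wm_mask, wmh_mask, infarct_mask = NULL) {
  check_same_grid(wm_mask, wmh_mask)
  nawm <- (wm_mask != 0) & !(wmh_mask != 0)
  if (!is.null(infarct_mask)) {
    check_same_grid(wm_mask, infarct_mask)
    nawm <- nawm & !(infarct_mask != 0)
  }
  stopifnot(!any(nawm & (wmh_mask != 0)))  # disjointness, asserted per run
  nawm
}

#' Time-activity curve container
#'
#' @param values Frame activities (kBq/mL), one per frame.
#' @param schedule `frame_schedule`.
#' @param roi_label ROI name.
#' @param weights Fit weights; default duration-decay ([tac_weights()]).
#' @return Object of class `time_activity_curve`.
#' @export
time_activity_curve <- function(values, schedule, roi_label = "ROI",
                                weights = NULL) {
  stop_if_not(length(values) == nrow(schedule),
              "values length must equal the number of frames")
  if (is.null(weights)) weights <- tac_weights(schedule)
  stop_if_not(length(weights) == length(values) && all(weights >= 0) &&
                any(weights > 0), "invalid weights")
  structure(list(roi_label = roi_label, schedule = schedule,
                 values = as.numeric(values), weights = weights),
            class = "time_activity_curve")
}

#' Extract a regional time-activity curve from a dynamic image
#'
#' Each frame value is the mean over the mask voxels of that frame.
#'
#' @param dynamic_image 4-D array (x, y, z, frame).
#' @param mask Logical/0-1 3-D array on the same grid.
#' @param schedule `frame_schedule`; frame count must match the image.
#' @param roi_label Name carried on the returned TAC.
#' @param weights Optional fit weights.
#' @return A `time_activity_curve`.
#' @export
extract_tac <- function(dynamic_image, mask, schedule, roi_label = "ROI",
                        weights = NULL) {
  d <- dim(dynamic_image)
  stop_if_not(length(d) == 4, "dynamic_image must be 4-D")
  stop_if_not(identical(d[1:3], dim(mask)), "grid mismatch between image and mask")
  stop_if_not(d[4] == nrow(schedule), "frame count does not match schedule")
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("empty ROI", call. = FALSE)
  nvox <- prod(d[1:3])
  m <- matrix(dynamic_image, nrow = nvox, ncol = d[4])
  time_activity_curve(colMeans(m[idx, , drop = FALSE]), schedule,
                      roi_label = roi_label, weights = weights)
}

#' Mean regional CBF
#'
#' Mean of a cerebral blood flow map (mL/100 g/min) over a mask.
#'
#' @param cbf_map 3-D array.
#' @param mask Logical/0-1 array on the same grid.
#' @return Mean CBF over the mask.
#' @export
regional_cbf <- function(cbf_map, mask) {
  check_same_grid(cbf_map, mask)
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("empty ROI", call. = FALSE)
  mean(cbf_map[idx])
}

#' Voxelwise group frequency map
#'
#' Counts, per voxel, how many subjects carry a given label, producing
#' the group frequency maps used to display WMH/NAWM overlap.
#'
#' @param masks List of label volumes (or binary masks) on a common grid.
#' @param label Integer label to count; if `NULL`, masks are treated as
#'   binary.
#' @return Integer array of per-voxel counts (max = number of subjects).
#' @export
frequency_map <- function(masks, label = NULL) {
  stop_if_not(length(masks) >= 1, "need at least one mask")
  d <- dim(masks[[1]])
  out <- array(0L, d)
  for (m in masks) {
    check_same_grid(masks[[1]], m)
    out <- out + if (is.null(label)) (m != 0) else (m == label)
  }
  out
}

#' Read / write 3-D and 4-D NIfTI volumes
#'
#' Thin wrappers over RNifti used by the pipeline; data are returned as
#' plain arrays.
#'
#' @param path NIfTI file path.
#' @return `read_volume()`: numeric array.
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim(v))
}

#' @rdname read_volume
#' @param x Array to write.
#' @param pixdim Voxel dimensions.
#' @export
write_volume <- function(x, path, pixdim = rep(1, min(length(dim(x)), 3))) {
  img <- RNifti::asNifti(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a frame-timing table
#'
#' CSV with columns `start` and `duration` (minutes), one row per frame.
#'
#' @param path CSV path.
#' @return A `frame_schedule`.
#' @export
read_frame_schedule <- function(path) {
  df <- utils::read.csv(path)
  stop_if_not(all(c("start", "duration") %in% names(df)),
              "frame table needs start and duration columns")
  stop_if_not(all(df$duration > 0), "durations must be positive")
  stop_if_not(max(abs(df$start - c(0, cumsum(df$duration)[-nrow(df)]))) < 1e-9,
              "frames must be contiguous from t = 0")
  sched <- build_frame_schedule(Map(c, rep(1, nrow(df)), df$duration))
  sched
}

#' Write a frame schedule as CSV
#' @param schedule `frame_schedule`.
#' @param path Output CSV.
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(start = schedule$start,
                              duration = schedule$duration),
                   path, row.names = FALSE)
  invisible(path)
}
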