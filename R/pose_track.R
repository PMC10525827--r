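#' Pose track container
#'
#' A `pose_track` holds the per-frame output of markerless pose estimation
#' for one trial: for every labelled body part an x coordinate, a y
#' coordinate (pixels, image convention with y increasing downward) and a
#' tracking likelihood in \[0, 1\]. Frames are indexed from 0, matching the
#' first column of the pose CSV dialect. A cell is *missing* when its
#' coordinates are `NA`; missing cells always carry likelihood 0.
#'
#' @param trial_id character scalar identifying the trial.
#' @param x,y numeric matrices (frames x body parts) with identical
#'   dimnames; column names are the body-part labels.
#' @param likelihood numeric matrix of the same shape, values in \[0, 1\].
#' @param frame_rate frames per second (default 50).
#'
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(trial_id, x, y, likelihood, frame_rate = 50) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (is.null(colnames(y))) colnames(y) <- colnames(x)
  if (is.null(colnames(likelihood))) colnames(likelihood) <- colnames(x)
  obj <- structure(
    list(trial_id = as.character(trial_id),
         frame_rate = frame_rate,
         x = x, y = y, likelihood = likelihood),
    class = "pose_track")
  validate_pose_track(obj)
  obj
}

#' Validate a pose track
#'
#' Checks the structural invariants: matching dimensions across the x, y
#' and likelihood matrices, likelihoods in \[0, 1\], finite coordinates
#' wherever a cell is not missing, and likelihood 0 on every missing cell.
#' On violation the error names the offending body part and (0-based)
#' frame.
#'
#' @param track a `pose_track`.
#' @return `track`, invisibly.
#' @export
validate_pose_track <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  x <- track$x; y <- track$y; lik <- track$likelihood
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(lik)))
    stop("pose_track: x, y and likelihood must have identical dimensions")
  if (is.null(colnames(x)) || any(colnames(x) == ""))
    stop("pose_track: body-part labels (column names) are required")
  if (anyDuplicated(colnames(x)))
    stop("pose_track: duplicated body-part labels")
  if (!(is.numeric(track$frame_rate) && track$frame_rate > 0))
    stop("pose_track: frame_rate must be a positive number")
  miss <- is.na(x) | is.na(y)
  bad <- which(!is.na(lik) & (lik < 0 | lik > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("pose_track '%s': likelihood outside [0,1] for label '%s' at frame %d",
                 track$trial_id, colnames(x)[bad[1, 2]], bad[1, 1] - 1L))
  if (any(is.na(lik)))
    stop("pose_track: likelihood must not be NA (use 0 for missing cells)")
  nf <- which(!miss & (!is.finite(x) | !is.finite(y)), arr.ind = TRUE)
  if (nrow(nf) > 0)
    stop(sprintf("pose_track '%s': non-finite coordinate for label '%s' at frame %d",
                 track$trial_id, colnames(x)[nf[1, 2]], nf[1, 1] - 1L))
  badlik <- which(miss & lik != 0, arr.ind = TRUE)
  if (nrow(badlik) > 0)
    stop(sprintf("pose_track '%s': missing cell with non-zero likelihood for label '%s' at frame %d",
                 track$trial_id, colnames(x)[badlik[1, 2]], badlik[1, 1] - 1L))
  invisible(track)
}

#' Number of frames in a pose track
#' @param track a `pose_track`.
#' @return integer frame count.
#' @export
n_frames <- function(track) nrow(track$x)

#' Body-part labels of a pose track
#' @param track a `pose_track`.
#' @return character vector of labels.
#' @export
part_labels <- function(track) colnames(track$x)

#' Missing mask of a pose track
#' @param track a `pose_track`.
#' @return logical matrix (frames x labels); `TRUE` where the cell is missing.
#' @export
missing_mask <- function(track) is.na(track$x) | is.na(track$y)

#' Mask cells of a pose track
#'
#' Sets the given (label, frame) cells to missing: coordinates become `NA`
#' and the likelihood is set to 0. Idempotent.
#'
#' @param track a `pose_track`.
#' @param label body-part label (scalar) or a vector parallel to `frames`.
#' @param frames 0-based frame indices.
#' @return the modified `pose_track`.
#' @export
mask_cells <- function(track, label, frames) {
  if (length(frames) == 0) return(track)
  if (length(label) == 1) label <- rep(label, length(frames))
  stopifnot(length(label) == length(frames))
  if (!all(label %in% part_labels(track)))
    stop("mask_cells: unknown label(s): ",
         paste(setdiff(label, part_labels(track)), collapse = ", "))
  if (any(frames < 0 | frames >= n_frames(track)))
    stop("mask_cells: frame index out of range for trial '", track$trial_id, "'")
  idx <- cbind(frames + 1L, match(label, part_labels(track)))
  track$x[idx] <- NA_real_
  track$y[idx] <- NA_real_
  track$likelihood[idx] <- 0
  track
}

#' @method print pose_track
#' @export
print.pose_track <- function(x, ...) {
  miss <- missing_mask(x)
  cat(sprintf("<pose_track '%s'>\n", x$trial_id))
  cat(sprintf("  %d frames @ %g fps (%.1f s), %d body parts\n",
              n_frames(x), x$frame_rate, n_frames(x) / x$frame_rate,
              length(part_labels(x))))
  cat("  parts: ", paste(part_labels(x), collapse = ", "), "\n", sep = "")
  cat(sprintf("  missing cells: %d (%.2f%%)\n", sum(miss),
              if (length(miss)) 100 * mean(miss) else 0))
  invisible(x)
}

#' @method summary pose_track
#' @export
summary.pose_track <- function(object, ...) {
  miss <- missing_mask(object)
  data.frame(
    label = part_labels(object),
    n_frames = n_frames(object),
    missing = colSums(miss),
    missing_fraction = if (nrow(miss)) colMeans(miss) else 0,
    mean_likelihood = colMeans(object$likelihood),
    row.names = NULL)
}

#' @method all.equal pose_track
#' @export
all.equal.pose_track <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}
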