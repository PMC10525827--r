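#' Likelihood cutoff filter
#'
#' Masks every tracked point whose likelihood falls below the cutoff,
#' the first quality-control step before any kinematic parameter is
#' computed. The default cutoff is 0.75. A point with likelihood exactly
#' equal to the cutoff is retained (masking applies to `likelihood <
#' cutoff`).
#'
#' @param track a [pose_track].
#' @param cutoff numeric in \[0, 1\].
#' @return list with elements `track` (the filtered [pose_track]) and
#'   `report` (a QC data.frame, one row per label: frames masked by the
#'   cutoff, frames masked as outliers — 0 here —, and the total missing
#'   fraction after masking).
#' @export
apply_likelihood_cutoff <- function(track, cutoff = 0.75) {
  validate_pose_track(track)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1)
    stop("apply_likelihood_cutoff: cutoff must be a number in [0, 1]")
  already <- missing_mask(track)
  low <- !already & track$likelihood < cutoff
  track$x[low] <- NA_real_
  track$y[low] <- NA_real_
  track$likelihood[low] <- 0
  list(track = track,
       report = qc_report(track, masked_likelihood = colSums(low)))
}

qc_report <- function(track, masked_likelihood = 0, masked_outlier = 0) {
  miss <- missing_mask(track)
  data.frame(label = part_labels(track),
             n_frames = n_frames(track),
             masked_likelihood = masked_likelihood,
             masked_outlier = masked_outlier,
             missing_fraction = if (nrow(miss)) colMeans(miss) else 0,
             row.names = NULL)
}

#' Flag outlier frames
#'
#' The labelled data cluster of each body part is screened in x-y space.
#' Two rules are available: a verbatim manual exclusion list (mirroring
#' visual screening of the video), and an automated robust-distance
#' screen that flags frames whose position lies further than `k` robust
#' standard deviations (median/MAD of the distance to the label's spatial
#' median) from that median. When the MAD is 0 — a perfectly stationary
#' label, as reference points can be — no automatic flags are raised.
#' Flags are advisory until passed to [apply_exclusions].
#'
#' @param track a [pose_track].
#' @param rule "robust" or "manual".
#' @param k robust-SD multiplier for the automatic screen (default 6).
#' @param manual data.frame with columns `label` and `frame` (0-based)
#'   for `rule = "manual"`.
#' @param labels labels to screen; default all.
#' @return data.frame with columns `label`, `frame` (0-based).
#' @export
flag_outliers <- function(track, rule = c("robust", "manual"), k = 6,
                          manual = NULL, labels = part_labels(track)) {
  rule <- match.arg(rule)
  if (rule == "manual") {
    if (is.null(manual) || !all(c("label", "frame") %in% names(manual)))
      stop("flag_outliers: rule 'manual' needs a data.frame with columns label, frame")
    bad <- manual$frame < 0 | manual$frame >= n_frames(track)
    if (any(bad))
      stop("flag_outliers: manual frame index out of range: ",
           paste(manual$frame[bad], collapse = ", "))
    if (!all(manual$label %in% part_labels(track)))
      stop("flag_outliers: unknown label in manual list")
    return(data.frame(label = as.character(manual$label),
                      frame = as.integer(manual$frame)))
  }
  if (!is.numeric(k) || k <= 0) stop("flag_outliers: k must be positive")
  out <- list()
  for (lab in labels) {
    x <- track$x[, lab]; y <- track$y[, lab]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    mx <- stats::median(x[ok]); my <- stats::median(y[ok])
    r <- sqrt((x - mx)^2 + (y - my)^2)
    s <- stats::mad(r[ok], center = stats::median(r[ok]))
    if (s == 0) next  # stationary cluster: no automatic flags
    thr <- stats::median(r[ok]) + k * s
    fl <- which(ok & r > thr)
    if (length(fl))
      out[[lab]] <- data.frame(label = lab, frame = fl - 1L)
  }
  if (!length(out)) return(data.frame(label = character(), frame = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply outlier exclusions
#'
#' Turns flagged (label, frame) cells into missing cells. Idempotent:
#' applying the same flag set twice equals applying it once.
#'
#' @param track a [pose_track].
#' @param flags data.frame with columns `label`, `frame` as produced by
#'   [flag_outliers].
#' @return the filtered [pose_track].
#' @export
apply_exclusions <- function(track, flags) {
  if (is.null(flags) || nrow(flags) == 0) return(track)
  mask_cells(track, flags$label, flags$frame)
}
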