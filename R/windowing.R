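#' Segment a trial into 30-s analysis intervals
#'
#' Derives the interval grid of the windowed analysis from a trial
#' design. Each interval spans `round(interval_s * frame_rate)` frames
#' (1500 frames for the standard 30 s at 50 fps). For each stimulus, four
#' post-stimulus intervals (0-30, 30-60, 60-90, 90-120 s) start at the
#' release frame — the moment the clamp is no longer in contact with the
#' beak — and pre-stimulus intervals are tiled backward from the onset
#' frame across the baseline period (four tiles for a 120 s baseline).
#'
#' @param design a [trial_design].
#' @param frame_rate frames per second.
#' @param n_frames total frames in the recording, used to reject post
#'   windows that extend past the end.
#' @param interval_s interval length in seconds (default 30).
#' @return data.frame with columns `stimulus` ("Pinch"/"Touch"), `window`
#'   ("Baseline"/"Post"), `interval` (label such as "-30-0" or "0-30"),
#'   `start_frame`, `end_frame` (0-based, end exclusive).
#' @export
segment_intervals <- function(design, frame_rate, n_frames, interval_s = 30) {
  stopifnot(inherits(design, "trial_design"))
  L <- as.integer(round(interval_s * frame_rate))
  n_pre <- as.integer(floor(design$baseline_duration / interval_s))
  n_post <- as.integer(floor(design$post_duration / interval_s))
  rows <- list()
  for (i in seq_len(nrow(design$stimuli))) {
    kind <- design$stimuli$kind[i]
    onset <- design$stimuli$onset_frame[i]
    release <- design$stimuli$release_frame[i]
    pre_start <- onset - L * (n_pre:1)
    if (any(pre_start < 0))
      stop(sprintf("segment_intervals: baseline window of trial '%s' (%s) starts before frame 0",
                   design$embryo_id, kind))
    post_start <- release + L * (0:(n_post - 1))
    if (max(post_start) + L > n_frames)
      stop(sprintf("segment_intervals: post-stimulus window of trial '%s' (%s) extends past the last frame",
                   design$embryo_id, kind))
    pre_lab <- sprintf("%d-%d", -interval_s * (n_pre:1), -interval_s * ((n_pre:1) - 1))
    post_lab <- sprintf("%d-%d", interval_s * (0:(n_post - 1)), interval_s * (1:n_post))
    rows[[i]] <- data.frame(
      stimulus = kind,
      window = rep(c("Baseline", "Post"), c(n_pre, n_post)),
      interval = c(pre_lab, post_lab),
      start_frame = c(pre_start, post_start),
      end_frame = c(pre_start, post_start) + L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval exclusion rule
#'
#' An interval is excluded from the analysis when more than 5% of its
#' values are missing, counted before imputation. "More than" is strict:
#' at 1500 frames, 75 missing (exactly 5%) is retained and 76 is
#' excluded.
#'
#' @param values raw (pre-imputation) interval values, NA = missing.
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @return logical: `TRUE` if the interval is excluded.
#' @export
is_interval_excluded <- function(values, max_missing = 0.05) {
  sum(is.na(values)) > max_missing * length(values)
}

#' Median imputation of tracking dropouts
#'
#' Fills each contiguous missing run using the median of half as many
#' adjacent observed values as the run is long: a run of length g is
#' filled with one constant, the median of the k = max(1, ceiling(g/2))
#' nearest observed values on each side, pooled (at most 2k values;
#' one-sided at the interval edges). Neighbours are always observed
#' values from the raw series — fills never feed later fills. Observed
#' values are never altered, and no missing value remains afterwards.
#'
#' @param values numeric interval values with NA for missing.
#' @return the imputed numeric vector.
#' @export
impute_interval <- function(values) {
  miss <- is.na(values)
  if (!any(miss)) return(values)
  if (all(miss))
    stop("impute_interval: interval has no observed values; it must be excluded, not imputed")
  obs_idx <- which(!miss)
  obs_val <- values[obs_idx]
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    s <- starts[j]; g <- r$lengths[j]
    k <- max(1L, as.integer(ceiling(g / 2)))
    left <- obs_val[obs_idx < s]
    right <- obs_val[obs_idx > s + g - 1L]
    pool <- c(utils::tail(left, k), utils::head(right, k))
    values[s:(s + g - 1L)] <- stats::median(pool)
  }
  values
}

#' Interval sum
#'
#' The per-interval statistic: the arithmetic sum of the (imputed)
#' per-frame values of one 30-s interval — total pixels travelled for
#' movement-type parameters, summed gap or angle for the beak parameters.
#'
#' @param values imputed interval values (no NA).
#' @return numeric sum.
#' @export
interval_sum <- function(values) {
  if (anyNA(values))
    stop("interval_sum: interval still contains missing values; impute or exclude first")
  sum(values)
}

#' Baseline statistic
#'
#' The baseline of a stimulus is the median of the sums of the four 30-s
#' intervals immediately preceding it. Excluded intervals are dropped
#' from the median; if all four are excluded the baseline is missing
#' (`NA`).
#'
#' @param sums numeric vector of pre-stimulus interval sums (NA where the
#'   interval was excluded).
#' @param excluded optional logical vector marking excluded intervals;
#'   defaults to `is.na(sums)`.
#' @return the baseline value, or `NA` if no interval survives.
#' @export
baseline_value <- function(sums, excluded = is.na(sums)) {
  keep <- sums[!excluded & !is.na(sums)]
  if (!length(keep)) return(NA_real_)
  stats::median(keep)
}

series_interval_values <- function(series, start_frame, end_frame) {
  # frame f lives at vector index f + 1; a step series entry at index
  # f + 1 is the displacement between frames f and f + 1, attributed to
  # the interval containing its first frame. The final step of the
  # recording's last interval may not exist and is simply absent.
  idx <- (start_frame + 1L):end_frame
  idx <- idx[idx <= length(series$values)]
  series$values[idx]
}

#' Windowed interval summary
#'
#' Runs the full windowed aggregation for one kinematic series: segments
#' the recording per [segment_intervals], applies the >5% missingness
#' exclusion rule (pre-imputation), imputes surviving intervals with
#' [impute_interval], sums them, and appends one "BL" row per stimulus
#' carrying the baseline statistic (median of the four pre-stimulus
#' interval sums, [baseline_value]).
#'
#' @param series a [kinematic_series].
#' @param design a [trial_design].
#' @param frame_rate frames per second of the source track.
#' @param interval_s interval length in seconds (default 30).
#' @param max_missing exclusion threshold on the missing fraction
#'   (default 0.05).
#' @return an `interval_summary` data.frame: one row per trial x
#'   parameter x window x interval with columns `trial_id`, `parameter`,
#'   `stimulus`, `window`, `interval`, `sum`, `missing_fraction`,
#'   `excluded`. Baseline rows have `window = "Baseline"`, `interval =
#'   "BL"`.
#' @export
interval_summary <- function(series, design, frame_rate, interval_s = 30,
                             max_missing = 0.05) {
  stopifnot(inherits(series, "kinematic_series"))
  nf <- length(series$values) + (series$series_type == "step")
  seg <- segment_intervals(design, frame_rate, nf, interval_s = interval_s)
  res <- seg[c("stimulus", "window", "interval")]
  res$sum <- NA_real_
  res$missing_fraction <- NA_real_
  res$excluded <- FALSE
  for (i in seq_len(nrow(seg))) {
    v <- series_interval_values(series, seg$start_frame[i], seg$end_frame[i])
    mf <- mean(is.na(v))
    res$missing_fraction[i] <- mf
    if (is_interval_excluded(v, max_missing) || all(is.na(v))) {
      res$excluded[i] <- TRUE
    } else {
      res$sum[i] <- interval_sum(impute_interval(v))
    }
  }
  bl <- lapply(unique(res$stimulus), function(st) {
    pre <- res[res$stimulus == st & res$window == "Baseline", ]
    pre <- utils::tail(pre, 4L)  # the four intervals immediately before onset
    b <- baseline_value(pre$sum, pre$excluded)
    data.frame(stimulus = st, window = "Baseline", interval = "BL",
               sum = b, missing_fraction = NA_real_, excluded = is.na(b))
  })
  out <- rbind(res, do.call(rbind, bl))
  out <- cbind(trial_id = series$trial_id, parameter = series$parameter, out)
  rownames(out) <- NULL
  class(out) <- c("interval_summary", "data.frame")
  out
}

#' Combine interval summaries across trials
#'
#' @param ... `interval_summary` data.frames (or a single list of them).
#' @return one combined `interval_summary` data.frame.
#' @export
bind_interval_summaries <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  out <- do.call(rbind, lapply(args, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("interval_summary", "data.frame")
  out
}
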