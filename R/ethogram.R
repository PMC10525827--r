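#' The beak-movement ethogram
#'
#' Closed set of manually scored beak behaviors: *BeakShift* (small
#' horizontal shift of the beak halves against each other),
#' *Mandibulation* (small repeated vertical opening, chewing-like),
#' *BeakOpening* (single swift vertical opening) and *WideBeakOpening*
#' (single wide vertical opening with a characteristic tongue movement).
#'
#' @return character vector of valid behavior names.
#' @export
ethogram_behaviors <- function() {
  c("BeakShift", "Mandibulation", "BeakOpening", "WideBeakOpening")
}

#' Read behavior annotations
#'
#' Reads a CSV of manually scored behavior events with columns
#' `trial_id`, `behavior`, `frame` (0-based frame stamp). Behavior names
#' must come from the closed ethogram set.
#'
#' @param path annotation CSV path.
#' @return data.frame of validated events.
#' @export
read_annotations <- function(path) {
  ev <- utils::read.csv(path, colClasses = c(trial_id = "character",
                                             behavior = "character",
                                             frame = "integer"))
  validate_annotations(ev)
}

#' @rdname read_annotations
#' @param events data.frame with columns `trial_id`, `behavior`, `frame`.
#' @export
validate_annotations <- function(events) {
  need <- c("trial_id", "behavior", "frame")
  if (!all(need %in% names(events)))
    stop("annotations need columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(events$behavior), ethogram_behaviors())
  if (length(bad))
    stop("unknown behavior(s) ", paste(sQuote(bad), collapse = ", "),
         "; valid behaviors are: ", paste(ethogram_behaviors(), collapse = ", "))
  if (nrow(events) && any(events$frame < 0))
    stop("annotations: negative frame stamp")
  events
}

#' Responder percentage
#'
#' Share of embryos in a group showing at least one event, as a
#' percentage rounded half-away-from-zero to one decimal (13/16 gives
#' 81.3, 3/16 gives 18.8, 1/16 gives 6.3).
#'
#' @param n_responders embryos with at least one event.
#' @param n group size.
#' @return numeric percentage with one decimal.
#' @export
responder_percentage <- function(n_responders, n) {
  p <- 100 * n_responders / n
  sign(p) * floor(abs(p) * 10 + 0.5) / 10
}

#' Tally behavior events into the responder table
#'
#' Assigns each annotated event to an analysis window of its trial and
#' tallies per group x stimulus x window x interval x behavior: the event
#' count, the responder count (embryos with >= 1 event) and the responder
#' percentage. For manual observations the baseline is the single 30-s
#' interval immediately before the stimulus onset; the post window has
#' four 30-s intervals starting at the release frame (the 0-30 s column
#' is the one reported in responder overview tables). Events falling
#' outside every window are not counted; they are returned in the
#' `unassigned` attribute.
#'
#' @param events annotation data.frame (see [read_annotations]).
#' @param designs named list of [trial_design] objects covering every
#'   trial in `events`.
#' @param frame_rate frames per second (default 50).
#' @param n_by_group optional named vector of group sizes; defaults to
#'   the number of designs per group. Group labels are "ED<d>" with the
#'   design's group tag appended when it is not "plain".
#' @param interval_s interval length in seconds (default 30).
#' @return a `behavior_tally` data.frame with columns `group`,
#'   `stimulus`, `window`, `interval`, `behavior`, `n_events`,
#'   `n_responders`, `n`, `responder_pct`.
#' @export
tally_behaviors <- function(events, designs, frame_rate = 50,
                            n_by_group = NULL, interval_s = 30) {
  events <- validate_annotations(events)
  miss <- setdiff(unique(events$trial_id), names(designs))
  if (length(miss))
    stop("tally_behaviors: no design for trial(s) ", paste(miss, collapse = ", "))
  group_of <- function(d)
    paste0("ED", d$embryonic_day,
           if (d$group != "plain") paste0(" ", d$group) else "")
  groups <- vapply(designs, group_of, "")
  if (is.null(n_by_group))
    n_by_group <- table(groups)
  L <- as.integer(round(interval_s * frame_rate))
  # window table: one baseline interval + four post intervals per stimulus
  win <- do.call(rbind, lapply(names(designs), function(id) {
    d <- designs[[id]]
    do.call(rbind, lapply(seq_len(nrow(d$stimuli)), function(i) {
      onset <- d$stimuli$onset_frame[i]; release <- d$stimuli$release_frame[i]
      n_post <- as.integer(floor(d$post_duration / interval_s))
      data.frame(trial_id = id, group = groups[[id]],
                 stimulus = d$stimuli$kind[i],
                 window = c("Baseline", rep("Post", n_post)),
                 interval = c("-30-0", sprintf("%d-%d",
                                               interval_s * (0:(n_post - 1)),
                                               interval_s * (1:n_post))),
                 start = c(onset - L, release + L * (0:(n_post - 1))))
    }))
  }))
  win$end <- win$start + L
  assigned <- rep(FALSE, nrow(events))
  rows <- list()
  for (i in seq_len(nrow(win))) {
    hit <- events$trial_id == win$trial_id[i] &
      events$frame >= win$start[i] & events$frame < win$end[i]
    assigned <- assigned | hit
    if (!any(hit)) next
    ev <- events[hit, ]
    agg <- stats::aggregate(list(n_events = ev$frame),
                            by = list(behavior = ev$behavior), FUN = length)
    resp <- stats::aggregate(list(n_responders = ev$trial_id),
                             by = list(behavior = ev$behavior),
                             FUN = function(z) length(unique(z)))
    m <- merge(agg, resp, by = "behavior")
    m$trial_id <- win$trial_id[i]
    m$group <- win$group[i]; m$stimulus <- win$stimulus[i]
    m$window <- win$window[i]; m$interval <- win$interval[i]
    rows[[length(rows) + 1]] <- m
  }
  cells <- expand.grid(behavior = ethogram_behaviors(),
                       key = unique(paste(win$group, win$stimulus, win$window,
                                          win$interval, sep = "\r")),
                       stringsAsFactors = FALSE)
  key_parts <- do.call(rbind, strsplit(cells$key, "\r", fixed = TRUE))
  cells$group <- key_parts[, 1]; cells$stimulus <- key_parts[, 2]
  cells$window <- key_parts[, 3]; cells$interval <- key_parts[, 4]
  cells$key <- NULL
  if (length(rows)) {
    per_trial <- do.call(rbind, rows)
    agg2 <- stats::aggregate(
      cbind(n_events, n_responders) ~ group + stimulus + window + interval + behavior,
      data = per_trial, FUN = sum)
  } else {
    agg2 <- cbind(cells[0, ], n_events = integer(), n_responders = integer())
  }
  out <- merge(cells, agg2,
               by = c("group", "stimulus", "window", "interval", "behavior"),
               all.x = TRUE)
  out$n_events[is.na(out$n_events)] <- 0L
  out$n_responders[is.na(out$n_responders)] <- 0L
  out$n <- as.integer(n_by_group[out$group])
  out$responder_pct <- responder_percentage(out$n_responders, out$n)
  ord <- order(out$group, out$stimulus, out$window, out$interval, out$behavior)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "unassigned") <- events[!assigned, , drop = FALSE]
  class(out) <- c("behavior_tally", "data.frame")
  out
}

#' Wide responder table
#'
#' Reshapes a behavior tally into the conventional overview layout: one
#' row per behavior x window, responder percentages across group x
#' stimulus columns, restricted to the single baseline interval and the
#' 0-30 s post interval.
#'
#' @param tally a `behavior_tally` from [tally_behaviors].
#' @param post_interval which post interval to report (default "0-30",
#'   the column conventionally shown in responder overview tables).
#' @return a wide data.frame of responder percentages.
#' @export
tally_wide <- function(tally, post_interval = "0-30") {
  keep <- tally[(tally$window == "Baseline") |
                  (tally$window == "Post" & tally$interval == post_interval), ]
  keep$col <- paste(keep$group, keep$stimulus)
  stats::reshape(keep[c("behavior", "window", "col", "responder_pct")],
                 idvar = c("behavior", "window"), timevar = "col",
                 direction = "wide")
}

#' Candidate beak-opening detector
#'
#' Advisory helper that proposes annotation candidates from the
#' beak-distance series: frames where the series crosses `threshold`
#' upward, debounced so that two crossings closer than `min_separation`
#' frames yield a single candidate. Candidates are offered to the
#' annotator and are never counted as behavior events by the tally.
#'
#' @param series a beak-distance [kinematic_series] (or numeric vector).
#' @param threshold gap value (px) above which the beak counts as open;
#'   must be positive.
#' @param min_separation debounce distance in frames (default 25, i.e.
#'   0.5 s at 50 fps).
#' @return integer vector of 0-based candidate frames.
#' @export
detect_candidate_openings <- function(series, threshold, min_separation = 25) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("detect_candidate_openings: threshold must be positive")
  v <- if (inherits(series, "kinematic_series")) series$values else as.numeric(series)
  above <- !is.na(v) & v >= threshold
  rises <- which(above & !c(FALSE, utils::head(above, -1)))
  if (!length(rises)) return(integer())
  keep <- rises[1]
  for (r in rises[-1]) if (r - keep[length(keep)] >= min_separation) keep <- c(keep, r)
  as.integer(keep - 1L)
}
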